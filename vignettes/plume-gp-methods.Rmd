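---
title: "Modelling point-source fallout in surface soil with plumefall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling point-source fallout in surface soil with plumefall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumefall)
```

## The problem

A point source — here, a fire on a lead-clad roof — releases metal that
settles downwind. Months later, a survey team collects on the order of a
hundred surface-soil samples around the source: some spaced along concentric
rings to map the background in all directions, the rest concentrated in the
wedge of bearings the wind favoured during the release. Each sample has a
position, a soil-source category (tree pit, park, small garden, sidewalk
crack, plant pot), and a Pb concentration in mg/kg from a handheld XRF
instrument.

Three features make naive averaging unreliable:

* concentrations are heavy right tailed (tens to thousands of mg/kg), so a
  few extreme samples dominate raw means;
* soil categories differ systematically — sidewalk cracks preserve legacy
  contamination, parks receive fresh soil — and the categories are very
  unbalanced;
* the survey is spatially clustered, with deliberate oversampling downwind.

`plumefall` addresses all three with a single hierarchical Bayesian model,
and then answers the questions that matter for exposure assessment: *how
much more lead lies in the downwind sector than elsewhere, and how many
kilograms does that excess amount to?*

## The model

Work in source-centred polar coordinates: distance $r$ (km) and compass
bearing $\theta$ (degrees, North = 0, East = 90, clockwise). Concentrations
are modelled on the quarter-power scale, $y = \mathrm{Pb}^{1/4}$ — milder
than a log transform, it stabilises variance when measurement error is
additive at the low end and multiplicative at the high end. On that scale
the observation at location $i$ decomposes as

$$ y_i = \mu_{k[i]} + f(r_i, \theta_i) + \varepsilon_i, \qquad
   \varepsilon_i \sim \mathrm{N}(0, \sigma^2), $$

with $k[i]$ the soil category of sample $i$. The pieces:

* **Soil-category offsets** $\mu_1, \dots, \mu_5$ with iid
  $\mathrm{N}(0, 1)$ priors under the exact constraint
  $\sum_k \mu_k = 0$. The constraint makes the decomposition identifiable
  (any constant could otherwise shuttle between $\mu$ and $f$), and the
  hierarchical prior partially pools the noisy categories (two plant pots)
  toward zero.
* **A latent spatial field** $f$ with a mean-zero Gaussian-process prior and
  product kernel
  $$ \mathrm{Cov}\!\left(f(r_1,\theta_1), f(r_2,\theta_2)\right)
     = \alpha \, e^{-(r_1 - r_2)^2 / \rho_r^2} \,
       e^{-2 \sin^2(\pi |\theta_1 - \theta_2| / 360) / \rho_\theta^2}. $$
  The squared-exponential factor controls smoothness in distance (length
  scale $\rho_r$, km); the periodic factor makes the field continuous across
  the 0°/360° seam (dimensionless length scale $\rho_\theta$); $\alpha$ is
  the marginal variance of the spatial signal. Distances enter in km and
  bearings in degrees, exactly as written.
* **Priors on scales**: $\rho_r \sim \mathrm{N}^+(0, 1.5^2)$,
  $\rho_\theta \sim \mathrm{N}^+(0, 1)$,
  $\alpha, \sigma \sim \mathrm{N}^+(0, 6^2)$ — half-Normal (positive
  truncations of the stated Normal scales), the conventional reading for
  parameters that must be positive. Both the transformed outcome and
  distances in km are roughly unit scaled, so these are weakly informative.

Because $f$ has a mean-zero prior and $\mu$ sums to zero, the overall
concentration level lives in the posterior of $f$; nothing in the model
requires the level to be "explained" separately.

## Inference

`fit_plume_gp()` samples the joint posterior with a two-block
Metropolis-within-Gibbs scheme:

1. The latent field is **marginalized analytically**:
   $y \sim \mathrm{N}(\mu_{k}, \alpha K + \sigma^2 I)$. An adaptive
   random-walk Metropolis step explores
   $(\log\alpha, \log\rho_r, \log\rho_\theta, \log\sigma)$, with the
   proposal covariance adapted during warmup from a Laplace approximation
   at the posterior mode and a running draw covariance, and the step size
   tuned toward 23% acceptance.
2. Given the scales, the four free coordinates of the zero-sum offsets have
   an **exact Gaussian conditional** (a weighted ridge regression), drawn by
   Gibbs. Every retained draw therefore satisfies $\sum_k \mu_k = 0$ to
   machine precision by construction, not by penalty.
3. Conditional on each retained draw, $f$ at the data locations is drawn
   from its exact Gaussian conditional.

Steps 1–3 target the same joint posterior over
$(\mu, \alpha, \rho_r, \rho_\theta, \sigma, f)$ as a sampler that carries
$f$ explicitly, because the marginalization is exact. We chose this design
over explicit latent-vector sampling deliberately: a random-walk sampler in
100+ latent dimensions does not mix at any reasonable chain length, whereas
the marginalized scheme reduces the random-walk to four dimensions and
handles everything else in closed form. The marginal likelihood itself is
exposed as `gp_marginal_loglik()` and is verified in the test suite against
independently coded dense multivariate-normal densities.

Defaults are 4 chains of 3,000 iterations, the first half discarded as
warmup. Convergence is gated, not assumed: the fit fails with a
`plume_convergence_error` (carrying the diagnostics table) if any reported
parameter has split R-hat above 1.05 or effective sample size below 100.
A diagonal jitter of $10^{-9}\alpha$ keeps covariance factorizations
positive-definite.

## Prediction and the plume estimands

`predict_f()` draws the field $\tilde f$ on a polar grid — by default
30 × 30, uniform in $(r, \theta)$ over 0.1–1.5 km — from the exact
conditional Gaussian given each posterior draw's hyperparameters and latent
field. The disc $r < 0.1$ km is excluded throughout: no survey data can
exist inside it and any statement there would be pure extrapolation.
`predict_y()` adds fresh observational noise per draw and location, giving
the predictive outcome for a *typical* soil (offset zero), so sector
comparisons isolate spatial structure from the category composition of the
samples. We chose a grid uniform in polar rather than Cartesian coordinates
because the estimands below are ring-wise and sector-wise; area weighting
(weight $\propto r$) compensates where integrals are needed.

Back-transformation raises draws to the 4th power. Negative field
excursions (possible where data are sparse, since $f$ is mean-zero a
priori) fold to positive concentrations under the literal 4th power; the
default reports that literal convention and a sign-preserving alternative
$\max(\tilde f, 0)^4$ is available via `fold = "positive"`. Quantiles are
computed across transformed draws per location.

With the concentration field in hand, and the downwind wedge fixed *a
priori* from meteorology as the open sector 260°–310° (boundary bearings
count as outside, matching the strict inequalities in the sector's
definition):

* `ring_sector_means()` / `excess_profile()` — at each grid ring, the
  angular mean inside the sector minus the mean outside: the **plume
  excess** as a function of distance, with credible intervals from the
  per-draw differences.
* `average_excess_within()` — area-weighted averages inside and outside the
  sector over the annulus $0.1 < r < R$ km.
* `integrated_excess_mass()` — per draw,
  $\int_{\text{sector}} \left(c(r,\theta) - \bar c_{\text{out}}(r)\right)
  \rho_b \, d \; r \, dr \, d\theta$, converting concentration to mass per
  area through the sampling depth $d$ and soil bulk density $\rho_b$.
  Subtracting the *same-radius* outside mean $\bar c_{\text{out}}(r)$ (not a
  single pooled background) cancels both soil-type composition and any
  radial background trend.

### Numerical choices in the quadrature

Polar-grid quadrature against a 50° sector is exact-by-construction here,
not approximate: the sector (and separately its complement) is partitioned
among the grid bearings it contains by nearest-bearing intervals, and
radial midpoint cells are clipped to the integration bounds. A naive
count-the-nodes rule on a 30 × 30 grid can miss up to 4° of the sector
(an 8% mass error); the partition scheme integrates a constant field
exactly at any resolution. For the mass integral the innermost cell is
extended to $r = 0$ by constant extrapolation of the 0.1 km ring, so that
"within radius $R$" means the full sector of area
$\frac{50}{360}\pi R^2$; the extrapolated disc contributes about 1% of the
area at $R = 1$ km. The sector *averages*, by contrast, are taken over the
annulus $0.1 < r < R$ only, where predictions actually exist.

### Unit conversions

`concentration_to_areal()` converts mg/kg in a sampled layer to the
µg/m² areal loadings used in surface-wipe regulation:
$\text{areal} = \text{conc} \times d \times \rho_b \times 1000$. The
defaults $d = 0.01$ m (the top centimetre actually sampled) and
$\rho_b = 2000$ kg/m³ are the unique pair consistent with both worked
conversions the analysis rests on (200 mg/kg ↔ 4,000,000 µg/m² at 1 cm;
1,000,000 µg/m² over 5 cm ↔ 10 mg/kg); both are arguments, not constants.

## The synthetic-survey generator

`generate_survey()` emulates the survey design so every stage is testable
with known ground truth: 58 samples roughly equally spaced on rings at
0.4 and 1.0 km (24/34, proportional to circumference, with small angular
and radial placement jitter), 42 samples uniform over the downwind sector
at 0.15–1.2 km, and soil categories assigned by shuffling the exact
tallies 55/23/7/13/2 (tree pit / park / garden / sidewalk crack / plant
pot). On the quarter scale the truth field is

$$ f_{\text{true}}(r, \theta) = b_0 + g(r,\theta) +
   A \, e^{-\Delta(\theta, 285°)^2 / (2 \cdot 20°^2)} \, e^{-r / 0.5}, $$

a baseline $b_0 = 3.2$ (≈ 105 mg/kg; it puts the survey median near the
observed ~140 mg/kg), a GP draw $g$ with
$\alpha = 0.6, \rho_r = 0.6, \rho_\theta = 0.6$, and a deterministic plume
bump of amplitude 1.2 centred at bearing 285°. Outcomes add the zero-sum
soil offsets (sidewalk cracks highest, parks lowest) and noise with
$\sigma = 0.35$. The bump is injected as a known mean component rather than
hoping a GP draw produces one, precisely so that recovery experiments can
score the estimated mass against an exact per-replicate truth, computed by
the same polar quadrature on a finer (40 × 40) grid from the realized
noise-free field.

Two honest caveats about that truth. First, the realized excess mass is a
property of the *whole* realized field, GP draw included: a realization can
put more field outside the sector than inside, so the per-replicate true
excess can be negative even though the injected bump is positive (the GP's
sector-scale variability, roughly ±700 kg at the defaults, exceeds the
bump's ≈ +400 kg). Recovery is scored against the realized value — scoring
against the bump alone would fault the model for correctly estimating the
field it was shown. Second, the generator is stylized: its marginal
concentration distribution is right-skewed with realistic magnitudes
(roughly 3–1,000 mg/kg), but it does not reproduce the most extreme
observed values (~9,000 mg/kg), street-layout artefacts, or genuinely
non-Gaussian local contamination (paint chips, construction fill). Passing
calibration tests on these surveys demonstrates internal consistency of
model + estimators, not distributional fidelity to any real city.

`simulate_from_model()` is the generator's counterpart for calibration in
the strict sense: it draws data *exactly* from the fitted model (mean-zero
GP, prior-drawn zero-sum offsets, no baseline, no bump), keeping outcome
signs on the transformed scale. Interval coverage at nominal rates is the
theoretical expectation only in this setting. The survey generator's
baseline and bump live outside the fitted model's support — the zero-mean
GP must absorb a constant of ≈ 3, which inflates the posterior of
$\alpha$ far above the generator's 0.6 — so "hyperparameter recovery" is
only a meaningful question under exact model simulation, while
*mass* recovery remains meaningful under the full generator because the
ring-wise differencing cancels the baseline. The test suite follows that
split: hyperparameter coverage (90% intervals, 20 replicates, $n = 100$)
under `simulate_from_model()`; excess-mass coverage (95% intervals, 10
replicates) under `generate_survey()`.

One related property worth stating plainly: with the bump amplitude set to
zero, individual synthetic surveys still show real inside/outside
differences — the spatial correlation is genuine, not an artefact — and a
naive two-sample t-test rejects far more often than its nominal level. The
correct null property, which the tests assert, is that the difference is
centred on zero *across* realizations.

## Problem sizes and runtime choices

Production-scale defaults (4 × 3,000 iterations, 30 × 30 grid, all retained
draws through prediction) fit a 100-sample survey in a few seconds and
predict in under a minute. The test suite runs its calibration experiments
scaled down — 4 × 600 iterations per fit, 150–300 prediction draws, and
truth grids of 12–20 cells per axis where the truth field's resolution is
not at issue — sizes chosen so the full suite completes in minutes while
leaving the Monte Carlo error small relative to the tolerances being
asserted. Interval-coverage checks at these chain lengths use fits whose
convergence gate is recorded rather than enforced; the gate itself is
exercised separately.

## Known limitations

* The sampler is exact-in-distribution but random-walk based; posteriors
  with strong ridge correlations between $\alpha$ and $\rho_\theta$ mix
  slowly at short chain lengths. The convergence gate reports this rather
  than hiding it.
* Quadrature accuracy for sharply peaked fields is limited by the 12°
  angular spacing of the default grid; use a finer grid for bump widths
  below ~15°.
* The excess estimands condition on the sector being fixed a priori.
  Choosing the sector from the same data would invalidate the intervals.
* Negative-excursion folding under the literal 4th-power back-transform
  slightly inflates concentrations in data-sparse regions; compare both
  `fold` conventions when that matters.
* Areal-loading conversions assume the sampled layer is homogeneous and the
  bulk density known; both enter multiplicatively, so relative errors pass
  straight through.
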