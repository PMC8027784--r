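# Sector-based excess statistics and the integrated excess-mass inventory.
#
# All quantities are computed per posterior draw on the concentration scale
# (f~^4, mg/kg) and then summarized, so credible intervals propagate the full
# joint posterior. Quadrature over the polar grid uses exact partitions:
# bearings partition the sector (and its complement) by nearest grid node,
# and radii get midpoint cells clipped to the integration bounds, so a
# constant field integrates exactly.

# Partition of the circle among grid bearings: w_in[j] > 0 only for nodes
# strictly inside the sector and the w_in sum to the sector width; w_out
# partitions the complement. Both in radians.
angular_partition <- function(thetas, sector) {
  th <- thetas %% 360
  inside <- in_sector(th, sector)
  w_in <- w_out <- numeric(length(th))
  if (any(inside)) {
    idx <- which(inside)[order(th[inside])]
    phi <- th[idx]
    bounds <- c(sector$theta_min, (phi[-length(phi)] + phi[-1]) / 2,
                sector$theta_max)
    w_in[idx] <- diff(bounds) * pi / 180
  }
  if (any(!inside)) {
    idx0 <- which(!inside)
    phi <- (th[idx0] - sector$theta_max) %% 360
    len <- 360 - (sector$theta_max - sector$theta_min)
    idx <- idx0[order(phi)]
    p <- sort(phi)
    bounds <- c(0, (p[-length(p)] + p[-1]) / 2, len)
    w_out[idx] <- diff(bounds) * pi / 180
  }
  list(w_in = w_in, w_out = w_out, inside = inside)
}

# Integral of r dr over each ring's midpoint cell intersected with
# [lower, upper]; rings must be the sorted unique grid radii. km^2.
radial_cell_weights <- function(rings, lower, upper) {
  if (is.unsorted(rings, strictly = TRUE)) {
    stop("ring radii must be strictly increasing", call. = FALSE)
  }
  mids <- (rings[-1] + rings[-length(rings)]) / 2
  lo <- pmax(c(-Inf, mids), lower)
  hi <- pmin(c(mids, Inf), upper)
  pmax(0, hi^2 - lo^2) / 2
}

# Shared precomputation: ring structure and per-ring angular partition of a
# field grid (computed ring by ring so duplicate bearings across rings do not
# interact).
field_geometry <- function(field, sector) {
  rings <- sort(unique(field$grid$r_km))
  ring_of <- match(field$grid$r_km, rings)
  w_in <- w_out <- numeric(nrow(field$grid))
  for (k in seq_along(rings)) {
    idx <- which(ring_of == k)
    ap <- angular_partition(field$grid$bearing_deg[idx], sector)
    w_in[idx] <- ap$w_in
    w_out[idx] <- ap$w_out
  }
  list(rings = rings, ring_of = ring_of,
       ang = list(w_in = w_in, w_out = w_out))
}

# Per-draw weighted column means; w is a node-weight vector.
weighted_draw_means <- function(conc, w) {
  s <- sum(w)
  if (s <= 0) stop("no grid support for the requested region", call. = FALSE)
  drop(conc %*% w) / s
}

#' Per-draw ring means inside and outside a sector
#'
#' At the grid ring nearest `r`, computes for every posterior draw the
#' angular average of the concentration field over bearings inside the
#' sector and over bearings outside it.
#'
#' @param field a [field_grid()].
#' @param sector a [plume_sector()].
#' @param r target radius in km; the nearest grid ring is used.
#' @param use `"f"` for the latent mean field, `"y"` for noisy outcomes
#'   (requires [predict_y()] draws).
#' @param fold back-transform convention, see [back_transform_field()].
#' @return A `data.frame` with one row per draw: `inside`, `outside`,
#'   `excess` (= inside - outside), all mg/kg, plus attribute `r_km` (the
#'   ring actually used).
#' @export
ring_sector_means <- function(field, sector = plume_sector(), r,
                              use = c("f", "y"),
                              fold = c("literal", "positive")) {
  stopifnot(inherits(field, "field_grid"))
  geo <- field_geometry(field, sector)
  if (r < min(geo$rings) - 1e-9 || r > max(geo$rings) + 1e-9) {
    stop("r = ", r, " km is outside the grid's radial range", call. = FALSE)
  }
  ring <- which.min(abs(geo$rings - r))
  on_ring <- geo$ring_of == ring
  conc <- field_conc_draws(field, use = match.arg(use),
                           fold = match.arg(fold))[, on_ring, drop = FALSE]
  inside <- weighted_draw_means(conc, geo$ang$w_in[on_ring])
  outside <- weighted_draw_means(conc, geo$ang$w_out[on_ring])
  structure(data.frame(inside = inside, outside = outside,
                       excess = inside - outside),
            r_km = geo$rings[ring])
}

#' Radial profile of the plume excess
#'
#' For every grid ring, the posterior distribution of the difference between
#' the in-sector and out-of-sector angular mean concentrations.
#'
#' @inheritParams ring_sector_means
#' @param probs interval quantiles; default the central 95%.
#' @return A `data.frame` of class `excess_profile`: `r_km`, `excess_mean`,
#'   `excess_q025`, `excess_q975` (mg/kg; names follow `probs`).
#' @export
excess_profile <- function(field, sector = plume_sector(),
                           probs = c(0.025, 0.975), use = c("f", "y"),
                           fold = c("literal", "positive")) {
  stopifnot(inherits(field, "field_grid"))
  geo <- field_geometry(field, sector)
  conc <- field_conc_draws(field, use = match.arg(use), fold = match.arg(fold))
  rows <- lapply(seq_along(geo$rings), function(k) {
    on_ring <- geo$ring_of == k
    ex <- weighted_draw_means(conc[, on_ring, drop = FALSE],
                              geo$ang$w_in[on_ring]) -
      weighted_draw_means(conc[, on_ring, drop = FALSE],
                          geo$ang$w_out[on_ring])
    c(mean(ex), stats::quantile(ex, probs))
  })
  out <- data.frame(geo$rings, do.call(rbind, rows))
  names(out) <- c("r_km", "excess_mean",
                  sprintf("excess_q%03.0f", 1000 * probs))
  class(out) <- c("excess_profile", "data.frame")
  out
}

#' Area-weighted average concentration inside and outside the sector
#'
#' Averages the concentration field over the annulus 0.1 km < r < `R`,
#' weighting by area (weight proportional to r on a polar grid), separately
#' for the in-sector wedge and its complement, per posterior draw.
#'
#' @inheritParams ring_sector_means
#' @param R outer radius in km; must not exceed the grid's radial extent.
#' @param level `"f"` (mean response) or `"y"` (with observational noise,
#'   requires [predict_y()] draws).
#' @return A list of class `sector_average`: `radius`, `level`,
#'   `avg_inside` / `avg_outside` (each `c(mean, lower, upper)` mg/kg using a
#'   central 95% interval), `excess` (same layout for inside - outside), and
#'   `draws` (per-draw data.frame).
#' @export
average_excess_within <- function(field, sector = plume_sector(), R = 1,
                                  level = c("f", "y"),
                                  fold = c("literal", "positive")) {
  stopifnot(inherits(field, "field_grid"))
  level <- match.arg(level)
  if (R <= 0.1) stop("R must exceed the 0.1 km exclusion zone", call. = FALSE)
  geo <- field_geometry(field, sector)
  if (R > max(geo$rings) + 1e-9) {
    stop("R exceeds the grid's radial extent", call. = FALSE)
  }
  wr <- radial_cell_weights(geo$rings, lower = 0.1, upper = R)[geo$ring_of]
  conc <- field_conc_draws(field, use = level, fold = match.arg(fold))
  inside <- weighted_draw_means(conc, wr * geo$ang$w_in)
  outside <- weighted_draw_means(conc, wr * geo$ang$w_out)
  summ <- function(x) {
    stats::setNames(c(mean(x), stats::quantile(x, c(0.025, 0.975))),
                    c("mean", "lower", "upper"))
  }
  structure(list(
    radius = R, level = level,
    avg_inside = summ(inside), avg_outside = summ(outside),
    excess = summ(inside - outside),
    draws = data.frame(inside = inside, outside = outside)
  ), class = "sector_average")
}

#' @export
print.sector_average <- function(x, ...) {
  cat(sprintf("Sector averages within %.2g km (level %s):\n", x$radius,
              x$level))
  cat(sprintf("  inside plume:  %.0f (95%% interval %.0f-%.0f) mg/kg\n",
              x$avg_inside["mean"], x$avg_inside["lower"],
              x$avg_inside["upper"]))
  cat(sprintf("  outside:       %.0f (95%% interval %.0f-%.0f) mg/kg\n",
              x$avg_outside["mean"], x$avg_outside["lower"],
              x$avg_outside["upper"]))
  invisible(x)
}

#' Integrated excess mass of lead within a radius
#'
#' Integrates, per posterior draw, the excess concentration over the sector
#' area within radius `R` and converts to mass through the sampling depth
#' and soil bulk density:
#' `mass = integral_sector (conc(r, theta) - outside_mean(r)) * depth *
#' density dA`, with `dA = r dr dtheta`. The excess at each point is taken
#' relative to the out-of-sector angular mean at the same radius, so
#' systematic background (and its spatial trend in r) cancels. The inner
#' 0.1 km disc, where no prediction is made, is filled by constant
#' extrapolation of the innermost grid ring (about 1% of the area at
#' R = 1 km).
#'
#' @inheritParams average_excess_within
#' @param depth sampled soil depth in m (default 0.01, i.e. the top 1 cm).
#' @param bulk_density soil bulk density in kg/m^3 (default 2000).
#' @param use `"f"` or `"y"`, as in [ring_sector_means()].
#' @return A list of class `excess_mass`: `mass_kg` (`c(mean, lower, upper)`,
#'   central 95%), `draws` (per-draw masses, kg), `radius`, `depth`,
#'   `bulk_density`.
#' @export
integrated_excess_mass <- function(field, sector = plume_sector(), R = 1,
                                   depth = 0.01, bulk_density = 2000,
                                   use = c("f", "y"),
                                   fold = c("literal", "positive")) {
  stopifnot(inherits(field, "field_grid"))
  if (depth <= 0 || bulk_density <= 0) {
    stop("depth and bulk_density must be positive", call. = FALSE)
  }
  if (R <= 0.1) stop("R must exceed the 0.1 km exclusion zone", call. = FALSE)
  geo <- field_geometry(field, sector)
  if (R > max(geo$rings) + 1e-9) {
    stop("R exceeds the grid's radial extent", call. = FALSE)
  }
  conc <- field_conc_draws(field, use = match.arg(use), fold = match.arg(fold))
  n_draws <- nrow(conc)
  # out-of-sector angular mean per ring and draw
  o <- matrix(NA_real_, n_draws, length(geo$rings))
  for (k in seq_along(geo$rings)) {
    on_ring <- geo$ring_of == k
    o[, k] <- weighted_draw_means(conc[, on_ring, drop = FALSE],
                                  geo$ang$w_out[on_ring])
  }
  wr <- radial_cell_weights(geo$rings, lower = 0, upper = R)
  node_w <- wr[geo$ring_of] * geo$ang$w_in * 1e6      # m^2 per node
  excess <- conc - o[, geo$ring_of, drop = FALSE]     # mg/kg
  mass <- drop(excess %*% node_w) * 1e-6 * depth * bulk_density  # kg
  structure(list(
    mass_kg = stats::setNames(
      c(mean(mass), stats::quantile(mass, c(0.025, 0.975))),
      c("mean", "lower", "upper")),
    draws = mass, radius = R, depth = depth, bulk_density = bulk_density
  ), class = "excess_mass")
}

#' @export
print.excess_mass <- function(x, ...) {
  cat(sprintf(
    "Integrated excess Pb within %.2g km: %.0f kg (95%% interval %.0f-%.0f)\n",
    x$radius, x$mass_kg["mean"], x$mass_kg["lower"], x$mass_kg["upper"]))
  cat(sprintf("  (depth %.3g m, bulk density %.4g kg/m^3)\n", x$depth,
              x$bulk_density))
  invisible(x)
}

#' Convert a soil concentration to an areal loading
#'
#' A concentration in the sampled layer corresponds to a mass per unit
#' surface area through the sampling depth and soil bulk density:
#' `areal (ug/m^2) = conc (mg/kg) * depth (m) * bulk_density (kg/m^3) * 1000`.
#' Areal loadings are the wipe-style unit used for regulatory surface
#' measurements.
#'
#' @param conc concentration in mg/kg.
#' @param depth sampled depth in m.
#' @param bulk_density soil bulk density in kg/m^3.
#' @return Areal loading in micrograms per square metre.
#' @examples
#' concentration_to_areal(200, 0.01, 2000)  # 4e6 ug/m^2
#' @export
concentration_to_areal <- function(conc, depth, bulk_density) {
  stopifnot(all(conc > 0), depth > 0, bulk_density > 0)
  conc * depth * bulk_density * 1000
}

#' @rdname concentration_to_areal
#' @param areal areal loading in ug/m^2.
#' @examples
#' areal_to_concentration(1e6, 0.05, 2000)  # 10 mg/kg over a 5 cm layer
#' @export
areal_to_concentration <- function(areal, depth, bulk_density) {
  stopifnot(all(areal > 0), depth > 0, bulk_density > 0)
  areal / (depth * bulk_density * 1000)
}
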