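# Model / MCMC configuration.

#' Model and sampler configuration
#'
#' Collects the prior scales and MCMC settings for [fit_plume_gp()].
#'
#' Priors (on the quarter-power outcome scale, which is roughly unit scaled,
#' as is distance in km): half-Normal(0, 1.5) on `rho_r`, half-Normal(0, 1)
#' on `rho_theta`, half-Normal(0, 6) on `alpha` and `sigma`, and standard
#' Normal(0, 1) on each soil-type offset `mu_k` subject to the exact zero-sum
#' constraint. Scale parameters are given the positive-truncated (half-Normal)
#' reading of the stated Normal scales, the conventional interpretation of a
#' positive-constrained Bayesian model.
#'
#' @param prior_sd_alpha,prior_sd_sigma,prior_sd_rho_r,prior_sd_rho_theta,prior_sd_mu
#'   prior scale parameters (see Details).
#' @param chains number of MCMC chains (default 4).
#' @param iter iterations per chain including warmup (default 3000).
#' @param warmup_frac fraction of each chain discarded as adaptive warmup
#'   (default 0.5).
#' @param jitter_rel relative diagonal jitter, added as `jitter_rel * alpha`
#'   to GP covariance diagonals (default 1e-9).
#' @param rhat_max,ess_min convergence gates applied by [fit_plume_gp()]
#'   when `check_convergence = TRUE`.
#' @return A list of class `model_config`.
#' @export
model_config <- function(prior_sd_alpha = 6, prior_sd_sigma = 6,
                         prior_sd_rho_r = 1.5, prior_sd_rho_theta = 1,
                         prior_sd_mu = 1,
                         chains = 4L, iter = 3000L, warmup_frac = 0.5,
                         jitter_rel = 1e-9,
                         rhat_max = 1.05, ess_min = 100) {
  stopifnot(prior_sd_alpha > 0, prior_sd_sigma > 0, prior_sd_rho_r > 0,
            prior_sd_rho_theta > 0, prior_sd_mu > 0,
            chains >= 1, iter >= 20, warmup_frac > 0, warmup_frac < 1,
            jitter_rel >= 0)
  structure(list(
    prior_sd_alpha = prior_sd_alpha, prior_sd_sigma = prior_sd_sigma,
    prior_sd_rho_r = prior_sd_rho_r, prior_sd_rho_theta = prior_sd_rho_theta,
    prior_sd_mu = prior_sd_mu,
    chains = as.integer(chains), iter = as.integer(iter),
    warmup_frac = warmup_frac, jitter_rel = jitter_rel,
    rhat_max = rhat_max, ess_min = ess_min
  ), class = "model_config")
}
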