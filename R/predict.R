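# Posterior-predictive reconstruction of the spatial field on a grid.
#
# For each retained posterior draw, the field at new locations is drawn from
# the exact conditional Gaussian given that draw's hyperparameters and its
# latent field at the data locations:
#   f~ | f ~ N( K*' Kdd^-1 f,  K** - K*' Kdd^-1 K* ).
# Adding fresh observational noise per draw gives the predictive outcome at
# "a typical soil type" (mu = 0), so sector comparisons isolate pure spatial
# structure.

#' Construct a field-grid object
#'
#' Container for per-draw values of the latent spatial field (and optionally
#' noisy predictive outcomes) at a set of polar grid locations, on the
#' quarter-power scale.
#'
#' @param grid `data.frame` with columns `r_km` (all at least 0.1) and
#'   `bearing_deg`.
#' @param f_draws draws x locations matrix of latent-field values.
#' @param sigma_draws optional vector of noise sds, one per draw (required
#'   by [predict_y()]).
#' @param y_draws optional draws x locations matrix of noisy predictive
#'   values.
#' @return An object of class `field_grid`.
#' @export
field_grid <- function(grid, f_draws, sigma_draws = NULL, y_draws = NULL) {
  f_draws <- as.matrix(f_draws)
  stopifnot(all(c("r_km", "bearing_deg") %in% names(grid)),
            ncol(f_draws) == nrow(grid))
  if (any(grid$r_km < 0.1 - 1e-12)) {
    stop("grid locations must have r >= 0.1 km (no-imputation zone)",
         call. = FALSE)
  }
  if (!is.null(sigma_draws)) stopifnot(length(sigma_draws) == nrow(f_draws))
  if (!is.null(y_draws)) {
    y_draws <- as.matrix(y_draws)
    stopifnot(all(dim(y_draws) == dim(f_draws)))
  }
  structure(list(grid = grid, f_draws = f_draws, sigma_draws = sigma_draws,
                 y_draws = y_draws),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("<field_grid> %d draws at %d locations (r %.2f-%.2f km)%s\n",
              nrow(x$f_draws), nrow(x$grid), min(x$grid$r_km),
              max(x$grid$r_km),
              if (is.null(x$y_draws)) "" else ", with noisy outcome draws"))
  invisible(x)
}

# Exact conditional moments of the field at `grid` given latent values f at
# `points` under one hyperparameter setting:
#   mean = Kgd Kdd^-1 f,   cov = Kgg - Kgd Kdd^-1 Kdg.
# With no conditioning points this is the prior: mean 0, cov Kgg.
gp_conditional <- function(points, f, grid, alpha, rho_r, rho_theta,
                           jitter = 1e-9 * alpha) {
  m <- nrow(grid)
  Kgg <- build_covariance(grid, alpha, rho_r, rho_theta, jitter = jitter)
  if (is.null(points) || nrow(points) == 0) {
    return(list(mean = numeric(m), cov = Kgg))
  }
  Kdd <- build_covariance(points, alpha, rho_r, rho_theta, jitter = jitter)
  Kgd <- cross_covariance(grid, points, alpha, rho_r, rho_theta)
  L <- chol(Kdd)
  V <- backsolve(L, t(Kgd), transpose = TRUE)
  w <- backsolve(L, f, transpose = TRUE)
  Cg <- Kgg - crossprod(V)
  list(mean = drop(crossprod(V, w)), cov = (Cg + t(Cg)) / 2)
}

#' Posterior-predictive draws of the latent field on a grid
#'
#' Conditions each (optionally thinned) posterior draw on its latent field at
#' the data locations and draws the field at the grid locations from the
#' resulting Gaussian. Grid points closer than 0.1 km to the source are
#' excluded: no data can exist there and inference would be extrapolation.
#'
#' @param fit a [fit_plume_gp()] result with latent-field draws (`draw_f =
#'   TRUE`), or one with zero-column `f` for prior-predictive draws.
#' @param grid polar locations (`r_km`, `bearing_deg`); default [make_grid()].
#' @param n_draws number of posterior draws to use (evenly thinned); default
#'   `min(1000, total draws)`.
#' @param seed integer seed for the predictive noise.
#' @param strict if `TRUE`, error instead of warning-and-dropping grid
#'   points with r below 0.1 km.
#' @return A [field_grid()] with `f_draws`, the matching `sigma_draws`, and
#'   the thinned draw indices as attribute `draw_index`.
#' @export
predict_f <- function(fit, grid = make_grid(), n_draws = NULL, seed = 1L,
                      strict = FALSE) {
  stopifnot(inherits(fit, "plume_fit"))
  too_close <- grid$r_km < 0.1 - 1e-12
  if (any(too_close)) {
    if (strict) stop("grid contains locations with r < 0.1 km", call. = FALSE)
    warning(sum(too_close), " grid location(s) with r < 0.1 km excluded",
            call. = FALSE)
    grid <- grid[!too_close, , drop = FALSE]
  }
  if (nrow(grid) == 0) stop("no grid locations to predict at", call. = FALSE)
  total <- nrow(fit$draws)
  if (is.null(n_draws)) n_draws <- min(1000L, total)
  idx <- unique(round(seq(1, total, length.out = min(n_draws, total))))
  dr <- fit$draws[idx, , drop = FALSE]
  have_data <- !is.null(fit$f) && ncol(fit$f) > 0 && nrow(fit$samples) > 0 &&
    fit$likelihood
  m <- nrow(grid)
  jit <- fit$config$jitter_rel
  pts_d <- fit$samples[, c("r_km", "bearing_deg")]
  out <- with_seed(seed, {
    fd <- matrix(NA_real_, length(idx), m)
    for (j in seq_along(idx)) {
      a <- dr$alpha[j]
      cond <- gp_conditional(
        if (have_data) pts_d, if (have_data) fit$f[idx[j], ],
        grid, a, dr$rho_r[j], dr$rho_theta[j], jitter = a * jit)
      Cg <- cond$cov
      diag(Cg) <- diag(Cg) + max(1e-12, a * jit)
      fd[j, ] <- cond$mean + drop(crossprod(chol(Cg), stats::rnorm(m)))
    }
    fd
  })
  fg <- field_grid(grid, out, sigma_draws = dr$sigma)
  attr(fg, "draw_index") <- idx
  fg
}

#' Add observational noise to field draws
#'
#' Produces posterior-predictive outcome draws `y~ = f~ + N(0, sigma)` with
#' independent noise per draw and location, each draw using its own posterior
#' `sigma`. This is the prediction for a typical soil type (`mu = 0`).
#'
#' @param field a [field_grid()] carrying `sigma_draws` (as produced by
#'   [predict_f()]).
#' @param fit optional [fit_plume_gp()] object; only needed if `field` lacks
#'   `sigma_draws` (its posterior `sigma` draws are then thinned to match).
#' @param seed integer seed.
#' @return The `field_grid` with `y_draws` populated.
#' @export
predict_y <- function(field, fit = NULL, seed = 1L) {
  stopifnot(inherits(field, "field_grid"))
  sig <- field$sigma_draws
  if (is.null(sig)) {
    if (is.null(fit)) stop("field has no sigma_draws; supply the fit",
                           call. = FALSE)
    idx <- unique(round(seq(1, nrow(fit$draws),
                            length.out = nrow(field$f_draws))))
    sig <- fit$draws$sigma[idx]
  }
  nd <- nrow(field$f_draws); m <- ncol(field$f_draws)
  field$y_draws <- field$f_draws +
    with_seed(seed, matrix(stats::rnorm(nd * m), nd, m) * sig)
  field$sigma_draws <- sig
  field
}

#' Back-transform field draws to mg/kg and summarize per location
#'
#' Each draw is raised to the 4th power (the inverse of the quarter-power
#' transform) and per-location posterior means and quantiles are computed
#' across the transformed draws.
#'
#' The latent field has a mean-zero prior, so individual draws can be
#' negative where data are sparse; the literal 4th power is even and folds
#' such negative tails into positive concentrations. The default reports the
#' literal `f^4`; `fold = "positive"` instead uses `max(f, 0)^4`, which
#' treats negative excursions as zero concentration.
#'
#' @param field a [field_grid()].
#' @param probs quantile levels; default the display set
#'   `c(0.10, 0.25, 0.75, 0.90)`.
#' @param fold `"literal"` (`f^4`) or `"positive"` (`max(f, 0)^4`).
#' @param use `"f"` (latent mean field) or `"y"` (noisy outcome draws).
#' @return A `data.frame` with `r_km`, `bearing_deg`, `mean`, and one
#'   `q<level>` column per quantile, all in mg/kg.
#' @export
back_transform_field <- function(field, probs = c(0.10, 0.25, 0.75, 0.90),
                                 fold = c("literal", "positive"),
                                 use = c("f", "y")) {
  stopifnot(inherits(field, "field_grid"))
  fold <- match.arg(fold)
  use <- match.arg(use)
  draws <- field_conc_draws(field, use = use, fold = fold)
  qs <- apply(draws, 2, stats::quantile, probs = probs)
  if (length(probs) == 1) qs <- matrix(qs, nrow = 1)
  out <- data.frame(field$grid, mean = colMeans(draws))
  for (i in seq_along(probs)) {
    out[[sprintf("q%02d", round(100 * probs[i]))]] <- qs[i, ]
  }
  out
}

# Concentration-scale (mg/kg) draws of a field.
field_conc_draws <- function(field, use = c("f", "y"),
                             fold = c("literal", "positive")) {
  use <- match.arg(use)
  fold <- match.arg(fold)
  x <- if (use == "y") {
    if (is.null(field$y_draws)) {
      stop("field has no y_draws; run predict_y() first", call. = FALSE)
    }
    field$y_draws
  } else {
    field$f_draws
  }
  if (fold == "positive") x <- pmax(x, 0)
  x^4
}
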