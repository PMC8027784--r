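# Hierarchical Bayesian GP regression of transformed soil concentrations.
#
# Model (all on the quarter-power scale):
#   y_i = mu_{k[i]} + f(r_i, theta_i) + eps_i,   eps_i ~ N(0, sigma^2)
#   f ~ GP(0, alpha * K1(r, r') * K2(theta, theta'))
#   sum_k mu_k = 0 (exactly, by construction)
#
# Inference: the latent f is marginalized analytically, giving
#   y ~ N(mu_{k}, alpha*K + sigma^2 I),
# and an adaptive random-walk Metropolis sampler explores the 8-dimensional
# hyperparameter posterior (4 free zero-sum offsets + 4 log-scale
# parameters). Conditional on each retained hyperparameter draw, f at the
# data locations is drawn exactly from its Gaussian conditional, so the
# retained (hyperparameters, f) draws target the same joint posterior as
# sampling f explicitly would.

# Orthonormal basis of the zero-sum subspace of R^k: columns of Q are
# orthonormal and orthogonal to the ones vector, so mu = Q z with z ~ N(0, I)
# has exactly the N(0,1) iid prior conditioned on sum(mu) = 0.
zero_sum_basis <- function(k) {
  qr.Q(qr(cbind(rep(1, k), diag(k))))[, 2:k, drop = FALSE]
}

#' Marginal log-likelihood of the GP regression
#'
#' Log density of the transformed outcomes under the model with the latent
#' spatial field integrated out analytically:
#' `y^(1/4) ~ N(mu_k, alpha*K + sigma^2*I)` with the product kernel `K`.
#' This is the exact likelihood the sampler uses (up to the tiny diagonal
#' jitter); it is exposed so the model's probability computations can be
#' checked against independent dense multivariate-normal implementations.
#'
#' @param samples a survey `data.frame` (see [read_survey()]).
#' @param mu numeric length-5 vector of soil-type offsets, ordered as
#'   [soil_types()] (or named by those types).
#' @param alpha,rho_r,rho_theta,sigma hyperparameters, all positive.
#' @param jitter_rel relative diagonal jitter added as `alpha * jitter_rel`;
#'   default 0 (exact marginal likelihood).
#' @return Scalar log-likelihood.
#' @export
gp_marginal_loglik <- function(samples, mu, alpha, rho_r, rho_theta, sigma,
                               jitter_rel = 0) {
  validate_survey(samples)
  if (length(mu) != 5) stop("mu must have length 5", call. = FALSE)
  if (!is.null(names(mu))) mu <- mu[soil_types()]
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  y <- quarter_transform(samples$pb_mg_kg)
  k <- match(samples$soil_type, soil_types())
  K <- build_covariance(samples[, c("r_km", "bearing_deg")],
                        alpha, rho_r, rho_theta,
                        jitter = alpha * jitter_rel)
  S <- K + diag(sigma^2, nrow(K))
  L <- chol(S)
  w <- backsolve(L, y - mu[k], transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(w^2)
}

# log half-Normal(0, sd) density kernel at x > 0 (constants dropped).
log_half_normal <- function(x, sd) -x^2 / (2 * sd^2)

#' Fit the hierarchical GP model by MCMC
#'
#' Samples the joint posterior of the soil-type offsets `mu` (zero-sum), the
#' kernel hyperparameters `alpha`, `rho_r`, `rho_theta`, the noise scale
#' `sigma`, and the latent spatial field `f` at the data locations. See
#' [model_config()] for priors and sampler settings.
#'
#' The sampler is an adaptive random-walk Metropolis on
#' `(z, log alpha, log rho_r, log rho_theta, log sigma)` — `z` being the four
#' free coordinates of the zero-sum offsets — with the latent field
#' marginalized analytically; proposal scale and covariance adapt during
#' warmup and are then frozen. Conditional draws of `f` given each retained
#' hyperparameter draw complete the joint posterior sample.
#'
#' @param samples a survey `data.frame`; at least 2 distinct locations. All
#'   five soil types need not be present (absent types keep prior-only
#'   posteriors).
#' @param config a [model_config()].
#' @param seed integer seed; every chain derives its own stream from it.
#' @param likelihood set `FALSE` to sample from the prior only (useful for
#'   checking the prior implied by the zero-sum parameterization).
#' @param check_convergence if `TRUE` (default), fail with a
#'   `plume_convergence_error` when any reported parameter has split R-hat
#'   above `config$rhat_max` or effective sample size below `config$ess_min`;
#'   the error object carries the diagnostics table.
#' @param draw_f draw the latent field at the data locations for every
#'   retained iteration (needed for [predict_f()]).
#' @param fix optional named list pinning hyperparameters at fixed values
#'   (e.g. `list(alpha = 1e-8)`); pinned parameters are excluded from
#'   sampling. Intended for model-checking, not routine use.
#' @param outcome `"pb"` (default) fits the quarter-power transform of the
#'   `pb_mg_kg` column; `"quarter"` fits a `y_quarter` column directly, which
#'   may be negative. The latter exists for calibration experiments on the
#'   model's native scale, where simulated outcomes are sign-carrying (see
#'   [simulate_from_model()]).
#' @return An object of class `plume_fit`: list with `draws` (a `data.frame`
#'   with one row per retained iteration: `chain`, `mu.<type>`, `alpha`,
#'   `rho_r`, `rho_theta`, `sigma`, `lp`), `f` (retained-draws x n matrix or
#'   `NULL`), `samples`, `diagnostics` (param, rhat, ess), `accept_rate`,
#'   `config`, `seed`.
#' @examples
#' \donttest{
#' sv <- generate_survey(seed = 1)
#' fit <- fit_plume_gp(sv$samples, model_config(iter = 600), seed = 1)
#' print(fit)
#' }
#' @export
fit_plume_gp <- function(samples, config = model_config(), seed = 1L,
                         likelihood = TRUE, check_convergence = TRUE,
                         draw_f = TRUE, fix = list(),
                         outcome = c("pb", "quarter")) {
  outcome <- match.arg(outcome)
  if (outcome == "pb") {
    validate_survey(samples)
    y <- quarter_transform(samples$pb_mg_kg)
  } else {
    if (!"y_quarter" %in% names(samples) ||
        any(!is.finite(samples$y_quarter))) {
      stop("outcome = 'quarter' needs a finite 'y_quarter' column",
           call. = FALSE)
    }
    if (any(!samples$soil_type %in% soil_types())) {
      stop("unknown soil_type values", call. = FALSE)
    }
    y <- samples$y_quarter
  }
  n <- nrow(samples)
  if (likelihood &&
      nrow(unique(samples[, c("r_km", "bearing_deg")])) < 2) {
    stop("need at least 2 distinct locations to fit", call. = FALSE)
  }
  k_idx <- match(samples$soil_type, soil_types())
  Q <- zero_sum_basis(5)
  # pairwise pieces of the product kernel, fixed for the whole run
  Dr2 <- outer(samples$r_km, samples$r_km, "-")^2
  Sth2 <- 2 * sin(pi * abs(outer(samples$bearing_deg, samples$bearing_deg,
                                 "-")) / 360)^2

  scale_names <- c("alpha", "rho_r", "rho_theta", "sigma")
  bad_fix <- setdiff(names(fix), scale_names)
  if (length(bad_fix)) stop("cannot fix: ", paste(bad_fix, collapse = ", "),
                            call. = FALSE)
  free_scales <- setdiff(scale_names, names(fix))
  prior_sd <- c(alpha = config$prior_sd_alpha, rho_r = config$prior_sd_rho_r,
                rho_theta = config$prior_sd_rho_theta,
                sigma = config$prior_sd_sigma)

  # design matrix sending the 4 free zero-sum coordinates z to per-sample
  # offsets: mu = prior_sd_mu * Q z, so the z prior is standard normal
  Ind <- matrix(0, n, 5)
  Ind[cbind(seq_len(n), k_idx)] <- 1
  X <- config$prior_sd_mu * (Ind %*% Q)

  scale_unpack <- function(etas) {
    sc <- as.list(exp(etas))
    names(sc) <- free_scales
    for (nm in names(fix)) sc[[nm]] <- fix[[nm]]
    sc
  }
  log_prior_scales <- function(etas) {
    sc <- scale_unpack(etas)
    lp <- 0
    for (nm in free_scales) {   # half-Normal density + log-Jacobian of exp
      lp <- lp + log_half_normal(sc[[nm]], prior_sd[[nm]]) + log(sc[[nm]])
    }
    lp
  }
  chol_S <- function(sc) {
    Sig <- sc$alpha * exp(-Dr2 / sc$rho_r^2 - Sth2 / sc$rho_theta^2)
    diag(Sig) <- diag(Sig) + sc$alpha * config$jitter_rel + sc$sigma^2
    tryCatch(chol(Sig), error = function(e) NULL)
  }
  loglik_chol <- function(L, z) {
    w <- backsolve(L, y - drop(X %*% z), transpose = TRUE)
    -0.5 * n * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(w^2)
  }
  # joint log posterior over eta = (z, log free scales); used for the
  # mode/Laplace initialization
  log_post <- function(eta) {
    z <- eta[1:4]
    etas <- eta[-(1:4)]
    lp <- -0.5 * sum(z^2) + log_prior_scales(etas)
    if (!likelihood) return(lp)
    L <- chol_S(scale_unpack(etas))
    if (is.null(L)) return(-Inf)
    lp + loglik_chol(L, z)
  }

  n_warm <- max(10L, as.integer(round(config$iter * config$warmup_frac)))
  n_keep <- config$iter - n_warm
  if (n_keep < 1) stop("no post-warmup iterations; lower warmup_frac",
                       call. = FALSE)
  ds <- length(free_scales)
  d <- 4L + ds
  chain_seeds <- sub_seeds(seed, config$chains)

  s_y <- if (n > 1) stats::sd(y) else 1
  if (!is.finite(s_y) || s_y == 0) s_y <- 1

  # Posterior mode and Laplace covariance seed the chains and the random-walk
  # proposal, so even short runs start in the typical set well scaled.
  neg_lp <- function(eta) {
    v <- log_post(eta)
    if (!is.finite(v)) 1e10 else -v
  }
  if (likelihood) {
    init0 <- c(rep(0, 4),
               log(pmax(c(alpha = s_y^2, rho_r = 0.5, rho_theta = 0.5,
                          sigma = s_y / 2)[free_scales], 1e-3)))
    opt <- stats::optim(init0, neg_lp, method = "Nelder-Mead",
                        control = list(maxit = 800, reltol = 1e-8))
    mode_eta <- opt$par
    H <- tryCatch(stats::optimHess(mode_eta, neg_lp), error = function(e) NULL)
    Sig0 <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
  } else {
    mode_eta <- c(rep(0, 4), log(prior_sd[free_scales]))
    Sig0 <- diag(c(rep(1, 4), rep(1.24, ds)))
  }
  if (is.null(Sig0)) Sig0 <- diag(0.05, d)
  ev <- eigen((Sig0 + t(Sig0)) / 2, symmetric = TRUE)
  Sig0 <- ev$vectors %*% (pmax(ev$values, 1e-6 * max(abs(ev$values), 1e-6)) *
                            t(ev$vectors))
  Sig0 <- (Sig0 + t(Sig0)) / 2
  L0 <- chol(Sig0)
  Sig0_s <- Sig0[4 + seq_len(ds), 4 + seq_len(ds), drop = FALSE]

  # One chain of the Metropolis-within-Gibbs sampler: adaptive random walk on
  # the log scales (d <= 4), exact Gaussian Gibbs update of the zero-sum
  # coordinates z given the scales (f stays marginalized throughout).
  run_chain <- function(cs) with_seed(cs, {
    keep <- matrix(NA_real_, n_keep, 9 + 1)
    if (!likelihood) {
      # the prior factorizes, so sample it exactly
      for (t in seq_len(n_keep)) {
        z <- stats::rnorm(4)
        sc <- scale_unpack(log(abs(stats::rnorm(ds, 0, prior_sd[free_scales]))))
        keep[t, ] <- c(drop(Q %*% z) * config$prior_sd_mu, sc$alpha,
                       sc$rho_r, sc$rho_theta, sc$sigma,
                       -0.5 * sum(z^2))
      }
      return(list(keep = keep, acc = 1))
    }
    eta <- mode_eta + drop(crossprod(L0, stats::rnorm(d)))
    z <- eta[1:4]
    etas <- eta[-(1:4)]
    L <- chol_S(scale_unpack(etas))
    tries <- 0
    while (is.null(L) && tries < 20) {
      eta <- mode_eta + 0.3 * drop(crossprod(L0, stats::rnorm(d)))
      z <- eta[1:4]
      etas <- eta[-(1:4)]
      L <- chol_S(scale_unpack(etas))
      tries <- tries + 1
    }
    if (is.null(L)) stop("could not initialize chain", call. = FALSE)
    lps <- log_prior_scales(etas)
    ll <- loglik_chol(L, z)
    ls <- log(2.38 / sqrt(max(ds, 1)))
    t0 <- 100                      # pseudo-observations at the Laplace guess
    mean_run <- etas
    cov_run <- Sig0_s
    Lprop <- if (ds > 0) chol(Sig0_s + diag(1e-9, ds))
    n_acc <- 0L
    for (t in seq_len(config$iter)) {
      if (ds > 0) {
        etas_p <- etas + exp(ls) * drop(crossprod(Lprop, stats::rnorm(ds)))
        L_p <- chol_S(scale_unpack(etas_p))
        a <- 0
        if (!is.null(L_p)) {
          lps_p <- log_prior_scales(etas_p)
          ll_p <- loglik_chol(L_p, z)
          a <- min(1, exp(lps_p + ll_p - lps - ll))
          if (is.finite(a) && stats::runif(1) < a) {
            etas <- etas_p; L <- L_p; lps <- lps_p; ll <- ll_p
            if (t > n_warm) n_acc <- n_acc + 1L
          }
        }
        if (t <= n_warm) {
          if (!is.finite(a)) a <- 0
          ls <- ls + (a - 0.234) / max(t, 20)^0.6
          w <- t + t0
          dlt <- etas - mean_run
          mean_run <- mean_run + dlt / w
          cov_run <- cov_run * (w - 1) / w +
            tcrossprod(dlt, etas - mean_run) / w
          if (t >= 50 && t %% 25 == 0) {
            Lprop <- chol((cov_run + t(cov_run)) / 2 + diag(1e-9, ds))
          }
        }
      }
      # Gibbs: z | scales, y  ~  N(A^-1 Xt S^-1 y, A^-1),  A = Xt S^-1 X + I
      W <- backsolve(L, cbind(X, y), transpose = TRUE)
      Wx <- W[, 1:4, drop = FALSE]
      A <- crossprod(Wx) + diag(4)
      cA <- chol(A)
      m_z <- backsolve(cA, backsolve(cA, crossprod(Wx, W[, 5]),
                                     transpose = TRUE))
      z <- drop(m_z) + backsolve(cA, stats::rnorm(4))
      ll <- loglik_chol(L, z)
      if (t > n_warm) {
        sc <- scale_unpack(etas)
        keep[t - n_warm, ] <- c(drop(Q %*% z) * config$prior_sd_mu,
                                sc$alpha, sc$rho_r, sc$rho_theta, sc$sigma,
                                lps + ll - 0.5 * sum(z^2))
      }
    }
    list(keep = keep, acc = if (ds > 0) n_acc / n_keep else 1)
  })

  chains_out <- lapply(chain_seeds, run_chain)
  par_names <- c(paste0("mu.", soil_types()), scale_names)
  draws <- do.call(rbind, lapply(seq_along(chains_out), function(i) {
    k <- chains_out[[i]]$keep
    colnames(k) <- c(par_names, "lp")
    data.frame(chain = i, k)
  }))
  names(draws)[-1] <- c(par_names, "lp")

  per_param <- lapply(par_names, function(p) {
    sapply(chains_out, function(ch) ch$keep[, match(p, par_names)])
  })
  names(per_param) <- par_names
  monitored <- c(paste0("mu.", soil_types()), free_scales)
  diag_tab <- diagnostics_table(per_param[monitored])

  fit <- structure(list(
    draws = draws, f = NULL, samples = samples, y_quarter = y,
    diagnostics = diag_tab,
    accept_rate = mean(vapply(chains_out, `[[`, numeric(1), "acc")),
    config = config, seed = seed, likelihood = likelihood, fix = fix
  ), class = "plume_fit")

  if (check_convergence) {
    bad <- diag_tab$rhat > config$rhat_max | diag_tab$ess < config$ess_min
    if (any(bad, na.rm = TRUE)) {
      msg <- paste0(
        "chains did not mix: ",
        paste(sprintf("%s (Rhat=%.3f, ESS=%.0f)", diag_tab$param[bad],
                      diag_tab$rhat[bad], diag_tab$ess[bad]), collapse = "; "))
      cond <- structure(
        class = c("plume_convergence_error", "error", "condition"),
        list(message = msg, call = sys.call(-1), diagnostics = diag_tab,
             fit = fit))
      stop(cond)
    }
  }

  if (draw_f) fit$f <- draw_latent_f(fit, seed = sub_seeds(seed, 5)[5])
  fit
}

# Draw the latent field at the data locations, one exact conditional
# Gaussian draw per retained hyperparameter draw:
#   f | y, theta ~ N(Kf S^-1 (y - mu), Kf - Kf S^-1 Kf),  S = Kf + sigma^2 I.
# In prior-only fits, f ~ N(0, Kf).
draw_latent_f <- function(fit, seed = NULL) with_seed(seed, {
  sm <- fit$samples
  n <- nrow(sm)
  y <- fit$y_quarter
  k_idx <- match(sm$soil_type, soil_types())
  dr <- fit$draws
  jit <- fit$config$jitter_rel
  mu_cols <- paste0("mu.", soil_types())
  out <- matrix(NA_real_, nrow(dr), n)
  pts <- sm[, c("r_km", "bearing_deg")]
  for (i in seq_len(nrow(dr))) {
    Kf <- build_covariance(pts, dr$alpha[i], dr$rho_r[i], dr$rho_theta[i],
                           jitter = dr$alpha[i] * jit)
    if (!fit$likelihood) {
      out[i, ] <- drop(crossprod(chol(Kf), stats::rnorm(n)))
      next
    }
    S <- Kf + diag(dr$sigma[i]^2, n)
    L <- chol(S)
    resid <- y - as.numeric(dr[i, mu_cols])[k_idx]
    V <- backsolve(L, Kf, transpose = TRUE)
    w <- backsolve(L, resid, transpose = TRUE)
    m_f <- drop(crossprod(V, w))
    C_f <- Kf - crossprod(V)
    C_f <- (C_f + t(C_f)) / 2
    diag(C_f) <- diag(C_f) + max(1e-12, dr$alpha[i] * jit)
    out[i, ] <- m_f + drop(crossprod(chol(C_f), stats::rnorm(n)))
  }
  out
})

#' @export
print.plume_fit <- function(x, ...) {
  dr <- x$draws
  cat(sprintf("Hierarchical GP fit: %d samples, %d chains x %d retained draws\n",
              nrow(x$samples), max(dr$chain), sum(dr$chain == 1)))
  if (!x$likelihood) cat("  (prior-only: likelihood disabled)\n")
  pars <- c(paste0("mu.", soil_types()), "alpha", "rho_r", "rho_theta", "sigma")
  est <- t(vapply(pars, function(p) {
    v <- dr[[p]]
    c(mean = mean(v), stats::quantile(v, c(0.025, 0.975)))
  }, numeric(3)))
  colnames(est) <- c("mean", "2.5%", "97.5%")
  print(round(est, 3))
  cat(sprintf("  max split R-hat %.3f, min ESS %.0f, acceptance %.2f\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE), x$accept_rate))
  invisible(x)
}
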