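test_that("GP conditioning matches a brute-force joint-Gaussian oracle", {
  set.seed(14)
  train <- data.frame(r_km = runif(5, 0.2, 1.2),
                      bearing_deg = runif(5, 0, 360))
  grid <- data.frame(r_km = c(0.3, 0.8, 1.4), bearing_deg = c(10, 200, 300))
  f <- rnorm(5)
  alpha <- 1.3; rho_r <- 0.5; rho_theta <- 0.8; jit <- 1e-9 * alpha

  cond <- plumefall:::gp_conditional(train, f, grid, alpha, rho_r, rho_theta,
                                     jitter = jit)

  # oracle: build the dense 8x8 joint covariance entry by entry from the
  # scalar kernels, then condition numerically with solve()
  all_pts <- rbind(train, grid)
  J <- matrix(NA_real_, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    J[i, j] <- alpha *
      kernel_se(all_pts$r_km[i], all_pts$r_km[j], rho_r) *
      kernel_periodic(all_pts$bearing_deg[i], all_pts$bearing_deg[j],
                      rho_theta)
  }
  J <- J + diag(jit, 8)
  K11 <- J[1:5, 1:5]; K21 <- J[6:8, 1:5]; K22 <- J[6:8, 6:8]
  mean_or <- drop(K21 %*% solve(K11, f))
  cov_or <- K22 - K21 %*% solve(K11, t(K21))

  expect_equal(cond$mean, mean_or, tolerance = 1e-8)
  expect_equal(cond$cov, cov_or, tolerance = 1e-8)
})

test_that("conditioning interpolates at data locations and is periodic", {
  train <- data.frame(r_km = c(0.4, 0.9), bearing_deg = c(100, 250))
  f <- c(1.7, -0.4)
  # grid point coincident with a data location: mean = latent value, var ~ 0
  cond <- plumefall:::gp_conditional(train, f, train[1, ], 2, 0.6, 0.7,
                                     jitter = 1e-12)
  expect_equal(cond$mean, 1.7, tolerance = 1e-5)
  expect_lt(cond$cov[1, 1], 1e-5)

  # the field is continuous across the 0/360 seam
  g0 <- plumefall:::gp_conditional(train, f,
                                   data.frame(r_km = 0.6, bearing_deg = 0),
                                   1, 0.5, 0.5)
  g360 <- plumefall:::gp_conditional(train, f,
                                     data.frame(r_km = 0.6,
                                                bearing_deg = 360 - 1e-9),
                                     1, 0.5, 0.5)
  expect_equal(g0$mean, g360$mean, tolerance = 1e-6)
  expect_equal(g0$cov[1, 1], g360$cov[1, 1], tolerance = 1e-6)
})

test_that("with no data the prior predictive has mean zero and variance alpha", {
  grid <- make_grid(0.2, 1.0, 4)
  cond <- plumefall:::gp_conditional(NULL, NULL, grid, alpha = 2.5,
                                     rho_r = 0.5, rho_theta = 0.5,
                                     jitter = 0)
  expect_equal(cond$mean, rep(0, nrow(grid)))
  expect_equal(unname(diag(cond$cov)), rep(2.5, nrow(grid)))

  # the draw-based path agrees within Monte Carlo error
  fit <- fake_fit(empty_survey(), alpha = rep(2.5, 4000), rho_r = 0.5,
                  rho_theta = 0.5, sigma = 0.3, f = numeric(0))
  fld <- predict_f(fit, grid, seed = 2, n_draws = 4000)
  expect_equal(mean(fld$f_draws), 0, tolerance = 0.1)
  expect_equal(mean(apply(fld$f_draws, 2, var)), 2.5, tolerance = 0.2)
})

test_that("conditioning on more data never increases predictive variance", {
  set.seed(31)
  pts <- data.frame(r_km = runif(6, 0.2, 1.3), bearing_deg = runif(6, 0, 360))
  f <- rnorm(6)
  grid <- make_grid(0.15, 1.45, 5)
  v3 <- diag(plumefall:::gp_conditional(pts[1:3, ], f[1:3], grid,
                                        1.1, 0.6, 0.6)$cov)
  v6 <- diag(plumefall:::gp_conditional(pts, f, grid, 1.1, 0.6, 0.6)$cov)
  expect_true(all(v6 <= v3 + 1e-10))
  # predictive sd is larger far from the data than at a data location
  at_data <- diag(plumefall:::gp_conditional(pts, f, pts[1, ],
                                             1.1, 0.6, 0.6)$cov)
  far <- data.frame(r_km = 1.45,
                    bearing_deg = (pts$bearing_deg[1] + 180) %% 360)
  at_far <- diag(plumefall:::gp_conditional(pts, f, far, 1.1, 0.6, 0.6)$cov)
  expect_gt(at_far, at_data)
})

test_that("predict_f excludes the unsampled inner disc", {
  sv <- make_test_survey(6)
  fit <- fake_fit(sv, alpha = rep(1, 3), rho_r = 0.5, rho_theta = 0.5,
                  sigma = 0.3, f = rnorm(6))
  bad <- rbind(data.frame(r_km = 0.05, bearing_deg = 10),
               data.frame(r_km = 0.5, bearing_deg = 20))
  expect_warning(fld <- predict_f(fit, bad, seed = 1), "excluded")
  expect_equal(nrow(fld$grid), 1)
  expect_error(predict_f(fit, bad, seed = 1, strict = TRUE), "r < 0.1")
})

test_that("predict_y adds noise with the posterior sigma", {
  sv <- make_test_survey(5)
  nd <- 6000
  fit <- fake_fit(sv, alpha = rep(1, nd), rho_r = 0.5, rho_theta = 0.5,
                  sigma = 0.4, f = rnorm(5))
  grid <- make_grid(0.3, 1.2, 3)
  fld <- predict_f(fit, grid, n_draws = nd, seed = 5)

  # sigma = 0 reproduces f exactly
  fld0 <- fld
  fld0$sigma_draws <- rep(0, nrow(fld0$f_draws))
  expect_identical(predict_y(fld0, seed = 1)$y_draws, fld0$f_draws)

  # moment check at 6,000 draws: Var(y - f) ~ posterior mean sigma^2
  fld <- predict_y(fld, seed = 2)
  eps <- fld$y_draws - fld$f_draws
  expect_equal(mean(apply(eps, 2, var)), 0.16, tolerance = 0.01)
  expect_equal(colMeans(fld$y_draws), colMeans(fld$f_draws),
               tolerance = 0.03)
})

test_that("back-transformed summaries respect monotonicity and constants", {
  grid <- make_grid(0.2, 1.0, 3)
  const <- field_grid(grid, matrix(2, 50, nrow(grid)))
  s <- back_transform_field(const)
  expect_equal(s$mean, rep(16, nrow(grid)))
  expect_equal(s$q10, rep(16, nrow(grid)))
  expect_equal(s$q90, rep(16, nrow(grid)))

  set.seed(6)
  # odd draw count so the median is an exact order statistic
  fld <- field_grid(grid, matrix(abs(rnorm(401 * nrow(grid), 2, 0.7)),
                                 401, nrow(grid)))
  s <- back_transform_field(fld)
  expect_true(all(s$q10 <= s$q25 & s$q25 <= s$q75 & s$q75 <= s$q90))

  # for positive draws the quantile of the 4th power is the 4th power of the
  # quantile (monotone-transform identity)
  med <- back_transform_field(fld, probs = 0.5)$q50
  med_direct <- apply(fld$f_draws, 2, median)^4
  expect_equal(med, med_direct, tolerance = 1e-10)

  # the sign-preserving alternative floors negative excursions at zero
  neg <- field_grid(grid, matrix(c(-1, 3), 2, nrow(grid)))
  lit <- back_transform_field(neg, fold = "literal")
  pos <- back_transform_field(neg, fold = "positive")
  expect_equal(lit$mean, rep((1 + 81) / 2, nrow(grid)))
  expect_equal(pos$mean, rep(81 / 2, nrow(grid)))
})
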