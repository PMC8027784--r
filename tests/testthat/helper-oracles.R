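# Independent oracles and small fixtures, built in code.

# Dense multivariate-normal log density via determinant() + solve(): a
# deliberately different code path from the package's Cholesky computation.
dense_mvn_logdens <- function(y, mean, Sigma) {
  n <- length(y)
  r <- y - mean
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + drop(t(r) %*% solve(Sigma, r)))
}

# A small valid survey at fixed polar locations.
make_test_survey <- function(n = 8, seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("T%02d", seq_len(n)),
    r_km = runif(n, 0.2, 1.2),
    bearing_deg = runif(n, 0, 360),
    soil_type = sample(soil_types(), n, replace = TRUE),
    pb_mg_kg = exp(rnorm(n, log(150), 0.8)),
    sn_mg_kg = NA_real_
  )
}

# Minimal plume_fit carrying fixed hyperparameter draws (one row per draw)
# and latent-field values, for deterministic prediction tests.
fake_fit <- function(samples, alpha, rho_r, rho_theta, sigma, f,
                     mu = rep(0, 5), config = model_config()) {
  nd <- length(alpha)
  draws <- data.frame(chain = 1L,
                      matrix(rep(mu, each = nd), nd, 5,
                             dimnames = list(NULL, paste0("mu.", soil_types()))),
                      alpha = alpha, rho_r = rho_r, rho_theta = rho_theta,
                      sigma = sigma, lp = 0)
  names(draws) <- c("chain", paste0("mu.", soil_types()),
                    "alpha", "rho_r", "rho_theta", "sigma", "lp")
  y <- if (nrow(samples) > 0) quarter_transform(samples$pb_mg_kg) else numeric(0)
  structure(list(draws = draws,
                 f = matrix(f, nrow = nd, ncol = nrow(samples), byrow = TRUE),
                 samples = samples, y_quarter = y, diagnostics = NULL,
                 accept_rate = 1, config = config, seed = 1L,
                 likelihood = TRUE, fix = list()),
            class = "plume_fit")
}

# Empty survey frame with the right columns (for prior-predictive tests).
empty_survey <- function() {
  data.frame(sample_id = character(), r_km = numeric(),
             bearing_deg = numeric(), soil_type = character(),
             pb_mg_kg = numeric(), sn_mg_kg = numeric())
}
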