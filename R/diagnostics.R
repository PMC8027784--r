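# Convergence diagnostics: split R-hat (computed here) and effective sample
# size (delegated to coda's spectral estimator).

#' Split R-hat for one parameter
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain drift registers as apparent non-convergence.
#'
#' @param x iterations x chains matrix of post-warmup draws.
#' @return Scalar R-hat; 1 indicates convergence. Returns `NA` for fewer than
#'   4 draws per chain and 1 for numerically constant draws.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp)
  ch_mean <- colMeans(sp)
  ch_var <- apply(sp, 2, stats::var)
  W <- mean(ch_var)
  B <- half * stats::var(ch_mean)
  if (!is.finite(W) || W <= .Machine$double.eps * max(abs(ch_mean), 1)) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Effective sample size pooled over chains (coda spectral estimate, capped at
# the number of draws).
ess_pooled <- function(x) {
  x <- as.matrix(x)
  total <- 0
  for (j in seq_len(ncol(x))) {
    v <- stats::var(x[, j])
    if (!is.finite(v) || v == 0) {
      total <- total + nrow(x)
    } else {
      total <- total + as.numeric(coda::effectiveSize(x[, j]))
    }
  }
  min(total, length(x))
}

# Diagnostics table over a named list of iterations x chains matrices.
diagnostics_table <- function(param_list) {
  data.frame(
    param = names(param_list),
    rhat = vapply(param_list, split_rhat, numeric(1)),
    ess = vapply(param_list, ess_pooled, numeric(1)),
    row.names = NULL
  )
}
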