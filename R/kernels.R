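# Product covariance kernel: squared-exponential in distance, periodic in
# bearing. Distances enter in km and bearings in degrees; the 360 in the
# periodic kernel assumes degree units, giving the field period 360 so it is
# continuous across the North seam.

#' Squared-exponential distance kernel
#'
#' `K1(r1, r2) = exp(-(r1 - r2)^2 / rho_r^2)`.
#'
#' @param r1,r2 distances in km (vectorized).
#' @param rho_r length-scale in km, positive.
#' @return Covariance factor(s) in (0, 1].
#' @examples
#' kernel_se(0, 1, 1)  # exp(-1)
#' @export
kernel_se <- function(r1, r2, rho_r) {
  if (!is.finite(rho_r) || rho_r <= 0) stop("rho_r must be positive", call. = FALSE)
  exp(-(r1 - r2)^2 / rho_r^2)
}

#' Periodic bearing kernel
#'
#' `K2(theta1, theta2) = exp(-2 sin^2(pi |theta1 - theta2| / 360) / rho_theta^2)`,
#' with period 360 degrees in the bearing difference.
#'
#' @param theta1,theta2 bearings in degrees (vectorized).
#' @param rho_theta dimensionless length-scale, positive.
#' @return Covariance factor(s) in (0, 1].
#' @examples
#' kernel_periodic(0, 180, 1)  # exp(-2)
#' @export
kernel_periodic <- function(theta1, theta2, rho_theta) {
  if (!is.finite(rho_theta) || rho_theta <= 0) {
    stop("rho_theta must be positive", call. = FALSE)
  }
  exp(-2 * sin(pi * abs(theta1 - theta2) / 360)^2 / rho_theta^2)
}

#' Product-kernel covariance matrix over polar locations
#'
#' Entry (i, j) is `alpha * K1(r_i, r_j) * K2(theta_i, theta_j)`, with
#' `jitter` added to the diagonal for numerical positive-definiteness.
#'
#' @param points a `data.frame` with columns `r_km` and `bearing_deg`.
#' @param alpha marginal variance of the spatial field (transformed units^2).
#' @param rho_r,rho_theta kernel length-scales, see [kernel_se()] and
#'   [kernel_periodic()].
#' @param jitter small variance added to the diagonal; default
#'   `1e-9 * alpha`.
#' @return A symmetric positive-definite matrix of dimension `nrow(points)`.
#' @export
build_covariance <- function(points, alpha, rho_r, rho_theta,
                             jitter = 1e-9 * alpha) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive", call. = FALSE)
  n <- nrow(points)
  if (is.null(n) || n < 1) stop("points must be a non-empty data.frame", call. = FALSE)
  K <- cross_covariance(points, points, alpha, rho_r, rho_theta)
  K + diag(jitter, n)
}

# Rectangular alpha * K1 * K2 between two location sets; no jitter.
cross_covariance <- function(p1, p2, alpha, rho_r, rho_theta) {
  if (!is.finite(rho_r) || rho_r <= 0) stop("rho_r must be positive", call. = FALSE)
  if (!is.finite(rho_theta) || rho_theta <= 0) {
    stop("rho_theta must be positive", call. = FALSE)
  }
  dr2 <- outer(p1$r_km, p2$r_km, "-")^2
  s2 <- sin(pi * abs(outer(p1$bearing_deg, p2$bearing_deg, "-")) / 360)^2
  alpha * exp(-dr2 / rho_r^2 - 2 * s2 / rho_theta^2)
}
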