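# Quarter-power outcome transform.
#
# Soil metal concentrations are heavy right tailed: errors are roughly
# additive at the low end and multiplicative at the high end. The 1/4-power
# transform is milder than the log and keeps measurement errors of comparable
# size across sites; all modelling happens on the transformed scale.

#' Quarter-power transform of a concentration
#'
#' @param pb concentration(s) in mg/kg; must be strictly positive.
#' @return `pb^(1/4)`, in (mg/kg)^(1/4).
#' @seealso [inverse_transform()]
#' @examples
#' quarter_transform(16)   # 2
#' @export
quarter_transform <- function(pb) {
  if (any(!is.finite(pb)) || any(pb <= 0)) {
    stop("concentrations must be finite and strictly positive", call. = FALSE)
  }
  pb^0.25
}

#' Back-transform from the quarter-power scale
#'
#' @param y value(s) on the quarter-power scale; must be non-negative.
#' @return `y^4`, in mg/kg.
#' @examples
#' inverse_transform(quarter_transform(137.2))  # 137.2
#' @export
inverse_transform <- function(y) {
  if (any(!is.finite(y)) || any(y < 0)) {
    stop("transformed values must be finite and non-negative", call. = FALSE)
  }
  y^4
}
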