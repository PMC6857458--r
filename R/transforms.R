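#' Beta to M-value transform
#'
#' M = log2(beta / (1 - beta)), the logit2 transform. Beta values are clamped
#' to [eps, 1 - eps] first so the output is finite; the M scale is the
#' variance-stabilized scale on which differential testing is done, while
#' beta remains the reporting scale.
#'
#' @param beta numeric vector or matrix of beta values in [0, 1].
#' @param eps clamp bound in (0, 0.5); default 1e-6, small enough not to
#'   move interior values materially.
#' @return object of the same shape on the M scale.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0 || eps >= 0.5) {
    stop("eps must lie in (0, 0.5)")
  }
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]")
  }
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' M-value to beta transform
#'
#' Inverse of [beta_to_m()]: beta = 2^M / (1 + 2^M), computed in a form
#' stable for large |M|.
#'
#' @param m numeric vector or matrix of finite M values.
#' @return object of the same shape on the beta scale, in (0, 1).
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}
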