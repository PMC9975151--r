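#' Numerically stable softplus
#'
#' Computes `log(1 + exp(z))` as `max(z, 0) + log1p(exp(-|z|))`, which is
#' exact to working precision for arguments of any magnitude (no overflow for
#' `z` up to the largest representable double).
#'
#' @param z Numeric vector.
#' @return Numeric vector of the same length.
#' @keywords internal
softplus <- function(z) {
  pmax(z, 0) + log1p(exp(-abs(z)))
}

# inverse of softplus, used to initialize log-scale parameters
softplus_inv <- function(s) {
  stopifnot(all(s > 0))
  # log(exp(s) - 1), stable for large s
  s + log(-expm1(-s))
}

#' Squashing activation function
#'
#' The parametric sigmoid-like family
#' \deqn{S_\beta(x) = \frac{1}{\beta}\,
#'   \ln\!\frac{1 + e^{\beta x}}{1 + e^{\beta (x - 1)}}}
#' which is strictly increasing (for `beta > 0`), maps the real line into
#' `(0, 1)`, and converges to the cutting function `clip(x, 0, 1)` as
#' `beta` grows. It satisfies the complement identity
#' `S(x) + S(1 - x) = 1` exactly, which is what makes perceptrons with
#' Lukasiewicz gate weights behave as continuous-valued logical operators.
#' The maximum deviation from `clip(x, 0, 1)` is `log(2) / beta`, attained
#' at `x = 0` and `x = 1`.
#'
#' Evaluation uses the softplus decomposition
#' `S_beta(x) = (softplus(beta * x) - softplus(beta * (x - 1))) / beta`,
#' stable for `|beta * x|` well beyond 700.
#'
#' @param x Numeric vector (any finite reals).
#' @param beta Sharpness parameter, a single non-zero real. Larger values
#'   make gates crisper; `beta = 10` is a good training default, `beta = 100`
#'   is effectively crisp.
#' @return Numeric vector in `(0, 1)` (for `beta > 0`).
#' @examples
#' squashing(0.5, 10)            # exactly 0.5 by symmetry
#' squashing(c(-1, 0.3, 2), 100) # close to clip(x, 0, 1)
#' @export
squashing <- function(x, beta = 10) {
  check_beta(beta)
  if (!all(is.finite(x))) {
    stop("`x` must be finite.", call. = FALSE)
  }
  (softplus(beta * x) - softplus(beta * (x - 1))) / beta
}

#' Derivative of the squashing function
#'
#' `S'_beta(x) = sigmoid(beta x) - sigmoid(beta (x - 1))`, used for
#' backpropagation through frozen logic layers.
#'
#' @inheritParams squashing
#' @return Numeric vector of derivatives, in `(0, 1)` for `beta > 0`.
#' @export
squashing_deriv <- function(x, beta = 10) {
  check_beta(beta)
  stats::plogis(beta * x) - stats::plogis(beta * (x - 1))
}

check_beta <- function(beta) {
  if (length(beta) != 1L || !is.finite(beta) || beta == 0) {
    stop("`beta` must be a single finite non-zero real.", call. = FALSE)
  }
  invisible(beta)
}
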