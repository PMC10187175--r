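#' Zero-truncated Poisson probability mass function
#'
#' Probability that a recorded cytometer event contains `n` cells when the
#' number of cells per event follows a Poisson process conditioned on at
#' least one cell (an empty laser window is never recorded as an event):
#' \deqn{p(n) = \frac{\lambda^n}{n! (e^\lambda - 1)}, \quad n \ge 1}
#' where \eqn{\lambda} is the mean number of cells arriving per event window.
#'
#' @param n Integer vector of cell counts, all >= 1. `n = 0` is a domain
#'   error: zero is truncated.
#' @param lambda Positive scalar, mean cells per event window.
#' @return Numeric vector of probabilities; sums to 1 over `n >= 1`.
#' @examples
#' ztp_pmf(1, 1)          # 1/(e - 1) = 0.581977
#' sum(ztp_pmf(1:100, 2)) # 1 to machine precision
#' @export
ztp_pmf <- function(n, lambda) {
  check_positive_scalar(lambda, "lambda")
  if (any(n < 1) || any(n != floor(n))) {
    abort("`n` must be an integer >= 1: the zero class is truncated.")
  }
  # expm1 keeps the normalising constant accurate for small lambda
  exp(n * log(lambda) - lgamma(n + 1)) / expm1(lambda)
}

#' Mean of the zero-truncated Poisson
#'
#' Expected number of cells per recorded event, \eqn{\lambda / (1 - e^{-\lambda})}.
#' Defined by continuity as 1 at `lambda = 0` (no coincidence).
#'
#' @param lambda Non-negative scalar or vector.
#' @return Mean cells per event, >= 1.
#' @export
ztp_mean <- function(lambda) {
  check_nonnegative(lambda, "lambda")
  out <- ifelse(lambda == 0, 1, lambda / (-expm1(-lambda)))
  as.numeric(out)
}

#' Correct a total event count for coincidence
#'
#' An event may contain more than one cell, so the number of recorded events
#' undercounts cells. The corrected cell count is the event count times the
#' mean cells per event of the zero-truncated Poisson:
#' \eqn{N_{corr} = N_{obs}\,\lambda e^\lambda / (e^\lambda - 1)}.
#' At `lambda = 0` the correction factor is 1 (continuous limit).
#'
#' @param n_observed Non-negative event count(s), noise events excluded.
#' @param lambda Non-negative coincidence intensity (mean cells per event).
#' @return Corrected cell count (real-valued).
#' @examples
#' correct_total_count(1000, 1) # 1581.977
#' @export
correct_total_count <- function(n_observed, lambda) {
  check_nonnegative(n_observed, "n_observed")
  check_nonnegative(lambda, "lambda")
  n_observed * ztp_mean(lambda)
}

# -- shared argument checks ---------------------------------------------------

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single finite number > 0.", name))
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be finite and >= 0.", name))
  }
  invisible(x)
}

check_frequencies <- function(f, name = "f_true", tol = 1e-8) {
  if (!is.numeric(f) || length(f) < 2L || any(!is.finite(f))) {
    abort(sprintf("`%s` must be a numeric vector of length >= 2.", name))
  }
  if (any(f < 0) || any(f > 1)) {
    abort(sprintf("`%s` entries must lie in [0, 1].", name))
  }
  if (abs(sum(f) - 1) > tol) {
    abort(sprintf("`%s` must sum to 1 (got %.12g).", name, sum(f)))
  }
  invisible(f)
}
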