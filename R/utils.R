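# Internal numerical helpers.

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Shannon entropy of a probability vector, in nats
#'
#' Zero entries contribute zero (the 0 log 0 = 0 convention).
#'
#' @param p Non-negative numeric vector summing to 1.
#' @return Non-negative scalar entropy in nats.
#' @export
entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

normalise <- function(x) {
  s <- sum(x)
  if (s <= 0) stop("cannot normalise a vector with non-positive total")
  x / s
}

assert_finite <- function(x, what) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x))) {
    stop(sprintf("%s must be a finite numeric vector", what))
  }
  invisible(x)
}

assert_prob <- function(p, what, tol = 1e-8) {
  assert_finite(p, what)
  if (any(p < -tol) || abs(sum(p) - 1) > 1e-6) {
    stop(sprintf("%s must be a probability vector (non-negative, summing to 1)", what))
  }
  invisible(p)
}

is_col_stochastic <- function(M, tol = 1e-8) {
  all(M >= -tol) && all(M <= 1 + tol) && all(abs(colSums(M) - 1) < 1e-6)
}
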