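# Independent oracles used to cross-check the implementation: a digamma
# computed from the recurrence plus asymptotic series, a scalar-loop
# enumeration of the expected free energy, and the exact Dirichlet KL
# divergence for auditing the inverse-count novelty approximation.

# digamma via psi(x) = psi(x + 1) - 1/x and the asymptotic expansion
digamma_oracle <- function(x) {
  acc <- 0
  while (x < 6) {
    acc <- acc - 1 / x
    x <- x + 1
  }
  acc + log(x) - 1 / (2 * x) - 1 / (12 * x^2) + 1 / (120 * x^4) - 1 / (252 * x^6)
}

# scalar-loop enumeration of G(pi) over the remaining horizon; every term is
# computed by direct summation over states and outcomes, without matrix ops
oracle_efe <- function(model, belief, policy, flags = list(use_novelty = TRUE, use_salience = TRUE),
                       t = 1L) {
  a <- model$obs$a
  mask <- model$obs$learnable
  c_log <- model$pref$log
  n_out <- nrow(a); n_states <- ncol(a)
  colsum <- numeric(n_states)
  for (s in 1:n_states) for (o in 1:n_out) colsum[s] <- colsum[s] + a[o, s]
  Abar <- matrix(0, n_out, n_states)
  for (s in 1:n_states) for (o in 1:n_out) Abar[o, s] <- a[o, s] / colsum[s]
  b <- belief
  G <- 0
  for (tau in (t + 1L):model$horizon) {
    B <- model$trans$B[[policy[tau - 1L]]]
    b2 <- numeric(n_states)
    for (s2 in 1:n_states) for (s1 in 1:n_states) b2[s2] <- b2[s2] + B[s2, s1] * b[s1]
    b <- b2
    obar <- numeric(n_out)
    for (o in 1:n_out) for (s in 1:n_states) obar[o] <- obar[o] + Abar[o, s] * b[s]
    sal <- 0
    if (flags$use_salience) {
      for (o in 1:n_out) for (s in 1:n_states) {
        joint <- Abar[o, s] * b[s]
        if (joint > 0 && obar[o] > 0) sal <- sal + joint * log(Abar[o, s] / obar[o])
      }
    }
    nov <- 0
    if (flags$use_novelty) {
      for (o in 1:n_out) for (s in 1:n_states) {
        if (mask[o, s]) {
          w <- 0.5 * (1 / a[o, s] - 1 / colsum[s])
          nov <- nov + obar[o] * w * b[s]
        }
      }
    }
    w_u <- switch(model$pref_timing,
      all = 1,
      final = if (tau == model$horizon) 1 else 0,
      ramp = 4^(tau - model$horizon))
    util <- 0
    for (o in 1:n_out) util <- util + obar[o] * c_log[o] * w_u
    G <- G - nov - sal - util
  }
  G
}

# exact KL(Dir(b) || Dir(a)) for one column of concentration parameters
kl_dirichlet <- function(b, a) {
  sb <- sum(b); sa <- sum(a)
  lgamma(sb) - sum(lgamma(b)) - lgamma(sa) + sum(lgamma(a)) +
    sum((b - a) * (digamma(b) - digamma(sb)))
}

# exact expected information gain about one learnable column after a single
# observation drawn from its predictive distribution
exact_column_info_gain <- function(col) {
  p <- col / sum(col)
  sum(vapply(seq_along(col), function(o) {
    b <- col
    b[o] <- b[o] + 1
    p[o] * kl_dirichlet(b, col)
  }, numeric(1)))
}
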