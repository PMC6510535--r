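# Posterior beliefs over hidden states given observations, and the
# variational free energy of a belief. At the shallow horizons used here the
# variational fixed point coincides with exact discrete Bayesian filtering,
# which is what these functions implement.

#' Propagate a state belief through an action's transition matrix
#'
#' @param belief Probability vector over states.
#' @param trans An [transition_model()] (or plain list of matrices).
#' @param action Action index.
#' @return Probability vector `B[[action]] %*% belief`.
#' @export
predict_states <- function(belief, trans, action) {
  B <- if (inherits(trans, "aimaze_trans")) trans$B else trans
  if (action < 1L || action > length(B)) stop("invalid action index")
  M <- B[[action]]
  if (ncol(M) != length(belief)) stop("belief does not match the state dimension")
  assert_prob(belief, "belief")
  normalise(as.vector(M %*% belief))
}

#' Bayesian state update given an observed outcome
#'
#' Posterior proportional to `exp(lnA[o, ]) * prior`. The update is invariant
#' to rescaling the likelihood row by a constant.
#'
#' @param prior Probability vector over states.
#' @param lnA Expected log-likelihood matrix (outcomes x states).
#' @param o Observed outcome index.
#' @return Posterior probability vector.
#' @export
bayes_update <- function(prior, lnA, o) {
  if (o < 1L || o > nrow(lnA)) stop("invalid outcome index")
  if (ncol(lnA) != length(prior)) stop("prior does not match the state dimension")
  assert_prob(prior, "prior")
  lik <- exp(lnA[o, ] - max(lnA[o, prior > 0]))
  w <- lik * prior
  s <- sum(w)
  if (s <= 0 || !is.finite(s)) {
    stop(sprintf("observation of outcome %d is impossible under the prior", o))
  }
  w / s
}

#' Variational free energy of a belief given an observation
#'
#' `F = KL[posterior || prior] - E_posterior[lnA[o, ]]` (complexity minus
#' accuracy). Minimised by, and equal to the negative log evidence at, the
#' exact Bayesian posterior.
#'
#' @param posterior,prior Probability vectors over states with shared support.
#' @param lnA Expected log-likelihood matrix.
#' @param o Observed outcome index.
#' @return Scalar free energy in nats.
#' @export
variational_free_energy <- function(posterior, prior, lnA, o) {
  assert_prob(posterior, "posterior")
  assert_prob(prior, "prior")
  if (any(posterior > 0 & prior == 0)) stop("posterior support is not contained in the prior's")
  idx <- posterior > 0
  kl <- sum(posterior[idx] * (log(posterior[idx]) - log(prior[idx])))
  acc <- sum(posterior[idx] * lnA[o, idx])
  kl - acc
}

#' Bayesian model average of per-policy state beliefs
#'
#' @param beliefs Matrix with one column per policy (states x policies), or a
#'   list of belief vectors.
#' @param weights Policy posterior probabilities.
#' @return Probability vector `sum_pi Q(pi) Q(s | pi)`.
#' @export
bayesian_model_average <- function(beliefs, weights) {
  if (is.list(beliefs)) beliefs <- do.call(cbind, beliefs)
  if (ncol(beliefs) != length(weights)) stop("one weight per policy belief required")
  assert_prob(weights, "policy weights")
  normalise(as.vector(beliefs %*% weights))
}
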