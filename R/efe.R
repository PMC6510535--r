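# Expected free energy of policies and precision-controlled selection.
#
# For each policy and future timestep tau the value decomposes into three
# additive terms, all in nats:
#   novelty   — expected information gain about the Dirichlet observation
#               model (drives active learning),
#   salience  — expected information gain about hidden states, the mutual
#               information between predicted states and outcomes (drives
#               active inference),
#   utility   — expected log preference of predicted outcomes (<= 0).
# G(pi, tau) = -novelty - salience - utility; G(pi) = sum_tau G(pi, tau).
# Policies are scored by a softmax of -gamma * G, and actions sampled from an
# alpha-sharpened marginal over the policies' next actions.

#' Predicted outcome distribution under a state belief
#'
#' @param s_bar Probability vector over states.
#' @param A_bar Column-stochastic expected likelihood matrix.
#' @return Probability vector over outcomes, `A_bar %*% s_bar`.
#' @export
predictive_outcome <- function(s_bar, A_bar) {
  if (ncol(A_bar) != length(s_bar)) stop("state belief does not match the likelihood matrix")
  assert_prob(s_bar, "state belief")
  as.vector(A_bar %*% s_bar)
}

#' Salience: expected information gain about hidden states
#'
#' The mutual information between predicted states and outcomes,
#' `H[o_bar] - sum_s s_bar(s) H[A_bar[, s]]` (predicted outcome entropy minus
#' expected ambiguity), in nats. Non-negative; zero when all state columns
#' emit identically or the state is already certain.
#'
#' @param s_bar Probability vector over states.
#' @param A_bar Expected likelihood matrix.
#' @return Non-negative scalar.
#' @export
salience <- function(s_bar, A_bar) {
  o_bar <- predictive_outcome(s_bar, A_bar)
  amb <- sum(s_bar * apply(A_bar, 2L, entropy_nats))
  max(entropy_nats(o_bar) - amb, 0)
}

#' Inverse-count novelty weights for a Dirichlet observation model
#'
#' `W[o,s] = (1/a[o,s] - 1/sum_o' a[o',s]) / 2`, zeroed outside the learnable
#' mask. Approximates the expected KL between the posterior and prior
#' Dirichlet beliefs after one observation of (o, s).
#'
#' @param a Counts matrix.
#' @param learnable Logical mask of learnable entries.
#' @return Non-negative weight matrix, zero where not learnable.
#' @export
novelty_weights <- function(a, learnable) {
  if (any(a[learnable] <= 0)) stop("learnable entries must have positive counts")
  W <- 0.5 * sweep(1 / a, 2L, 1 / colSums(a), "-")
  W[!learnable] <- 0
  W
}

#' Novelty: expected information gain about model parameters
#'
#' `sum_{o,s} o_bar(o) W[o,s] s_bar(s)` restricted to learnable entries.
#' Vanishes as counts grow large (a confident model offers no further
#' information gain) and for states with no learnable entries.
#'
#' @param s_bar Probability vector over states.
#' @param o_bar Probability vector over outcomes.
#' @param a Counts matrix.
#' @param learnable Logical mask of learnable entries.
#' @return Non-negative scalar.
#' @export
novelty <- function(s_bar, o_bar, a, learnable) {
  W <- novelty_weights(a, learnable)
  as.numeric(t(o_bar) %*% W %*% s_bar)
}

#' Expected utility of predicted outcomes
#'
#' `o_bar . c_log`, the expected log prior preference; always <= 0 for a
#' log-normalised preference vector.
#'
#' @param o_bar Probability vector over outcomes.
#' @param c_log Log-probability preference vector.
#' @return Non-positive scalar.
#' @export
expected_utility <- function(o_bar, c_log) {
  if (length(o_bar) != length(c_log)) stop("outcome prediction does not match the preference vector")
  sum(o_bar * c_log)
}

#' Ablation flags for the epistemic terms
#'
#' The utility term is always active; the two information terms can be
#' switched off to produce "broken" active learning / active inference.
#'
#' @param use_novelty,use_salience Logical.
#' @return List of flags.
#' @export
ablation_flags <- function(use_novelty = TRUE, use_salience = TRUE) {
  list(use_novelty = isTRUE(use_novelty), use_salience = isTRUE(use_salience))
}

#' Expected free energy of one policy over the remaining horizon
#'
#' Rolls the current belief forward through the policy's remaining actions
#' and accumulates the per-timestep three-term decomposition. Any term whose
#' ablation flag is off contributes zero. The utility term is weighted over
#' the trial according to the model's `pref_timing` (by default a geometric
#' ramp, `4^(tau - T)`: full weight at the end of the trial, quarter weight
#' one step earlier); the information terms always count fully.
#'
#' @param model An `aimaze_model`.
#' @param belief Current state belief (conditioned on observations up to `t`).
#' @param policy Integer vector of the policy's actions (full length T - 1).
#' @param flags [ablation_flags()].
#' @param t Current timestep (1-based; future steps are `t+1 .. T`).
#' @param cache Optional precomputed list from [efe_cache()].
#' @return Data frame with one row per future timestep: `tau`, `novelty`,
#'   `salience`, `utility`, `G_tau`, plus the policy total in attribute `G`.
#' @export
expected_free_energy <- function(model, belief, policy, flags = ablation_flags(),
                                 t = 1L, cache = NULL) {
  if (length(policy) < model$horizon - 1L) stop("policy shorter than the remaining horizon")
  if (t >= model$horizon) stop("no future timesteps remain")
  if (is.null(cache)) cache <- efe_cache(model)
  taus <- (t + 1L):model$horizon
  out <- matrix(0, length(taus), 4L)
  b <- belief
  for (k in seq_along(taus)) {
    tau <- taus[k]
    b <- as.vector(model$trans$B[[policy[tau - 1L]]] %*% b)
    o_bar <- as.vector(cache$Abar %*% b)
    nov <- if (flags$use_novelty && cache$any_learnable) {
      as.numeric(t(o_bar) %*% cache$W %*% b)
    } else 0
    sal <- if (flags$use_salience) {
      max(entropy_nats(o_bar) - sum(b * cache$colH), 0)
    } else 0
    w_u <- switch(model$pref_timing,
      all = 1,
      final = if (tau == model$horizon) 1 else 0,
      ramp = 4^(tau - model$horizon))
    util <- if (w_u > 0) w_u * sum(o_bar * model$pref$log) else 0
    out[k, ] <- c(nov, sal, util, -(nov + sal + util))
  }
  res <- data.frame(tau = taus, novelty = out[, 1L], salience = out[, 2L],
                    utility = out[, 3L], G_tau = out[, 4L])
  attr(res, "G") <- sum(out[, 4L])
  res
}

#' Precompute per-trial quantities for policy evaluation
#'
#' @param model An `aimaze_model`.
#' @return List with the expected likelihood `Abar`, per-column entropies
#'   `colH`, novelty weights `W` and a learnability flag.
#' @export
efe_cache <- function(model) {
  Abar <- expected_likelihood(model$obs$a)
  list(
    Abar = Abar,
    colH = apply(Abar, 2L, entropy_nats),
    W = novelty_weights(model$obs$a, model$obs$learnable),
    any_learnable = any(model$obs$learnable)
  )
}

#' Evaluate expected free energy for a set of policies
#'
#' @param model An `aimaze_model`.
#' @param belief Current state belief.
#' @param policy_idx Indices (into `model$policies`) of the policies to score.
#' @param flags [ablation_flags()].
#' @param t Current timestep.
#' @param cache Optional [efe_cache()].
#' @return List with `G` (one value per policy) and `ledger`, the per-policy,
#'   per-timestep decomposition table.
#' @export
evaluate_policies <- function(model, belief, policy_idx = seq_len(nrow(model$policies)),
                              flags = ablation_flags(), t = 1L, cache = NULL) {
  if (is.null(cache)) cache <- efe_cache(model)
  rows <- vector("list", length(policy_idx))
  G <- numeric(length(policy_idx))
  for (i in seq_along(policy_idx)) {
    ev <- expected_free_energy(model, belief, model$policies[policy_idx[i], ],
                               flags = flags, t = t, cache = cache)
    ev$policy <- policy_idx[i]
    rows[[i]] <- ev
    G[i] <- attr(ev, "G")
  }
  list(G = G, policy_idx = policy_idx, ledger = do.call(rbind, rows))
}

#' Policy posterior from expected free energies
#'
#' `Q(pi) = softmax(-gamma * G)`. As `gamma -> 0` the posterior becomes
#' uniform (pure random exploration).
#'
#' @param G Vector of policy expected free energies.
#' @param gamma Positive policy precision.
#' @return Probability vector over policies.
#' @export
policy_posterior <- function(G, gamma) {
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be positive")
  assert_finite(G, "G")
  softmax(-gamma * G)
}

#' Marginal next-action distribution under a policy posterior
#'
#' @param q Policy posterior over the policies in `policies`.
#' @param policies Policy matrix (rows matching `q`).
#' @param t Current timestep (the action taken at `t` is column `t`).
#' @param n_actions Total number of actions.
#' @return Probability vector over actions.
#' @export
action_marginal <- function(q, policies, t, n_actions) {
  acts <- policies[, t]
  p <- vapply(seq_len(n_actions), function(a) sum(q[acts == a]), numeric(1))
  p
}

#' Sample an action under action precision alpha
#'
#' Samples from `softmax(alpha * log P(a))` over the actions with positive
#' marginal probability. At `alpha = 1` this is the marginal itself; as
#' `alpha -> Inf` it approaches the argmax (ties broken by the lowest action
#' index, applied deterministically for non-finite `alpha`).
#'
#' @param p_action Marginal action probabilities.
#' @param alpha Positive action precision (may be `Inf`).
#' @return List with the sampled `action` and the sampling distribution
#'   `prob` (zero for excluded actions). Uses the current RNG state.
#' @export
select_action <- function(p_action, alpha) {
  support <- which(p_action > 0)
  if (length(support) == 0L) stop("no action has positive probability")
  if (!is.finite(alpha)) {
    probs <- numeric(length(p_action))
    best <- support[which.max(p_action[support])]  # which.max: lowest index wins ties
    probs[best] <- 1
    return(list(action = best, prob = probs))
  }
  lp <- alpha * log(p_action[support])
  ps <- softmax(lp)
  probs <- numeric(length(p_action))
  probs[support] <- ps
  action <- support[sample.int(length(support), 1L, prob = ps)]
  list(action = action, prob = probs)
}
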