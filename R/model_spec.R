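# Containers and validation for the discrete generative model: a Dirichlet
# observation model (counts a over outcomes x states), action-conditioned
# transition matrices B, log-preferences over outcomes c, an initial-state
# Dirichlet prior d, precision parameters, and a policy set.

COUNT_FLOOR <- 1e-16  # floor for structurally-zero counts before digamma

#' Dirichlet observation model
#'
#' Holds the concentration parameters (counts) of the Dirichlet-distributed
#' likelihood mapping hidden states (columns) to outcomes (rows), the counts
#' at the start of the experiment, and a mask of entries subject to learning.
#' Structural zeros are floored at a tiny positive value so that digamma-based
#' expected log-likelihoods are defined; floored entries are never learnable.
#'
#' @param a Non-negative outcomes x states matrix of concentration parameters.
#' @param learnable Logical matrix of the same shape marking entries that
#'   accumulate counts during learning. Defaults to no learnable entries.
#' @return An object of class `aimaze_obs` with fields `a`, `a0`, `learnable`.
#' @export
observation_model <- function(a, learnable = NULL) {
  a <- as.matrix(a)
  if (any(!is.finite(a)) || any(a < 0)) stop("counts must be finite and non-negative")
  if (any(colSums(a) <= 0)) stop("every state column needs at least one positive count")
  if (is.null(learnable)) learnable <- matrix(FALSE, nrow(a), ncol(a))
  learnable <- as.matrix(learnable)
  if (!identical(dim(learnable), dim(a))) stop("learnable mask must match the counts' shape")
  if (any(learnable & a <= 0)) stop("learnable entries must have strictly positive counts")
  a[a == 0] <- COUNT_FLOOR
  structure(list(a = a, a0 = a, learnable = learnable), class = "aimaze_obs")
}

#' Column-stochastic transition model
#'
#' One state x state matrix per action; column j gives the distribution of the
#' next state when action is taken in state j.
#'
#' @param B List of square column-stochastic matrices, one per action.
#' @return An object of class `aimaze_trans`.
#' @export
transition_model <- function(B) {
  if (!is.list(B) || length(B) < 1L) stop("B must be a non-empty list of matrices")
  n <- nrow(as.matrix(B[[1L]]))
  B <- lapply(B, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != n || ncol(m) != n) stop("all transition matrices must be square and equally sized")
    if (!is_col_stochastic(m)) stop("transition matrix columns must sum to 1 with entries in [0,1]")
    m
  })
  structure(list(B = B, n_states = n, n_actions = length(B)), class = "aimaze_trans")
}

#' Log-normalised outcome preferences
#'
#' Preferences are authored as unnormalised log-expectations over outcomes and
#' passed through a log-softmax, so that `exp(c_log)` is a proper prior
#' distribution over outcomes.
#'
#' @param c_raw Finite numeric vector of raw preference values.
#' @return Log-probability vector of the same length.
#' @examples
#' log_preferences(c(0, 2, 4, -2))  # c(-4.15, -2.15, -0.15, -6.15) to 2 dp
#' @export
log_preferences <- function(c_raw) {
  assert_finite(c_raw, "preference vector")
  c_raw - log_sum_exp(c_raw)
}

#' Prior odds ratio between two outcomes implied by the preferences
#'
#' Returns `exp(c_log[i] - c_log[j])`, which equals `exp(c_raw[i] - c_raw[j])`
#' by shift invariance of the log-softmax.
#'
#' @param c_log Log-probability preference vector.
#' @param i,j Outcome indices.
#' @return Positive scalar.
#' @export
preference_ratio <- function(c_log, i, j) {
  n <- length(c_log)
  if (i < 1 || i > n || j < 1 || j > n) stop("outcome index out of range")
  exp(c_log[i] - c_log[j])
}

#' Preference container
#'
#' @param c_raw Raw preference vector (log-expectations as authored).
#' @return List with `raw` and `log` (log-softmax of `raw`).
#' @export
preference_vector <- function(c_raw) {
  list(raw = c_raw, log = log_preferences(c_raw))
}

#' Expected likelihood matrix from Dirichlet counts
#'
#' Column-normalised Dirichlet means: `Abar[o,s] = a[o,s] / sum_o' a[o',s]`.
#'
#' @param a Counts matrix (outcomes x states).
#' @return Column-stochastic matrix of the same shape.
#' @export
expected_likelihood <- function(a) {
  a <- as.matrix(a)
  cs <- colSums(a)
  if (any(cs <= 0)) stop("expected likelihood undefined for an all-zero column")
  sweep(a, 2L, cs, "/")
}

#' Expected log-likelihood under the Dirichlet posterior
#'
#' `lnA[o,s] = digamma(a[o,s]) - digamma(sum_o' a[o',s])`, the expectation of
#' the log emission probability under the Dirichlet belief about the
#' observation model. Used for Bayesian state updates.
#'
#' @param a Counts matrix with strictly positive entries.
#' @return Real matrix of the same shape (entries are <= 0 in expectation
#'   terms but individually unbounded below).
#' @export
expected_log_likelihood <- function(a) {
  a <- as.matrix(a)
  if (any(a <= 0)) stop("expected log-likelihood requires strictly positive counts")
  sweep(digamma(a), 2L, digamma(colSums(a)), "-")
}

#' Initial-state Dirichlet belief
#'
#' @param d_counts Non-negative vector of concentration parameters over states.
#' @return List with `counts`, `counts0` and the normalised probability `prob`.
#' @export
initial_state_belief <- function(d_counts) {
  if (any(!is.finite(d_counts)) || any(d_counts < 0) || sum(d_counts) <= 0) {
    stop("initial-state counts must be non-negative with a positive total")
  }
  list(counts = d_counts, counts0 = d_counts, prob = d_counts / sum(d_counts))
}

#' Precision parameters
#'
#' `beta` is the rate hyper-prior on the policy precision gamma (the expected
#' precision is `1/beta`, and gamma is held at that value throughout a
#' simulation); `alpha` is the precision of action selection.
#'
#' @param beta Positive policy-precision rate parameter.
#' @param alpha Positive action precision.
#' @return List with `beta`, `alpha` and `gamma = 1/beta`.
#' @export
precision_params <- function(beta = 1, alpha = 4) {
  if (!is.finite(beta) || beta <= 0) stop("beta must be positive")
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive")
  list(beta = beta, alpha = alpha, gamma = 1 / beta)
}

#' Policy set
#'
#' @param policies Matrix (or list of equal-length vectors) of action indices;
#'   one row per policy, one column per trial step (horizon - 1 steps).
#' @param n_actions Number of available actions.
#' @return Integer matrix of action indices.
#' @export
policy_set <- function(policies, n_actions) {
  if (is.list(policies)) {
    len <- unique(lengths(policies))
    if (length(len) != 1L) stop("all policies must have equal length")
    policies <- do.call(rbind, policies)
  }
  policies <- matrix(as.integer(policies), nrow = nrow(as.matrix(policies)))
  if (any(policies < 1L) || any(policies > n_actions)) stop("policy actions must index into B")
  policies
}

#' Assemble a generative model
#'
#' Bundles the observation model, transitions, preferences, initial-state
#' prior, precisions, policy set, horizon and learning rates into one object.
#'
#' @param obs An [observation_model()].
#' @param trans A [transition_model()].
#' @param pref A [preference_vector()].
#' @param d An [initial_state_belief()].
#' @param precisions A [precision_params()].
#' @param policies A [policy_set()] matrix with `horizon - 1` columns.
#' @param horizon Number of timesteps per trial (observations), >= 2.
#' @param eta Learning rate for observation-model counts.
#' @param eta_d Learning rate for initial-state counts (defaults to `eta`).
#' @param pref_timing Within-trial time profile of the utility term:
#'   "ramp" (default) weights the expected utility at future step tau by
#'   `4^(tau - T)` — preferences describe end-of-trial outcomes at full
#'   weight, while intermediate outcomes still carry a quarter-weight
#'   opportunity cost; "final" scores only the last timestep; "all" scores
#'   every step fully.
#' @param state_factors Optional list of per-state factor labels (e.g.
#'   `location`, `context`) used for factorised initial-state updates.
#' @param labels Optional list of `states`, `outcomes`, `actions` name vectors.
#' @return Object of class `aimaze_model`.
#' @export
generative_model <- function(obs, trans, pref, d, precisions = precision_params(),
                             policies, horizon, eta = 0.5, eta_d = eta,
                             pref_timing = c("ramp", "final", "all"),
                             state_factors = NULL, labels = NULL) {
  pref_timing <- match.arg(pref_timing)
  model <- structure(list(
    obs = obs, trans = trans, pref = pref, d = d, precisions = precisions,
    policies = policies, horizon = as.integer(horizon),
    eta = eta, eta_d = eta_d, pref_timing = pref_timing,
    state_factors = state_factors, labels = labels
  ), class = "aimaze_model")
  model
}

#' Validate a generative model
#'
#' Checks all structural invariants and returns a character vector of
#' violations (empty if the model is valid). Run before any simulation.
#'
#' @param model An `aimaze_model`.
#' @return Character vector of violated invariants.
#' @export
validate_model <- function(model) {
  v <- character(0)
  a <- model$obs$a
  n_out <- nrow(a); n_states <- ncol(a)
  if (any(colSums(a) <= 0)) v <- c(v, "observation counts: all-zero state column")
  if (any(a < model$obs$a0 - 1e-12)) v <- c(v, "observation counts fell below their priors")
  Abar <- try(expected_likelihood(a), silent = TRUE)
  if (inherits(Abar, "try-error") || any(abs(colSums(Abar) - 1) > 1e-8)) {
    v <- c(v, "expected likelihood columns do not sum to 1")
  }
  for (k in seq_along(model$trans$B)) {
    if (!is_col_stochastic(model$trans$B[[k]])) {
      v <- c(v, sprintf("transition matrix %d is not column-stochastic", k))
    }
    if (nrow(model$trans$B[[k]]) != n_states) {
      v <- c(v, sprintf("transition matrix %d does not match the state dimension", k))
    }
  }
  if (abs(sum(exp(model$pref$log)) - 1) > 1e-8) v <- c(v, "exp(log preferences) do not sum to 1")
  if (length(model$pref$log) != n_out) v <- c(v, "preference vector does not match the outcome dimension")
  if (length(model$d$counts) != n_states) v <- c(v, "initial-state counts do not match the state dimension")
  if (any(model$d$counts < 0) || sum(model$d$counts) <= 0) v <- c(v, "initial-state counts invalid")
  if (model$precisions$beta <= 0 || model$precisions$alpha <= 0) v <- c(v, "precisions must be positive")
  if (ncol(model$policies) != model$horizon - 1L) v <- c(v, "policy length does not match horizon - 1")
  if (any(model$policies < 1L) || any(model$policies > model$trans$n_actions)) {
    v <- c(v, "policy contains an invalid action index")
  }
  v
}

#' @export
print.aimaze_model <- function(x, ...) {
  cat(sprintf("aimaze generative model: %d outcomes x %d states, %d actions, %d policies, T = %d\n",
              nrow(x$obs$a), ncol(x$obs$a), x$trans$n_actions, nrow(x$policies), x$horizon))
  cat(sprintf("  beta = %g (gamma = %g), alpha = %g, eta = %g, learnable entries: %d\n",
              x$precisions$beta, x$precisions$gamma, x$precisions$alpha, x$eta,
              sum(x$obs$learnable)))
  invisible(x)
}
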