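# Programmatic constructors for every model and environment used in the
# simulations and tests. No data files: everything is built in code.

FIXED_COUNT <- 512  # concentration mass for known (unlearned) likelihood entries

det_counts <- function(n_out, rows_probs) {
  # build one column of fixed counts from a (possibly probabilistic) emission
  col <- rep(0, n_out)
  for (nm in seq_along(rows_probs)) col[rows_probs[[nm]][1L]] <- FIXED_COUNT * rows_probs[[nm]][2L]
  col
}

#' Generative model for the reward-learning T-maze
#'
#' Three states (start, safe arm, risky arm), four outcomes (start,
#' safe-reward, high-reward, no-reward), two one-step policies (go safe, go
#' risky). The mappings at the start and safe arm are known (large fixed
#' counts); the risky arm's two reward outcomes carry small learnable
#' concentration parameters `a0_risky`, so the agent starts out maximally
#' uncertain about the risky reward probability. Preferences are
#' `c = (0, 2, 4, -2)`.
#'
#' @param a0_risky Prior concentration for each risky-arm reward outcome.
#' @param eta Learning rate for the risky-arm counts.
#' @param beta Policy-precision rate parameter.
#' @param alpha Action precision.
#' @return An `aimaze_model`.
#' @export
make_learning_model <- function(a0_risky = 0.25, eta = 0.5, beta = 1, alpha = 4) {
  a <- cbind(
    det_counts(4L, list(c(1L, 1))),  # start
    det_counts(4L, list(c(2L, 1))),  # safe arm
    rep(0, 4L)                       # risky arm, learnable
  )
  a[3:4, 3L] <- a0_risky
  mask <- matrix(FALSE, 4L, 3L)
  mask[3:4, 3L] <- TRUE
  B <- list(
    matrix(rep(c(0, 1, 0), 3L), 3L, 3L),  # all -> safe
    matrix(rep(c(0, 0, 1), 3L), 3L, 3L)   # all -> risky
  )
  generative_model(
    obs = observation_model(a, mask),
    trans = transition_model(B),
    pref = preference_vector(c(0, 2, 4, -2)),
    d = initial_state_belief(c(1, 0, 0)),
    precisions = precision_params(beta = beta, alpha = alpha),
    policies = policy_set(rbind(1L, 2L), 2L),
    horizon = 2L, eta = eta,
    labels = list(
      states = c("start", "safe", "risky"),
      outcomes = c("start", "safe_reward", "high_reward", "no_reward"),
      actions = c("go_safe", "go_risky"),
      risky_state = 3L, high_outcome = 3L, noreward_outcome = 4L,
      risky_action = 2L
    )
  )
}

#' Generative model for the context-inference T-maze
#'
#' Eight states (locations start/cue/safe/risky crossed with a high- or
#' low-reward context) and seven outcomes (start, cue-signals-high,
#' cue-signals-low, safe-reward, high-reward, no-reward, plus one reserved
#' outcome that is never emitted). The cue deterministically signals the
#' context; the risky arm rewards with probability `p_high` in the high and
#' `p_low` in the low context. The initial-state prior is certain about the
#' start location but uniform over the two contexts. Four two-step policies:
#' safe-then-stay, risky-then-stay, cue-then-safe, cue-then-risky (the arms
#' are absorbing, so the direct policies simply remain at the chosen arm).
#'
#' By default the observation model is fully known (no learnable entries, as
#' in a pure hidden-state-exploration setting); `learnable_risky = TRUE`
#' replaces the risky-arm mappings with small learnable counts `a0_risky`
#' for parameter-exploration agents.
#'
#' @param p_high,p_low Risky reward probability in the two contexts.
#' @param learnable_risky Make the risky-arm mappings learnable.
#' @param a0_risky Prior concentration for learnable risky entries.
#' @param eta,eta_d Learning rates for observation and initial-state counts.
#' @param beta Policy-precision rate parameter.
#' @param alpha Action precision.
#' @return An `aimaze_model`.
#' @export
make_inference_model <- function(p_high = 0.75, p_low = 0.25,
                                 learnable_risky = FALSE, a0_risky = 0.25,
                                 eta = 0.5, eta_d = 0.5, beta = 1, alpha = 16) {
  n_out <- 7L; n_states <- 8L
  a <- matrix(0, n_out, n_states)
  mask <- matrix(FALSE, n_out, n_states)
  for (ctx in 1:2) {
    off <- (ctx - 1L) * 4L
    a[1L, off + 1L] <- FIXED_COUNT                       # start
    a[if (ctx == 1L) 2L else 3L, off + 2L] <- FIXED_COUNT  # cue signals context
    a[4L, off + 3L] <- FIXED_COUNT                       # safe reward
    p <- if (ctx == 1L) p_high else p_low
    if (learnable_risky) {
      a[5:6, off + 4L] <- a0_risky
      mask[5:6, off + 4L] <- TRUE
    } else {
      a[5L, off + 4L] <- FIXED_COUNT * p
      a[6L, off + 4L] <- FIXED_COUNT * (1 - p)
    }
  }
  stay <- diag(8L)
  move_to <- function(loc) {
    # change location, preserve context; arms (3, 4) are absorbing
    M <- matrix(0, 8L, 8L)
    for (ctx in 0:1) for (from in 1:4) {
      to <- if (from %in% 3:4) from else loc
      M[ctx * 4L + to, ctx * 4L + from] <- 1
    }
    M
  }
  generative_model(
    obs = observation_model(a, mask),
    trans = transition_model(list(stay, move_to(2L), move_to(3L), move_to(4L))),
    pref = preference_vector(c(0, 0, 0, 2, 4, -2, 0)),
    d = initial_state_belief(c(0.5, 0, 0, 0, 0.5, 0, 0, 0)),
    precisions = precision_params(beta = beta, alpha = alpha),
    policies = policy_set(rbind(c(3L, 1L), c(4L, 1L), c(2L, 3L), c(2L, 4L)), 4L),
    horizon = 3L, eta = eta, eta_d = eta_d,
    state_factors = list(location = rep(1:4, 2L), context = rep(1:2, each = 4L),
                         static = "context", start_location = 1L),
    labels = list(
      states = paste(rep(c("start", "cue", "safe", "risky"), 2L),
                     rep(c("high", "low"), each = 4L), sep = "_"),
      outcomes = c("start", "cue_high", "cue_low", "safe_reward",
                   "high_reward", "no_reward", "unused"),
      actions = c("stay", "go_cue", "go_safe", "go_risky"),
      cue_action = 2L, safe_action = 3L, risky_action = 4L
    )
  )
}

#' Generative model for the information-preference task
#'
#' Two offers with equal reward probability 0.5 and pellet amounts `m_a`
#' (informative offer) and `m_b`. Nine states track the chosen offer, the
#' hidden reward identity and the trial phase; offer A's delay states emit a
#' signal that reveals the identity, offer B's emit a blank. Reward utility
#' is linear in the pellet amount (0.4 raw preference units per pellet, so a
#' four-pellet reward matches the high-reward preference of the T-maze
#' tasks).
#'
#' @param m_a,m_b Pellet amounts of the informative and uninformative offer.
#' @param beta Policy-precision rate parameter.
#' @param alpha Action precision.
#' @param bonus "salience" models the signal as resolving hidden-state
#'   uncertainty (known signal mapping); "novelty" instead makes the signal
#'   mapping learnable with small counts, so the information bonus is a
#'   model-parameter one.
#' @param util_per_pellet Raw preference units per pellet.
#' @return An `aimaze_model`.
#' @export
make_info_model <- function(m_a, m_b, beta = 1, alpha = 1,
                            bonus = c("salience", "novelty"),
                            util_per_pellet = 0.4) {
  bonus <- match.arg(bonus)
  # states: start, A-delay-win, A-delay-lose, B-delay-win, B-delay-lose,
  #         A-final-win, A-final-lose, B-final-win, B-final-lose
  n_states <- 9L; n_out <- 7L
  a <- matrix(0, n_out, n_states)
  a[1L, 1L] <- FIXED_COUNT
  a[2L, 2L] <- FIXED_COUNT; a[3L, 3L] <- FIXED_COUNT   # offer A signal
  a[4L, 4L] <- FIXED_COUNT; a[4L, 5L] <- FIXED_COUNT   # offer B blank
  a[5L, 6L] <- FIXED_COUNT; a[7L, 7L] <- FIXED_COUNT   # offer A outcome
  a[6L, 8L] <- FIXED_COUNT; a[7L, 9L] <- FIXED_COUNT   # offer B outcome
  mask <- matrix(FALSE, n_out, n_states)
  if (bonus == "novelty") {
    a[2:3, 2L] <- 0.25; a[2:3, 3L] <- 0.25
    mask[2:3, 2:3] <- TRUE
  }
  choose <- function(offer) {
    M <- diag(n_states)
    M[, 1L] <- 0
    M[2L + (offer - 1L) * 2L, 1L] <- 0.5
    M[3L + (offer - 1L) * 2L, 1L] <- 0.5
    M
  }
  wait <- diag(n_states)
  for (s in 2:5) { wait[s, s] <- 0; wait[s + 4L, s] <- 1 }  # delay -> outcome
  c_raw <- c(0, 0, 0, 0, util_per_pellet * m_a, util_per_pellet * m_b, 0)
  generative_model(
    obs = observation_model(a, mask),
    trans = transition_model(list(choose(1L), choose(2L), wait)),
    pref = preference_vector(c_raw),
    d = initial_state_belief(c(1, rep(0, 8L))),
    precisions = precision_params(beta = beta, alpha = alpha),
    policies = policy_set(rbind(c(1L, 3L), c(2L, 3L)), 3L),
    horizon = 3L, eta = 0.5,
    labels = list(
      states = c("start", "Aw", "Al", "Bw", "Bl", "AwF", "AlF", "BwF", "BlF"),
      outcomes = c("start", "signal_win", "signal_lose", "blank",
                   "reward_A", "reward_B", "no_reward"),
      actions = c("choose_A", "choose_B", "wait"),
      informative_action = 1L
    )
  )
}

#' Random small generative model for oracle tests
#'
#' Draws a valid model with mixed learnable and fixed likelihood entries,
#' random stochastic transitions, random preferences and an exhaustive
#' policy set, for cross-checking the policy evaluation against a direct
#' enumeration oracle.
#'
#' @param n_states,n_outcomes Dimensions (at most 4).
#' @param n_actions Number of actions.
#' @param horizon Trial length (2 or 3).
#' @param seed Optional seed for reproducibility.
#' @return An `aimaze_model`.
#' @export
make_tiny_model <- function(n_states = 2L, n_outcomes = 2L, n_actions = 2L,
                            horizon = 2L, seed = NULL) {
  if (n_states > 4L || n_outcomes > 4L) stop("tiny models are at most 4 x 4")
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(stats::runif(n_outcomes * n_states, 0.2, 3), n_outcomes, n_states)
  mask <- matrix(stats::runif(n_outcomes * n_states) < 0.5, n_outcomes, n_states)
  B <- lapply(seq_len(n_actions), function(k) {
    m <- matrix(stats::runif(n_states * n_states, 0.05, 1), n_states, n_states)
    sweep(m, 2L, colSums(m), "/")
  })
  pol <- as.matrix(expand.grid(rep(list(seq_len(n_actions)), horizon - 1L)))
  dimnames(pol) <- NULL
  generative_model(
    obs = observation_model(a, mask),
    trans = transition_model(B),
    pref = preference_vector(stats::rnorm(n_outcomes)),
    d = initial_state_belief(stats::runif(n_states, 0.2, 1)),
    precisions = precision_params(beta = 1, alpha = 4),
    policies = policy_set(pol, n_actions),
    horizon = horizon, eta = 0.5
  )
}

#' Catalog of fixture constructors
#'
#' Named constructors for every model used in tests and simulations,
#' including deliberately invalid objects for exercising [validate_model()].
#'
#' @return Named list of zero-argument constructors.
#' @export
fixture_catalog <- function() {
  list(
    learning_model = function() make_learning_model(),
    inference_model = function() make_inference_model(),
    info_model = function() make_info_model(5, 5),
    tiny_2x2 = function() make_tiny_model(seed = 1L),
    single_policy = function() {
      m <- make_learning_model()
      m$policies <- m$policies[1L, , drop = FALSE]
      m
    },
    broken_transition = function() {
      m <- make_learning_model()
      m$trans$B[[1L]][1L, 1L] <- 0.7  # column no longer sums to 1
      m
    },
    zero_column_counts = function() {
      m <- make_learning_model()
      m$obs$a[, 3L] <- 0
      m
    }
  )
}
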