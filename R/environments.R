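# True generative processes for the three simulated tasks, decoupled from the
# agent's model: the environments hold the true reward statistics and emit
# outcomes given the agent's location and the hidden context; they never see
# the agent's beliefs or counts.

#' T-maze reward-learning environment
#'
#' Three locations (start, safe arm, risky arm). The safe arm always emits a
#' small certain reward; the risky arm emits a high reward with probability
#' `p_high` and no reward otherwise. Outcomes: 1 start, 2 safe-reward,
#' 3 high-reward, 4 no-reward. Actions: 1 go-safe, 2 go-risky.
#'
#' @param p_high True probability of the high reward at the risky arm.
#' @return Environment object of class `aimaze_env`.
#' @export
tmaze_learning_env <- function(p_high = 0.5) {
  if (p_high < 0 || p_high > 1) stop("p_high must be in [0, 1]")
  structure(list(type = "learning", p_high = p_high, location = 1L),
            class = "aimaze_env")
}

#' T-maze context-inference environment
#'
#' Four locations (start, cue, safe arm, risky arm) crossed with a hidden
#' context that sets the risky arm's reward probability to `p_high` (high
#' context) or `p_low` (low context). The cue deterministically signals the
#' current context. Under the "random" schedule the context is redrawn
#' uniformly at every trial; under "stable" it is fixed. Outcomes: 1 start,
#' 2 cue-signals-high, 3 cue-signals-low, 4 safe-reward, 5 high-reward,
#' 6 no-reward, 7 unused. Actions: 1 stay, 2 go-cue, 3 go-safe, 4 go-risky;
#' the arms are absorbing within a trial and the cue is reachable only from
#' the start.
#'
#' @param schedule "random" (per-trial context) or "stable".
#' @param p_high,p_low Risky-arm reward probabilities in the two contexts.
#' @param stable_context Context used under the stable schedule ("high" or
#'   "low").
#' @return Environment object of class `aimaze_env`.
#' @export
tmaze_inference_env <- function(schedule = c("random", "stable"),
                                p_high = 0.75, p_low = 0.25,
                                stable_context = c("high", "low")) {
  schedule <- match.arg(schedule)
  stable_context <- match.arg(stable_context)
  structure(list(type = "inference", schedule = schedule,
                 p_high = p_high, p_low = p_low,
                 stable_context = stable_context,
                 context = if (stable_context == "high") 1L else 2L,
                 location = 1L, risky_outcome = NA_integer_),
            class = "aimaze_env")
}

#' Non-instrumental information-preference environment
#'
#' Two offers with equal reward probability 0.5 and pellet amounts `m_a` and
#' `m_b`. Offer A carries a pre-outcome signal that reveals the upcoming
#' reward identity during the delay; offer B shows a blank. The signal has no
#' effect on the reward statistics. Outcomes: 1 start, 2 signal-win,
#' 3 signal-lose, 4 blank, 5 reward-A, 6 reward-B, 7 no-reward. Actions:
#' 1 choose-A, 2 choose-B, 3 wait.
#'
#' @param m_a,m_b Pellet amounts of the two offers (0..10).
#' @return Environment object of class `aimaze_env`.
#' @export
info_preference_env <- function(m_a, m_b) {
  if (m_a < 0 || m_b < 0) stop("offer amounts must be non-negative")
  structure(list(type = "info", m_a = m_a, m_b = m_b,
                 location = 1L, offer = NA_integer_, win = NA),
            class = "aimaze_env")
}

#' Reset an environment at the start of a trial
#'
#' Draws the hidden context per the environment's schedule (uniformly per
#' trial under the random schedule, fixed under the stable schedule) and
#' returns the agent to the start location. Uses the current RNG state.
#'
#' @param env An `aimaze_env`.
#' @return The reset environment.
#' @export
env_reset <- function(env) {
  env$location <- 1L
  if (env$type == "inference") {
    env$context <- if (env$schedule == "random") {
      sample.int(2L, 1L)
    } else if (env$stable_context == "high") 1L else 2L
    env$risky_outcome <- NA_integer_
  } else if (env$type == "info") {
    env$offer <- NA_integer_
    env$win <- NA
  }
  env
}

#' Outcome observed at the start location before any action
#'
#' @param env A reset `aimaze_env`.
#' @return Outcome index (always the start observation).
#' @export
env_initial_outcome <- function(env) 1L

#' Advance the environment by one agent action
#'
#' Moves the agent and draws the outcome from the true emission distribution
#' of the resulting location and hidden context. Arms are absorbing and
#' their reward is drawn once per trial (the arm either holds a pellet this
#' trial or not): re-observing an arm repeats the same outcome and yields no
#' further pellets. Uses the current RNG state.
#'
#' @param env An `aimaze_env`.
#' @param action Action index (see the environment constructors).
#' @return List with the updated `env`, the `outcome` index, the new
#'   `location`, and the `pellets` collected at this step (rewards are
#'   collected once, on first arm entry).
#' @export
env_step <- function(env, action) {
  collected <- NA  # NA: use pellet_value of the outcome
  if (env$type == "learning") {
    if (!action %in% 1:2) stop("invalid action")
    env$location <- action + 1L  # 2 safe, 3 risky
    outcome <- if (action == 1L) 2L else if (stats::runif(1) < env$p_high) 3L else 4L
  } else if (env$type == "inference") {
    if (!action %in% 1:4) stop("invalid action")
    loc <- env$location
    entered_arm <- FALSE
    if (loc %in% 3:4) {
      # arms are absorbing
    } else if (action == 2L && loc != 1L) {
      stop("the cue is reachable only from the start location")
    } else if (action > 1L) {
      loc <- action
      entered_arm <- loc %in% 3:4
    }
    env$location <- loc
    outcome <- switch(loc,
      1L,                                       # start
      if (env$context == 1L) 2L else 3L,        # cue signals the context
      4L,                                       # safe reward
      {                                         # risky arm, drawn once per trial
        if (is.na(env$risky_outcome)) {
          p <- if (env$context == 1L) env$p_high else env$p_low
          env$risky_outcome <- if (stats::runif(1) < p) 5L else 6L
        }
        env$risky_outcome
      })
    if (!entered_arm) collected <- 0
  } else {
    if (!action %in% 1:3) stop("invalid action")
    if (env$location == 1L && action %in% 1:2) {
      env$offer <- action
      env$win <- stats::runif(1) < 0.5
      env$location <- 2L  # delay period
      outcome <- if (env$offer == 1L) (if (env$win) 2L else 3L) else 4L
    } else if (env$location == 2L) {
      env$location <- 3L  # outcome period
      outcome <- if (env$win) (if (env$offer == 1L) 5L else 6L) else 7L
    } else {
      outcome <- 1L  # waiting at the start
    }
  }
  if (is.na(collected)) collected <- pellet_value(env, outcome)
  list(env = env, outcome = outcome, location = env$location, pellets = collected)
}

#' Pellet value of an outcome
#'
#' A small safe reward is one pellet and a high reward four pellets; in the
#' information-preference task the reward outcomes are worth the offer's
#' pellet amount. All other outcomes are worth nothing.
#'
#' @param env An `aimaze_env`.
#' @param outcome Outcome index.
#' @return Non-negative pellet count.
#' @export
pellet_value <- function(env, outcome) {
  if (env$type == "learning") {
    c(0, 1, 4, 0)[outcome]
  } else if (env$type == "inference") {
    c(0, 0, 0, 1, 4, 0, 0)[outcome]
  } else {
    if (outcome == 5L) env$m_a else if (outcome == 6L) env$m_b else 0
  }
}
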