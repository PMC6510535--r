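# Agent factory, trial and experiment runners, and batch statistics.

#' Agent configuration
#'
#' The agent kind fixes the ablation flags: "full" uses novelty, salience and
#' utility; "parameter_explorer" (active learning) novelty and utility;
#' "state_explorer" (active inference) salience and utility;
#' "random" utility only. Goal-directed kinds default to action precision 8
#' and the random kind to 1, the values used when comparing agents; the
#' single-task simulations use 4 (learning maze) and 16 (inference maze).
#' The state explorer runs without observation-model learning (it relies on
#' inference, not parameter updates).
#'
#' @param kind One of "full", "parameter_explorer", "state_explorer",
#'   "random".
#' @param beta Policy-precision rate parameter (expected precision `1/beta`).
#' @param alpha Action precision; `NULL` picks the kind's comparison default.
#' @param eta Learning rate.
#' @param learn_a Update observation counts from experience (`NULL`: all
#'   kinds except the state explorer).
#' @param learn_d Update the initial-state prior across trials.
#' @return List of class `aimaze_agent_config`.
#' @export
agent_config <- function(kind = c("full", "parameter_explorer", "state_explorer", "random"),
                         beta = 1, alpha = NULL, eta = 0.5,
                         learn_a = NULL, learn_d = FALSE) {
  kind <- match.arg(kind)
  flags <- switch(kind,
    full = ablation_flags(TRUE, TRUE),
    parameter_explorer = ablation_flags(TRUE, FALSE),
    state_explorer = ablation_flags(FALSE, TRUE),
    random = ablation_flags(FALSE, FALSE))
  if (is.null(alpha)) alpha <- if (kind == "random") 1 else 8
  if (is.null(learn_a)) learn_a <- kind != "state_explorer"
  structure(list(kind = kind, flags = flags, beta = beta, alpha = alpha,
                 eta = eta, learn_a = learn_a, learn_d = learn_d),
            class = "aimaze_agent_config")
}

#' Build an agent from a generative model and a configuration
#'
#' @param model An `aimaze_model`.
#' @param config An [agent_config()]; `NULL` keeps the model's own precisions
#'   and runs the full agent.
#' @return List of class `aimaze_agent` holding the (mutable) model, ablation
#'   flags, learning switches, `gamma` and `alpha`.
#' @export
build_agent <- function(model, config = NULL) {
  if (is.null(config)) {
    return(structure(list(model = model, flags = ablation_flags(),
                          learn_a = TRUE, learn_d = FALSE,
                          gamma = model$precisions$gamma,
                          alpha = model$precisions$alpha,
                          kind = "full"),
                     class = "aimaze_agent"))
  }
  model$precisions <- precision_params(beta = config$beta, alpha = config$alpha)
  model$eta <- config$eta
  structure(list(model = model, flags = config$flags,
                 learn_a = config$learn_a, learn_d = config$learn_d,
                 gamma = model$precisions$gamma, alpha = model$precisions$alpha,
                 kind = config$kind),
            class = "aimaze_agent")
}

# Posterior over the trial's initial state given everything observed: for
# models with a static factor (the context), the final filtered marginal of
# that factor applies to the start of the trial; otherwise fall back to the
# first filtered belief.
initial_state_posterior <- function(model, final_belief, first_belief) {
  sf <- model$state_factors
  if (is.null(sf) || is.null(sf$static)) return(first_belief)
  ctx <- sf[[sf$static]]
  ctx_post <- vapply(sort(unique(ctx)), function(k) sum(final_belief[ctx == k]), numeric(1))
  s1 <- numeric(length(final_belief))
  start_states <- which(sf$location == sf$start_location)
  s1[start_states] <- ctx_post[ctx[start_states]]
  normalise(s1)
}

#' Run a single trial
#'
#' The agent starts from its initial-state prior, observes the start outcome,
#' and then, at every timestep, re-evaluates the expected free energy of all
#' policies consistent with its past actions given its current beliefs,
#' forms the policy posterior, samples an action under precision `alpha`,
#' observes the environment's outcome, and performs a Bayesian belief update.
#' Dirichlet learning of observation counts and (optionally) of the
#' initial-state prior is applied at the end of the trial.
#'
#' @param agent An `aimaze_agent` (from [build_agent()]).
#' @param env An `aimaze_env`.
#' @param record_ledger Keep the first-step policy-evaluation table.
#' @return List with the updated `agent`, `env`, and a `record` containing
#'   actions, outcomes, locations, pellets, the first-step policy posterior
#'   and action distribution, and optionally the evaluation ledger. Uses the
#'   current RNG state.
#' @export
run_trial <- function(agent, env, record_ledger = FALSE) {
  model <- agent$model
  cache <- efe_cache(model)
  lnA <- expected_log_likelihood(model$obs$a)
  env <- env_reset(env)
  horizon <- model$horizon
  belief <- model$d$counts / sum(model$d$counts)
  o1 <- env_initial_outcome(env)
  belief <- bayes_update(belief, lnA, o1)
  first_belief <- belief
  outcomes <- integer(horizon); outcomes[1L] <- o1
  actions <- integer(horizon - 1L)
  locations <- integer(horizon); locations[1L] <- env$location
  active <- rep(TRUE, nrow(model$policies))
  pellets <- 0
  q1 <- NULL; p_action1 <- NULL; ledger <- NULL
  updates <- vector("list", horizon - 1L)
  for (t in seq_len(horizon - 1L)) {
    idx <- which(active)
    ev <- evaluate_policies(model, belief, idx, agent$flags, t, cache)
    q <- policy_posterior(ev$G, agent$gamma)
    pa <- action_marginal(q, model$policies[idx, , drop = FALSE], t, model$trans$n_actions)
    sel <- select_action(pa, agent$alpha)
    if (t == 1L) {
      q1 <- numeric(nrow(model$policies))
      q1[idx] <- q
      p_action1 <- sel$prob
      if (record_ledger) ledger <- ev$ledger
    }
    act <- sel$action
    step <- env_step(env, act)
    env <- step$env
    actions[t] <- act
    outcomes[t + 1L] <- step$outcome
    locations[t + 1L] <- step$location
    pellets <- pellets + step$pellets
    belief <- bayes_update(predict_states(belief, model$trans, act), lnA, step$outcome)
    active <- active & (model$policies[, t] == act)
    updates[[t]] <- list(o = step$outcome, s = belief)
  }
  if (agent$learn_a && model$eta > 0 && any(model$obs$learnable)) {
    for (u in updates) {
      model$obs <- update_observation_counts(model$obs, u$o, u$s, model$eta)
    }
  }
  if (agent$learn_d && model$eta_d > 0) {
    s1 <- initial_state_posterior(model, belief, first_belief)
    model$d$counts <- update_initial_counts(model$d$counts, s1, model$eta_d)
    model$d$prob <- model$d$counts / sum(model$d$counts)
  }
  agent$model <- model
  list(agent = agent, env = env,
       record = list(actions = actions, outcomes = outcomes,
                     locations = locations, pellets = pellets,
                     q_policy = q1, p_action = p_action1,
                     final_belief = belief, ledger = ledger))
}

#' Run a sequential experiment of many trials
#'
#' Counts persist across trials; the environment is reset (context redrawn
#' per its schedule) at every trial.
#'
#' @param agent An `aimaze_agent`.
#' @param env An `aimaze_env`.
#' @param n_trials Number of trials.
#' @param seed Optional seed (set once before the first trial).
#' @return Object of class `aimaze_experiment`: a per-trial data frame
#'   `trials` (first action, final location, final outcome, pellets,
#'   cumulative pellets, risky / cue-first indicators, learnable-count and
#'   context-prior snapshots at trial start) plus the per-trial first-step
#'   action distributions and the final agent.
#' @export
run_experiment <- function(agent, env, n_trials = 32L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- agent$model
  lab <- model$labels
  risky_action <- if (!is.null(lab$risky_action)) lab$risky_action else NA_integer_
  cue_action <- if (!is.null(lab$cue_action)) lab$cue_action else NA_integer_
  n_act <- model$trans$n_actions
  first_action <- integer(n_trials); final_outcome <- integer(n_trials)
  pellets <- numeric(n_trials); chose_risky <- logical(n_trials)
  cue_first <- logical(n_trials)
  a_high <- rep(NA_real_, n_trials); a_no <- rep(NA_real_, n_trials)
  p_act <- matrix(NA_real_, n_trials, n_act)
  for (i in seq_len(n_trials)) {
    m <- agent$model
    if (!is.null(lab$high_outcome) && !is.null(lab$risky_state)) {
      a_high[i] <- m$obs$a[lab$high_outcome, lab$risky_state]
      a_no[i] <- m$obs$a[lab$noreward_outcome, lab$risky_state]
    }
    out <- run_trial(agent, env)
    agent <- out$agent; env <- out$env
    r <- out$record
    first_action[i] <- r$actions[1L]
    final_outcome[i] <- r$outcomes[length(r$outcomes)]
    pellets[i] <- r$pellets
    chose_risky[i] <- if (!is.na(risky_action)) {
      any(r$actions == risky_action)
    } else NA
    cue_first[i] <- if (!is.na(cue_action)) first_action[i] == cue_action else NA
    p_act[i, ] <- r$p_action
  }
  trials <- data.frame(
    trial = seq_len(n_trials), first_action = first_action,
    final_outcome = final_outcome, pellets = pellets,
    cum_pellets = cumsum(pellets), chose_risky = chose_risky,
    cue_first = cue_first, a_high = a_high, a_no = a_no
  )
  structure(list(trials = trials, p_action = p_act, agent = agent, env = env,
                 seed = seed),
            class = "aimaze_experiment")
}

#' @export
print.aimaze_experiment <- function(x, ...) {
  n <- nrow(x$trials)
  cat(sprintf("aimaze experiment: %d trials, %g pellets total\n",
              n, sum(x$trials$pellets)))
  if (!all(is.na(x$trials$chose_risky))) {
    cat(sprintf("  risky-arm choice rate: %.3f\n", mean(x$trials$chose_risky)))
  }
  if (!all(is.na(x$trials$cue_first))) {
    cat(sprintf("  cue-first rate: %.3f\n", mean(x$trials$cue_first)))
  }
  invisible(x)
}

#' Task configuration for batch runs
#'
#' @param task "learning", "inference" or "info".
#' @param ... Arguments passed to the task's model and environment
#'   constructors: `p_high`, `p_low`, `schedule`, `stable_context`,
#'   `learnable_risky`, `alpha`, `m_a`, `m_b`.
#' @return List of class `aimaze_task_config`.
#' @export
task_config <- function(task = c("learning", "inference", "info"), ...) {
  task <- match.arg(task)
  structure(list(task = task, args = list(...)), class = "aimaze_task_config")
}

build_task <- function(task_cfg, agent_cfg) {
  a <- task_cfg$args
  if (task_cfg$task == "learning") {
    model <- make_learning_model(
      a0_risky = a$a0_risky %||% 0.25, eta = agent_cfg$eta,
      beta = agent_cfg$beta, alpha = agent_cfg$alpha)
    env <- tmaze_learning_env(p_high = a$p_high %||% 0.5)
  } else if (task_cfg$task == "inference") {
    model <- make_inference_model(
      p_high = a$p_high %||% 0.75, p_low = a$p_low %||% 0.25,
      learnable_risky = a$learnable_risky %||%
        (agent_cfg$kind %in% c("parameter_explorer", "random")),
      eta = agent_cfg$eta, beta = agent_cfg$beta, alpha = agent_cfg$alpha)
    env <- tmaze_inference_env(
      schedule = a$schedule %||% "random",
      p_high = a$p_high %||% 0.75, p_low = a$p_low %||% 0.25,
      stable_context = a$stable_context %||% "high")
  } else {
    model <- make_info_model(m_a = a$m_a %||% 5, m_b = a$m_b %||% 5,
                             beta = agent_cfg$beta, alpha = agent_cfg$alpha)
    env <- info_preference_env(m_a = a$m_a %||% 5, m_b = a$m_b %||% 5)
  }
  list(agent = build_agent(model, agent_cfg), env = env)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run a batch of independent experiments and aggregate
#'
#' Each experiment rebuilds the agent and environment from the
#' configurations (fresh counts) and runs with its own derived seed, so the
#' batch is fully reproducible from `seed`.
#'
#' @param agent_cfg An [agent_config()].
#' @param task_cfg A [task_config()].
#' @param n_experiments Number of independent experiments.
#' @param n_trials Trials per experiment.
#' @param seed Master seed.
#' @return Object of class `aimaze_batch` with per-trial choice-rate curves
#'   (`risky_by_trial`, `cue_first_by_trial`), the mean and standard
#'   deviation of cumulative pellets, a concentration-binned risky-choice
#'   table (`heatmap`, learning task), and the totals per experiment.
#' @export
run_batch <- function(agent_cfg, task_cfg, n_experiments = 100L, n_trials = 32L,
                      seed = 1L) {
  set.seed(seed)
  exp_seeds <- sample.int(2147483646L, n_experiments)
  risky <- matrix(NA, n_experiments, n_trials)
  cue <- matrix(NA, n_experiments, n_trials)
  cum <- matrix(0, n_experiments, n_trials)
  ah <- matrix(NA_real_, n_experiments, n_trials)
  an <- matrix(NA_real_, n_experiments, n_trials)
  for (e in seq_len(n_experiments)) {
    parts <- build_task(task_cfg, agent_cfg)
    res <- run_experiment(parts$agent, parts$env, n_trials = n_trials,
                          seed = exp_seeds[e])
    risky[e, ] <- res$trials$chose_risky
    cue[e, ] <- res$trials$cue_first
    cum[e, ] <- res$trials$cum_pellets
    ah[e, ] <- res$trials$a_high
    an[e, ] <- res$trials$a_no
  }
  heatmap <- NULL
  if (!all(is.na(ah))) {
    df <- data.frame(a_high = as.vector(ah), a_no = as.vector(an),
                     risky = as.vector(risky))
    agg <- stats::aggregate(risky ~ a_high + a_no, data = df,
                            FUN = function(x) c(p = mean(x), n = length(x)))
    heatmap <- data.frame(a_high = agg$a_high, a_no = agg$a_no,
                          p_risky = agg$risky[, "p"], n = agg$risky[, "n"])
  }
  structure(list(
    risky_by_trial = colMeans(risky),
    cue_first_by_trial = colMeans(cue),
    cum_pellets_mean = colMeans(cum),
    cum_pellets_sd = apply(cum, 2L, stats::sd),
    total_pellets = cum[, n_trials],
    heatmap = heatmap,
    n_experiments = n_experiments, n_trials = n_trials, seed = seed
  ), class = "aimaze_batch")
}

#' @export
print.aimaze_batch <- function(x, ...) {
  cat(sprintf("aimaze batch: %d experiments x %d trials\n",
              x$n_experiments, x$n_trials))
  cat(sprintf("  mean total pellets: %.2f (sd %.2f)\n",
              mean(x$total_pellets), stats::sd(x$total_pellets)))
  if (!all(is.na(x$risky_by_trial))) {
    cat(sprintf("  risky choice rate, first/last trial: %.3f / %.3f\n",
                x$risky_by_trial[1L], x$risky_by_trial[x$n_trials]))
  }
  if (!all(is.na(x$cue_first_by_trial))) {
    cat(sprintf("  cue-first rate (mean over trials): %.3f\n",
                mean(x$cue_first_by_trial)))
  }
  invisible(x)
}

info_beta <- function(schedule, m_a, m_b) {
  if (schedule == "constant") 1 else 2^(1 - (m_a + m_b) / 10)
}

#' Preference for the informative offer across reward amounts
#'
#' Sweeps both offers' pellet amounts and reports, per cell, the probability
#' that the agent's first action selects the informative offer. Under the
#' "constant" precision schedule the preference is constant along the
#' equal-amount diagonal; under "offer_dependent" the policy precision rises
#' with the total offered amount (`log2 beta` interpolated linearly from 1
#' at 0 pellets total to -1 at 20 pellets total), so the information
#' preference grows with reward size.
#'
#' @param beta_schedule "constant" or "offer_dependent".
#' @param amounts Vector of pellet amounts to cross (default 0..10).
#' @param n_reps `Inf` (default) returns the exact first-action probability;
#'   a finite value estimates it from that many simulated trials per cell.
#' @param seed Seed used when `n_reps` is finite.
#' @param bonus Information-bonus mechanism, see [make_info_model()];
#'   "none" ablates the bonus entirely.
#' @return Matrix (amount A x amount B) of informative-offer preferences,
#'   with amounts as dimnames.
#' @export
run_info_preference_sweep <- function(beta_schedule = c("constant", "offer_dependent"),
                                      amounts = 0:10, n_reps = Inf, seed = NULL,
                                      bonus = c("salience", "novelty", "none")) {
  beta_schedule <- match.arg(beta_schedule)
  bonus <- match.arg(bonus)
  if (!is.null(seed)) set.seed(seed)
  pref <- matrix(NA_real_, length(amounts), length(amounts),
                 dimnames = list(A = amounts, B = amounts))
  for (i in seq_along(amounts)) for (j in seq_along(amounts)) {
    m_a <- amounts[i]; m_b <- amounts[j]
    beta <- info_beta(beta_schedule, m_a, m_b)
    model <- make_info_model(m_a, m_b, beta = beta,
                             bonus = if (bonus == "none") "salience" else bonus)
    flags <- switch(bonus,
      salience = ablation_flags(FALSE, TRUE),
      novelty = ablation_flags(TRUE, FALSE),
      none = ablation_flags(FALSE, FALSE))
    cache <- efe_cache(model)
    belief <- model$d$prob
    ev <- evaluate_policies(model, belief, flags = flags, t = 1L, cache = cache)
    q <- policy_posterior(ev$G, model$precisions$gamma)
    pa <- action_marginal(q, model$policies, 1L, model$trans$n_actions)
    support <- pa > 0
    p_sel <- numeric(length(pa))
    p_sel[support] <- softmax(model$precisions$alpha * log(pa[support]))
    p_info <- p_sel[model$labels$informative_action]
    if (is.finite(n_reps)) {
      p_info <- mean(stats::runif(n_reps) < p_info)
    }
    pref[i, j] <- p_info
  }
  pref
}
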