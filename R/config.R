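# Loss-free round trip of a generative model through a YAML key-value config.

#' Write a generative model to a YAML config file
#'
#' All matrices are stored as nested lists (row-major), policies as
#' action-index lists. The round trip through [read_model_config()] is
#' loss-free up to floating-point text precision.
#'
#' @param model An `aimaze_model`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  cfg <- list(
    a = apply(model$obs$a, 1L, as.list, simplify = FALSE),
    a0 = apply(model$obs$a0, 1L, as.list, simplify = FALSE),
    learnable = apply(model$obs$learnable, 1L, as.list, simplify = FALSE),
    B = lapply(model$trans$B, function(m) apply(m, 1L, as.list, simplify = FALSE)),
    c_raw = as.list(model$pref$raw),
    d_counts = as.list(model$d$counts),
    d_counts0 = as.list(model$d$counts0),
    beta = model$precisions$beta,
    alpha = model$precisions$alpha,
    policies = apply(model$policies, 1L, as.list, simplify = FALSE),
    horizon = model$horizon,
    eta = model$eta,
    eta_d = model$eta_d,
    pref_timing = model$pref_timing,
    state_factors = model$state_factors,
    labels = model$labels
  )
  writeLines(yaml::as.yaml(cfg, precision = 15L), path)
  invisible(path)
}

row_major <- function(rows) do.call(rbind, lapply(rows, function(r) unlist(r)))

#' Read a generative model from a YAML config file
#'
#' @param path File written by [write_model_config()].
#' @return An `aimaze_model`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  a <- row_major(cfg$a)
  obs <- observation_model(a, learnable = row_major(cfg$learnable) > 0)
  obs$a <- a          # preserve accumulated counts, not just priors
  obs$a0 <- row_major(cfg$a0)
  d <- initial_state_belief(unlist(cfg$d_counts0))
  d$counts <- unlist(cfg$d_counts)
  d$prob <- d$counts / sum(d$counts)
  trans <- transition_model(lapply(cfg$B, row_major))
  pol <- policy_set(lapply(cfg$policies, unlist), trans$n_actions)
  generative_model(
    obs = obs, trans = trans, pref = preference_vector(unlist(cfg$c_raw)), d = d,
    precisions = precision_params(beta = cfg$beta, alpha = cfg$alpha),
    policies = pol, horizon = cfg$horizon, eta = cfg$eta, eta_d = cfg$eta_d,
    pref_timing = cfg$pref_timing,
    state_factors = cfg$state_factors,
    labels = cfg$labels
  )
}
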