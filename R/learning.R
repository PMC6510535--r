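# Experience-dependent Dirichlet updates: counts accumulate as
# a <- a + eta * (outcome indicator) %o% (state posterior), restricted to the
# learnable entries, and analogously for the initial-state prior d.

#' Update observation-model counts after an observation
#'
#' Adds `eta * s_post[s]` to `a[o, s]` on learnable entries; all other
#' entries are unchanged. The total learnable increment per observation is
#' `eta` whenever the state posterior's mass lies on learnable columns.
#'
#' @param obs An [observation_model()] (or a plain counts matrix, in which
#'   case `learnable` must be given).
#' @param o Observed outcome index.
#' @param s_post State posterior at the time of the observation.
#' @param eta Positive learning rate (0 disables learning).
#' @param learnable Logical mask when `obs` is a plain matrix.
#' @return The updated object, same type as `obs`.
#' @export
update_observation_counts <- function(obs, o, s_post, eta, learnable = NULL) {
  plain <- !inherits(obs, "aimaze_obs")
  a <- if (plain) as.matrix(obs) else obs$a
  mask <- if (plain) as.matrix(learnable) else obs$learnable
  if (is.null(mask)) stop("a learnable mask is required")
  if (o < 1L || o > nrow(a)) stop("invalid outcome index")
  if (length(s_post) != ncol(a)) stop("state posterior does not match the state dimension")
  if (eta < 0) stop("eta must be non-negative")
  assert_prob(s_post, "state posterior")
  inc <- which(mask[o, ] & s_post > 0)
  if (length(inc)) a[o, inc] <- a[o, inc] + eta * s_post[inc]
  if (plain) return(a)
  obs$a <- a
  obs
}

#' Update initial-state prior counts at the end of a trial
#'
#' `d <- d + eta * s1_post`, where `s1_post` is the posterior belief about the
#' trial's initial state given everything observed in the trial. Subsequent
#' trials start from the normalised updated counts.
#'
#' @param d_counts Numeric vector of initial-state concentration parameters.
#' @param s1_post Posterior over the initial state.
#' @param eta Non-negative learning rate.
#' @return Updated counts vector.
#' @export
update_initial_counts <- function(d_counts, s1_post, eta) {
  if (length(s1_post) != length(d_counts)) stop("posterior does not match the state dimension")
  if (eta < 0) stop("eta must be non-negative")
  assert_prob(s1_post, "initial-state posterior")
  d_counts + eta * s1_post
}
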