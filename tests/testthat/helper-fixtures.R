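normalise_for_test <- function(x) x / sum(x)

softmax_for_test <- function(x) exp(x) / sum(exp(x))

# agent + environment pair for a task, built fresh
make_pair <- function(kind, task, ..., beta = 1, alpha = NULL, eta = 0.5,
                      learn_d = FALSE) {
  cfg <- agent_config(kind, beta = beta, alpha = alpha, eta = eta, learn_d = learn_d)
  tsk <- task_config(task, ...)
  # build via the exported batch plumbing: one-off experiment components
  parts <- aimaze:::build_task(tsk, cfg)
  parts
}
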