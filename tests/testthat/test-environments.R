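test_that("context schedules behave as declared and are seed-reproducible", {
  env <- tmaze_inference_env("stable", stable_context = "low")
  ctx <- replicate(20, { env <<- env_reset(env); env$context })
  expect_true(all(ctx == 2L))
  set.seed(123)
  env <- tmaze_inference_env("random")
  ctx <- replicate(1e4, { env <<- env_reset(env); env$context })
  expect_lt(abs(mean(ctx == 1L) - 0.5), 0.02)
  set.seed(55); seq1 <- replicate(50, { env <<- env_reset(env); env$context })
  set.seed(55); seq2 <- replicate(50, { env <<- env_reset(env); env$context })
  expect_identical(seq1, seq2)
})

test_that("emissions follow the true reward statistics", {
  # the safe arm is deterministic
  env <- env_reset(tmaze_learning_env(0.5))
  expect_true(all(replicate(20, env_step(env, 1L)$outcome) == 2L))
  # the risky arm matches its programmed probability
  set.seed(2)
  env <- tmaze_learning_env(0.75)
  outs <- replicate(1e4, { env <<- env_reset(env); env_step(env, 2L)$outcome })
  expect_lt(abs(mean(outs == 3L) - 0.75), 0.02)
  # the cue deterministically signals the context
  env <- env_reset(tmaze_inference_env("stable", stable_context = "high"))
  expect_equal(env_step(env, 2L)$outcome, 2L)
  env <- env_reset(tmaze_inference_env("stable", stable_context = "low"))
  expect_equal(env_step(env, 2L)$outcome, 3L)
})

test_that("arms are absorbing and the cue is reachable only as a first move", {
  set.seed(4)
  env <- env_reset(tmaze_inference_env("stable", stable_context = "high"))
  s1 <- env_step(env, 4L)   # enter the risky arm
  s2 <- env_step(s1$env, 3L)  # any further action keeps the arm
  expect_equal(s2$location, 4L)
  expect_equal(s2$outcome, s1$outcome)  # the trial's draw is repeated
  expect_equal(s2$pellets, 0)           # ...but not re-collected
  expect_error(env_step(env_step(env, 2L)$env, 2L), "reachable only")
})

test_that("pellet values price small and large rewards as one and four", {
  env <- tmaze_learning_env(0.5)
  expect_equal(pellet_value(env, 2L), 1)
  expect_equal(pellet_value(env, 3L), 4)
  expect_equal(pellet_value(env, 1L), 0)
  envi <- tmaze_inference_env()
  expect_equal(pellet_value(envi, 4L), 1)
  expect_equal(pellet_value(envi, 5L), 4)
  expect_equal(pellet_value(envi, 2L), 0)
  envp <- info_preference_env(7, 3)
  expect_equal(pellet_value(envp, 5L), 7)
  expect_equal(pellet_value(envp, 6L), 3)
  expect_equal(pellet_value(envp, 7L), 0)
})

test_that("environment draws never depend on the agent's beliefs", {
  # identical seeds and actions yield identical outcome streams whatever the
  # agent's counts look like (the environment API receives no agent state)
  run_stream <- function() {
    set.seed(77)
    env <- tmaze_inference_env("random")
    outs <- integer(0)
    for (i in 1:10) {
      env <- env_reset(env)
      s <- env_step(env, 2L); env <- s$env; outs <- c(outs, s$outcome)
      s <- env_step(env, 4L); env <- s$env; outs <- c(outs, s$outcome)
    }
    outs
  }
  expect_identical(run_stream(), run_stream())
})

test_that("the information task reveals the outcome only for the informative offer", {
  set.seed(9)
  env <- env_reset(info_preference_env(5, 5))
  s1 <- env_step(env, 1L)  # choose the informative offer
  expect_true(s1$outcome %in% 2:3)
  s2 <- env_step(s1$env, 3L)
  expect_true(s2$outcome %in% c(5L, 7L))
  # the signal matches the later outcome
  expect_equal(s1$outcome == 2L, s2$outcome == 5L)
  env <- env_reset(info_preference_env(5, 5))
  b1 <- env_step(env, 2L)
  expect_equal(b1$outcome, 4L)  # blank delay
  # signal presence does not change reward statistics
  set.seed(10)
  win_a <- mean(replicate(4000, {
    e <- env_reset(info_preference_env(1, 1)); e <- env_step(e, 1L)$env
    env_step(e, 3L)$outcome == 5L
  }))
  win_b <- mean(replicate(4000, {
    e <- env_reset(info_preference_env(1, 1)); e <- env_step(e, 2L)$env
    env_step(e, 3L)$outcome == 6L
  }))
  expect_lt(abs(win_a - 0.5), 0.03)
  expect_lt(abs(win_b - 0.5), 0.03)
})
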