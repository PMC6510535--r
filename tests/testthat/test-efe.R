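test_that("predicted outcomes follow the expected likelihood", {
  A <- diag(3)
  expect_equal(predictive_outcome(c(0, 1, 0), A), c(0, 1, 0))
  A_bal <- matrix(1 / 4, 4, 4)
  expect_equal(predictive_outcome(rep(0.25, 4), A_bal), rep(0.25, 4))
  # risky-arm state of the learning maze maps to a 50/50 reward prediction
  m <- make_learning_model()
  ob <- predictive_outcome(c(0, 0, 1), expected_likelihood(m$obs$a))
  expect_equal(ob[3], 0.5, tolerance = 1e-10)
  expect_equal(ob[4], 0.5, tolerance = 1e-10)
})

test_that("salience is the mutual information between states and outcomes", {
  expect_equal(salience(c(0.5, 0.5), diag(2)), log(2), tolerance = 1e-12)
  # an uninformative channel has zero salience for any belief
  A_flat <- matrix(c(0.3, 0.7, 0.3, 0.7), 2, 2)
  for (p in c(0, 0.25, 0.8, 1)) {
    expect_equal(salience(c(p, 1 - p), A_flat), 0, tolerance = 1e-12)
  }
  # the cue recovers the full context entropy under a uniform context belief
  m <- make_inference_model()
  Abar <- expected_likelihood(m$obs$a)
  b <- numeric(8); b[2] <- 0.5; b[6] <- 0.5  # at the cue, contexts uniform
  mi <- salience(b, Abar)
  # independent direct MI evaluation over the joint distribution
  joint <- sweep(Abar, 2, b, "*")
  po <- rowSums(joint); ps <- b
  mi_direct <- 0
  for (o in which(po > 0)) for (s in which(ps > 0)) {
    if (joint[o, s] > 0) mi_direct <- mi_direct + joint[o, s] * log(joint[o, s] / (po[o] * ps[s]))
  }
  expect_equal(mi, mi_direct, tolerance = 1e-10)
  expect_equal(mi, log(2), tolerance = 1e-6)
})

test_that("novelty follows the inverse-count weights and vanishes for known models", {
  m <- make_learning_model()
  a <- m$obs$a; mask <- m$obs$learnable
  s_bar <- c(0, 0, 1)
  o_bar <- predictive_outcome(s_bar, expected_likelihood(a))
  expect_equal(novelty(s_bar, o_bar, a, mask), 1, tolerance = 1e-6)
  W <- novelty_weights(a, mask)
  expect_equal(W[3, 3], 0.5 * (1 / 0.25 - 1 / sum(a[, 3])), tolerance = 1e-10)
  # counts -> infinity: no further information gain
  a_big <- a; a_big[3:4, 3] <- 1e8
  expect_lt(novelty(s_bar, o_bar, a_big, mask), 1e-7)
  # a state without learnable entries contributes nothing
  expect_equal(novelty(c(0, 1, 0), predictive_outcome(c(0, 1, 0), expected_likelihood(a)), a, mask),
               0, tolerance = 1e-9)
})

test_that("the inverse-count weight agrees with the exact Dirichlet gain in sign, order and limit", {
  cols <- list(c(0.25, 0.25), c(0.75, 0.75), c(2.75, 2.75), c(30, 30), c(1, 3))
  approx_gain <- vapply(cols, function(col) {
    p <- col / sum(col)
    W <- 0.5 * (1 / col - 1 / sum(col))
    sum(p * W)
  }, numeric(1))
  exact_gain <- vapply(cols, exact_column_info_gain, numeric(1))
  expect_true(all(exact_gain > 0))
  expect_true(all(approx_gain > 0))
  # the same ordering over count scales
  expect_equal(order(approx_gain[1:4]), order(exact_gain[1:4]))
  # both vanish for concentrated counts
  expect_lt(exact_column_info_gain(c(1e5, 1e5)), 1e-4)
  expect_lt(approx_gain[4], exact_gain[1])
})

test_that("expected utility is the preference-weighted outcome prediction", {
  cl <- log_preferences(c(0, 2, 4, -2))
  expect_equal(round(expected_utility(c(0, 0, 1, 0), cl), 2), -0.15)
  expect_equal(expected_utility(c(0.2, 0.8), rep(-log(5), 2)), -log(5))
  ob <- c(0.5, 0, 0.25, 0.25)
  expect_equal(expected_utility(ob, cl), sum(ob * cl), tolerance = 1e-14)
})

test_that("expected free energy matches the enumeration oracle on random tiny models", {
  set.seed(99)
  for (i in 1:12) {
    m <- make_tiny_model(n_states = sample(2:4, 1), n_outcomes = sample(2:4, 1),
                         n_actions = 2, horizon = sample(2:3, 1))
    b <- normalise_for_test(stats::runif(ncol(m$obs$a), 0.1, 1))
    for (p in seq_len(nrow(m$policies))) {
      ev <- expected_free_energy(m, b, m$policies[p, ], ablation_flags(), t = 1L)
      expect_equal(attr(ev, "G"), oracle_efe(m, b, m$policies[p, ]), tolerance = 1e-10)
    }
  }
})

test_that("the stored decomposition always reassembles into G", {
  set.seed(17)
  for (i in 1:10) {
    m <- make_tiny_model(3, 3, 2, 3)
    b <- normalise_for_test(stats::runif(3, 0.1, 1))
    ev <- expected_free_energy(m, b, m$policies[sample(nrow(m$policies), 1), ])
    expect_equal(ev$G_tau, -(ev$novelty + ev$salience + ev$utility), tolerance = 1e-14)
    expect_true(all(ev$novelty >= 0))
    expect_true(all(ev$salience >= 0))
    expect_true(all(ev$utility <= 1e-14))
  }
})

test_that("pure-utility policy values reproduce the preference gap", {
  # two deterministic policies leading to outcomes with log preferences
  # -0.1452 and -6.1452: the G difference is exactly the raw gap of 6
  m <- make_learning_model()
  m$obs$learnable[] <- FALSE
  m$obs$a[3, 3] <- 512; m$obs$a[4, 3] <- 1e-16   # arm 2 surely emits the high reward
  m$obs$a[2, 2] <- 1e-16; m$obs$a[4, 2] <- 512   # arm 1 surely emits no reward
  flags <- ablation_flags(FALSE, FALSE)
  b <- c(1, 0, 0)
  g_noreward <- attr(expected_free_energy(m, b, 1L, flags), "G")
  g_high <- attr(expected_free_energy(m, b, 2L, flags), "G")
  expect_equal(g_noreward - g_high, 6, tolerance = 1e-3)
})

test_that("a fully known symmetric task values all policies equally", {
  m <- make_learning_model()
  m$obs$a[3, 3] <- 512 * 0.5; m$obs$a[4, 3] <- 512 * 0.5
  m$obs$learnable[] <- FALSE
  m$pref <- preference_vector(rep(0, 4))
  # make the safe arm emit the same two-outcome gamble so the task is symmetric
  m$obs$a[2, 2] <- 1e-16; m$obs$a[3, 2] <- 512 * 0.5; m$obs$a[4, 2] <- 512 * 0.5
  b <- c(1, 0, 0)
  g1 <- attr(expected_free_energy(m, b, 1L), "G")
  g2 <- attr(expected_free_energy(m, b, 2L), "G")
  expect_equal(g1, g2, tolerance = 1e-9)
})

test_that("the policy posterior is a precision-scaled softmax", {
  expect_equal(policy_posterior(c(1.3, 1.3, 1.3), 2), rep(1 / 3, 3))
  expect_equal(policy_posterior(c(0, 5, -3), 1e-9), rep(1 / 3, 3), tolerance = 1e-6)
  q <- policy_posterior(c(0, 1), 1)
  expect_equal(q, c(exp(0), exp(-1)) / (exp(0) + exp(-1)), tolerance = 1e-12)
  expect_error(policy_posterior(c(0, 1), 0), "positive")
})

test_that("action selection sharpens the policy marginal by alpha", {
  sel <- select_action(c(0.8, 0.2), 2)
  expect_equal(sel$prob, softmax_for_test(2 * log(c(0.8, 0.2))), tolerance = 1e-10)
  expect_equal(round(sel$prob, 3), c(0.941, 0.059))
  # alpha = 1 samples the marginal itself
  sel1 <- select_action(c(0.3, 0.7), 1)
  expect_equal(sel1$prob, c(0.3, 0.7), tolerance = 1e-12)
  # infinite precision picks the argmax, lowest index on ties
  expect_equal(select_action(c(0.5, 0.5), Inf)$action, 1L)
  expect_equal(select_action(c(0.1, 0.9), Inf)$action, 2L)
  # zero-probability actions are excluded from the softmax support
  selz <- select_action(c(0.5, 0, 0.5), 1)
  expect_equal(selz$prob[2], 0)
  expect_equal(sum(selz$prob), 1)
})

test_that("novelty strictly decreases after Dirichlet updates into the sampled column", {
  m <- make_learning_model()
  s_bar <- c(0, 0, 1)
  prev <- Inf
  for (i in 1:12) {
    o_bar <- predictive_outcome(s_bar, expected_likelihood(m$obs$a))
    nov <- novelty(s_bar, o_bar, m$obs$a, m$obs$learnable)
    expect_lt(nov, prev)
    prev <- nov
    o <- sample(3:4, 1)
    m$obs <- update_observation_counts(m$obs, o, s_bar, 0.5)
  }
})
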