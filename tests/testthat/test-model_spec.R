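test_that("log preferences are a log-softmax with the published normalisation", {
  cl <- log_preferences(c(0, 2, 4, -2))
  expect_equal(round(cl, 2), c(-4.15, -2.15, -0.15, -6.15))
  expect_equal(sum(exp(cl)), 1, tolerance = 1e-12)
  expect_equal(log_preferences(c(0, 0)), c(-log(2), -log(2)))
  # independent direct evaluation for an arbitrary vector
  c_raw <- c(0, 1, -1)
  expect_equal(log_preferences(c_raw), c_raw - log(sum(exp(c_raw))), tolerance = 1e-14)
  expect_error(log_preferences(c(0, NaN)), "finite")
})

test_that("log preferences are shift-invariant and normalise under random draws", {
  set.seed(42)
  for (i in 1:25) {
    c_raw <- stats::rnorm(sample(2:8, 1), sd = 3)
    cl <- log_preferences(c_raw)
    expect_equal(sum(exp(cl)), 1, tolerance = 1e-12)
    expect_equal(log_preferences(c_raw + stats::rnorm(1, sd = 10)), cl, tolerance = 1e-9)
    expect_equal(order(cl), order(c_raw))
  }
})

test_that("preference ratios reproduce the implied prior odds", {
  cl <- log_preferences(c(0, 2, 4, -2))
  expect_equal(round(preference_ratio(cl, 3, 1)), 55)  # high reward vs start
  expect_equal(preference_ratio(cl, 2, 2), 1)
  expect_equal(preference_ratio(log_preferences(c(0, 1)), 2, 1), exp(1), tolerance = 1e-12)
  expect_error(preference_ratio(cl, 5, 1), "out of range")
})

test_that("expected likelihood column-normalises counts and is scale invariant", {
  expect_equal(expected_likelihood(matrix(c(0.25, 0.25), 2)), matrix(c(0.5, 0.5), 2))
  expect_equal(expected_likelihood(matrix(c(3, 1), 2)), matrix(c(0.75, 0.25), 2))
  for (k in c(0.1, 1, 57)) {
    expect_equal(expected_likelihood(k * diag(3)), diag(3))
  }
  set.seed(7)
  a <- matrix(stats::runif(12, 0.1, 2), 4, 3)
  scales <- c(0.5, 2, 11)
  expect_equal(expected_likelihood(sweep(a, 2, scales, "*")), expected_likelihood(a))
  expect_error(expected_likelihood(matrix(c(1, 0, 0, 0), 2)), "all-zero")
})

test_that("expected log-likelihood matches digamma identities and an independent oracle", {
  # psi(n + 1) = psi(n) + 1/n gives exactly -1 for a unit column of two
  expect_equal(expected_log_likelihood(matrix(c(1, 1), 2)),
               matrix(c(-1, -1), 2), tolerance = 1e-12)
  a <- matrix(c(0.25, 0.25), 2)
  lnA <- expected_log_likelihood(a)
  expect_equal(lnA[1, 1], digamma_oracle(0.25) - digamma_oracle(0.5), tolerance = 1e-9)
  # with fixed proportions, lnA converges to log p as counts grow
  p <- c(0.3, 0.6, 0.1)
  expect_equal(expected_log_likelihood(matrix(1e7 * p, 3)), matrix(log(p), 3),
               tolerance = 1e-6)
  expect_error(expected_log_likelihood(matrix(c(0, 1), 2)), "positive")
})

test_that("exp(expected log-likelihood) columns sum to at most 1, approaching 1", {
  set.seed(3)
  for (i in 1:20) {
    a <- matrix(stats::runif(8, 0.1, 3), 4, 2)
    s <- colSums(exp(expected_log_likelihood(a)))
    expect_true(all(s <= 1 + 1e-12))
    s_big <- colSums(exp(expected_log_likelihood(1e6 * a)))
    expect_equal(s_big, rep(1, 2), tolerance = 1e-5)
  }
})

test_that("model validation accepts the task fixtures and flags corruption", {
  expect_length(validate_model(make_learning_model()), 0)
  expect_length(validate_model(make_inference_model()), 0)
  expect_length(validate_model(make_info_model(5, 5)), 0)
  cat_fns <- fixture_catalog()
  expect_length(validate_model(cat_fns$single_policy()), 0)
  expect_match(validate_model(cat_fns$broken_transition()), "stochastic", all = FALSE)
  expect_match(validate_model(cat_fns$zero_column_counts()), "zero", all = FALSE)
})

test_that("observation model dimensions match the two T-maze designs", {
  expect_equal(dim(make_learning_model()$obs$a), c(4, 3))
  expect_equal(dim(make_inference_model()$obs$a), c(7, 8))
})

test_that("a model round-trips through the YAML config without loss", {
  path <- withr::local_tempfile(fileext = ".yaml")
  for (m in list(make_learning_model(), make_inference_model(learnable_risky = TRUE),
                 make_tiny_model(3, 4, 2, 3, seed = 5))) {
    # accumulate some counts so a != a0 survives the round trip
    if (any(m$obs$learnable)) {
      o <- which(m$obs$learnable, arr.ind = TRUE)[1, ]
      s_post <- numeric(ncol(m$obs$a)); s_post[o["col"]] <- 1
      m$obs <- update_observation_counts(m$obs, o["row"], s_post, 0.5)
    }
    write_model_config(m, path)
    m2 <- read_model_config(path)
    expect_equal(m2$obs$a, m$obs$a, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(m2$obs$a0, m$obs$a0, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(m2$obs$learnable, m$obs$learnable, ignore_attr = TRUE)
    expect_equal(m2$trans$B, m$trans$B, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(m2$pref$log, m$pref$log, tolerance = 1e-12)
    expect_equal(m2$d$counts, m$d$counts, tolerance = 1e-12)
    expect_equal(m2$policies, m$policies, ignore_attr = TRUE)
    expect_equal(m2$precisions, m$precisions)
    expect_equal(m2$pref_timing, m$pref_timing)
  }
})
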