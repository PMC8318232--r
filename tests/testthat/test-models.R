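test_that("softmax probabilities behave as the choice rule requires", {
  expect_equal(softmax_probabilities(c(50, 50), 1), c(0.5, 0.5))
  expect_equal(softmax_probabilities(c(12, -70), 0), c(0.5, 0.5))
  # direct evaluation: beta (A1 - A2) = 2 gives 1 / (1 + e^-2)
  p <- softmax_probabilities(c(60, 40), 0.1)
  expect_equal(p[1], 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(sum(p), 1)
  # stability at extreme activations
  p2 <- softmax_probabilities(c(5000, -5000), 10)
  expect_true(all(is.finite(p2)) && sum(p2) == 1)
  expect_error(softmax_probabilities(c(NaN, 1), 1), "finite")
  expect_error(softmax_probabilities(c(1, 2), -1), "non-negative")
})

test_that("outcome and stimulus prediction errors match their definitions", {
  expect_equal(outcome_prediction_error(70, 60), 10)
  expect_equal(outcome_prediction_error(55, 55), 0)
  expect_equal(outcome_prediction_error(1, 50), -49)
  q <- c(60, 60, 40, 40)
  expect_equal(stimulus_prediction_error(q, c(1, 2)), 10)
  expect_equal(stimulus_prediction_error(q, c(3, 4)), -10)
  expect_equal(stimulus_prediction_error(rep(33, 4), c(2, 3)), 0)
  # PIRS variant: the raw pair-mean prediction
  expect_equal(stimulus_prediction_error(q, c(1, 4), "prediction"), 50)
})

test_that("utility families evaluate correctly and hit their limits", {
  # the shift point is a fixed point of every family
  for (fam in c("concave", "convex", "s-shaped", "inverse-s")) {
    k <- switch(fam, concave = 0.3, convex = -0.3, "s-shaped" = 0.5,
                "inverse-s" = 2)
    expect_equal(utility_transform(50, fam, k), 50)
  }
  # unit exponent of the power family is the identity
  expect_equal(utility_transform(c(1, 37, 99), "s-shaped", 1), c(1, 37, 99))
  # direct evaluation of the exponential family
  expect_equal(utility_transform(99, "concave", 0.1),
               50 + 50 * (1 - exp(-0.1 * 0.98)) / 0.1, tolerance = 1e-12)
  # exponential family approaches identity as curvature vanishes
  expect_equal(utility_transform(80, "concave", 1e-9), 80, tolerance = 1e-6)
  expect_equal(utility_transform(20, "convex", -1e-9), 20, tolerance = 1e-6)
  # curvature range enforcement
  expect_error(utility_transform(60, "concave", -1), "admissible")
  expect_error(utility_transform(60, "convex", 0.2), "admissible")
  expect_error(utility_transform(60, "s-shaped", 1.2), "admissible")
  expect_error(utility_transform(60, "inverse-s", 0.9), "admissible")
})

test_that("rate rules select the effective learning rate", {
  par <- list(alpha = 0.2, alpha_pos = 0.4, alpha_neg = 0.1,
              alpha_risky = 0.5, alpha_safe = 0.05, k_attention = 0.7)
  expect_equal(effective_learning_rate(par, "fixed", 3, 1), 0.2)
  expect_equal(effective_learning_rate(par, "valence", 3, 1), 0.4)
  expect_equal(effective_learning_rate(par, "valence", -3, 1), 0.1)
  expect_equal(effective_learning_rate(par, "variance", 3, 3), 0.5)
  expect_equal(effective_learning_rate(par, "variance", 3, 2), 0.05)
  # unit surprise leaves the attention rate at its base value
  expect_equal(effective_learning_rate(par, "attention", 1, 1), 0.2)
  expect_equal(effective_learning_rate(par, "attention", -1, 1), 0.2)
  expect_equal(effective_learning_rate(par, "attention", 4, 1), 0.2 * 4^0.7)
})

test_that("scaled outcome prediction errors divide by the spread", {
  expect_equal(scaled_outcome_pe(70, 60, 10), 1)
  expect_equal(scaled_outcome_pe(60, 60, 3), 0)
  expect_equal(scaled_outcome_pe(50, 60, 5), -2)
  expect_error(scaled_outcome_pe(50, 60, 0), "positive")
})

test_that("delta-rule value updates touch only the chosen entry", {
  q <- c(50, 50, 50, 50)
  expect_equal(value_update(q, 2, 0, 10), q)
  expect_equal(value_update(q, 2, 1, 17), c(50, 67, 50, 50))
  # geometric convergence under a fixed reward: Q_n = 60 - 10 * 0.7^n
  qq <- 50
  for (n in 1:25) {
    qq <- value_update(c(qq, 0, 0, 0), 1, 0.3, 60 - qq)[1]
    expect_equal(qq, 60 - 10 * 0.7^n, tolerance = 1e-12)
  }
})

test_that("spread updates track mean absolute deviation", {
  s <- c(10, 10, 10, 10)
  # fixed point: |delta| equal to the current spread
  expect_equal(spread_update(s, 1, 0.5, -10), s)
  expect_equal(spread_update(s, 3, 0.1, 20), c(10, 10, 11, 10))
  # scaled form is stationary at calibration |scaled delta| = 1
  expect_equal(spread_update(s, 2, 0.3, 1, scaled = TRUE), s)
  expect_equal(spread_update(s, 2, 0.3, -1, scaled = TRUE), s)
  expect_error(spread_update(s, 1, 1.5, 3), "\\[0,1\\]")
  # long-run level for Gaussian noise is sigma * sqrt(2/pi)
  set.seed(8)
  sv <- 10
  deltas <- rnorm(20000, 0, 20)
  for (d in deltas) sv <- spread_update(c(sv, 0, 0, 0), 1, 0.05, d)[1]
  expect_equal(sv, 20 * sqrt(2 / pi), tolerance = 0.15)
})

test_that("tanh gating moves activations between Q and Q +/- S", {
  q <- c(60, 60, 40, 40); s <- c(16, 5, 16, 5)
  expect_equal(action_activations(q, s, c(1, 2), gated = FALSE), c(60, 60))
  expect_equal(action_activations(q, s, c(1, 2), gated = TRUE, omega = 0,
                                  gate = 10), c(60, 60))
  expect_equal(action_activations(q, s, c(1, 2), gated = TRUE, omega = 2,
                                  gate = 0), c(60, 60))
  expect_equal(action_activations(q, s, c(1, 2), gated = TRUE, omega = 100,
                                  gate = 100), q[1:2] + s[1:2])
  expect_equal(action_activations(q, s, c(3, 4), gated = TRUE, omega = 100,
                                  gate = -100), q[3:4] - s[3:4])
  # risky-choice probability is non-decreasing in the gating signal
  gates <- seq(-15, 15, by = 1)
  p_risky <- vapply(gates, function(g) {
    softmax_probabilities(action_activations(q, s, c(1, 2), gated = TRUE,
                                             omega = 0.3, gate = g), 0.2)[1]
  }, numeric(1))
  expect_true(all(diff(p_risky) >= 0))
})

test_that("the registry exposes exactly the twelve models", {
  expect_length(model_names(), 12)
  for (m in model_names()) {
    spec <- model_spec(m)
    expect_equal(spec$k, length(spec$params))
    expect_true(spec$utility_family %in%
                  c("identity", "concave", "convex", "s-shaped", "inverse-s"))
  }
  expect_equal(model_spec("RW")$k, 2)
  expect_equal(model_spec("PEIRS")$k, 5)
  expect_equal(model_spec("scaled-PE")$k, 4)
  expect_error(model_spec("nope"), "unknown model")
})
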