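test_that("simulated sessions honour the task and probability contracts", {
  sched <- build_schedule(2, 5, seed = 3)
  for (m in c("RW", "PEIRS", "scaled-PE", "attention-RATES")) {
    sess <- simulate_session(m, default_parameters(m), sched, seed = 4)
    tr <- sess$trials
    expect_equal(nrow(tr), nrow(sched))
    expect_true(all(tr$choice == tr$stim_first | tr$choice == tr$stim_second))
    expect_true(all(tr$reward >= 1 & tr$reward <= 99))
    expect_true(all(sess$trace$p_chosen > 0 & sess$trace$p_chosen < 1))
    expect_true(all(sess$trace$p_first > 0 & sess$trace$p_first < 1))
  }
})

test_that("identical seeds reproduce sessions bit-for-bit", {
  sched <- quick_schedule()
  a <- simulate_session("PEIRS", default_parameters("PEIRS"), sched, seed = 12)
  b <- simulate_session("PEIRS", default_parameters("PEIRS"), sched, seed = 12)
  expect_identical(a$trials, b$trials)
  expect_identical(a$trace, b$trace)
})

test_that("the replay likelihood matches the independent reference replay", {
  sched <- build_schedule(2, 3, seed = 21)
  for (m in model_names()) {
    par <- default_parameters(m)
    sess <- simulate_session(m, par, sched, seed = 22)
    got <- session_log_likelihood(m, par, sess, trace = TRUE)
    ref <- oracle_replay(m, par, sess$trials)
    expect_equal(got$loglik, ref$loglik, tolerance = 1e-10)
    expect_equal(got$latents$p_chosen, ref$p_chosen, tolerance = 1e-10)
    # the simulator's own probability trace agrees with both
    expect_equal(sess$trace$p_chosen, ref$p_chosen, tolerance = 1e-10)
  }
})

test_that("values stay inside the convex hull of rewards and initial value", {
  sched <- build_schedule(2, 5, seed = 31)
  for (m in c("RW", "pos-neg-RATES", "variance-RATES", "PEIRS", "PIRS")) {
    sess <- simulate_session(m, default_parameters(m), sched, seed = 32)
    qs <- as.matrix(sess$trace[, paste0("Q", 1:4)])
    expect_true(all(qs >= 1 & qs <= 99))
    ss <- as.matrix(sess$trace[, paste0("S", 1:4)])
    expect_true(all(ss >= 0))
  }
})

test_that("unchosen stimuli keep their latent estimates between trials", {
  sess <- simulate_session("PEIRS", default_parameters("PEIRS"),
                           build_schedule(1, 5, seed = 41), seed = 42)
  tr <- sess$trials
  q <- as.matrix(sess$trace[, paste0("Q", 1:4)])
  s <- as.matrix(sess$trace[, paste0("S", 1:4)])
  for (t in 2:nrow(tr)) {
    others <- setdiff(1:4, tr$choice[t - 1])
    expect_equal(q[t, others], q[t - 1, others])
    expect_equal(s[t, others], s[t - 1, others])
  }
})

test_that("beta = 0 yields uniform choices and the chance log-likelihood", {
  sched <- build_schedule(1, 10, seed = 51)
  sess <- simulate_session("RW", c(alpha = 0.3, beta = 0), sched, seed = 52)
  expect_equal(session_log_likelihood("RW", c(alpha = 0.3, beta = 0), sess),
               nrow(sched) * log(0.5))
  expect_equal(mean(sess$trials$choice %in% c(1, 3)), 0.5, tolerance = 0.15)
})

test_that("a single recorded trial contributes exactly its log probability", {
  one <- data.frame(participant = 1, block = 1, trial = 1, stim_first = 1,
                    stim_second = 3, condition = "different", choice = 1,
                    reward = 70)
  # Q0 = 50 everywhere: beta (A1 - A2) = 0, then force an asymmetry
  expect_equal(session_log_likelihood("RW", c(alpha = 0.3, beta = 0.1), one),
               log(0.5))
  two <- rbind(one, transform(one, trial = 2, choice = 1, reward = 60))
  # after trial 1: Q1 = 56, so trial 2 sees beta (56 - 50) = 0.6
  expect_equal(session_log_likelihood("RW", c(alpha = 0.3, beta = 0.1), two),
               log(0.5) + log(1 / (1 + exp(-0.6))), tolerance = 1e-12)
})

test_that("the generating parameters dominate grossly perturbed ones", {
  sched <- build_schedule(4, 10, seed = 61)
  gen <- c(alpha = 0.3, beta = 0.25)
  bad <- c(alpha = 0.95, beta = 0.01)
  wins <- 0
  for (i in 1:10) {
    sess <- simulate_session("RW", gen, sched, seed = 100 + i)
    if (session_log_likelihood("RW", gen, sess) >
        session_log_likelihood("RW", bad, sess)) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("choices outside the shown pair are a data-integrity error", {
  bad <- data.frame(participant = 1, block = 1, trial = 1, stim_first = 1,
                    stim_second = 2, condition = "both-high", choice = 3,
                    reward = 50)
  expect_error(session_log_likelihood("RW", c(alpha = 0.3, beta = 0.2), bad),
               "outside the shown pair")
})

test_that("parameter sets are validated against the model", {
  sched <- quick_schedule()
  expect_error(simulate_session("PEIRS", c(alpha_q = 0.3, beta = 0.2), sched),
               "missing or non-finite")
  expect_error(simulate_session("RW", c(alpha = 1.4, beta = 0.2), sched),
               "\\[0,1\\]")
  expect_error(simulate_session("RW", c(alpha = 0.4, beta = -2), sched),
               ">= 0")
  p <- default_parameters("PEIRS"); p["s0"] <- -1
  expect_error(simulate_session("PEIRS", p, sched), "`s0`")
})
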