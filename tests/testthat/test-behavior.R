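# builds a deterministic trial table with prescribed choice behaviour
make_trials <- function(choose, participant = 1, n_blocks = 4, reps = 10,
                        seed = 1) {
  sched <- build_schedule(n_blocks, reps, seed = seed)
  choice <- mapply(choose, sched$stim_first, sched$stim_second, sched$trial)
  data.frame(participant = participant, block = sched$block,
             trial = sched$trial, stim_first = sched$stim_first,
             stim_second = sched$stim_second, condition = sched$condition,
             choice = as.integer(choice), reward = 50L)
}

choose_high_value <- function(f, s, t) {
  hv <- c(f, s)[c(f, s) %in% c(1, 2)]
  if (length(hv)) hv[1] else min(f, s)
}

test_that("the inclusion filter keys on late different-condition accuracy", {
  perfect <- make_trials(choose_high_value)
  f <- inclusion_filter(perfect)
  expect_true(f[1])
  expect_equal(attr(f, "proportion"), 1)
  # the threshold is a strict inequality: exactly 65% is excluded
  boundary <- function(n_correct) {
    data.frame(participant = 1, block = 1, trial = 1:120, stim_first = 1,
               stim_second = 3, condition = "different",
               choice = c(rep(1, 60), rep(1, n_correct), rep(3, 60 - n_correct)),
               reward = 50L)
  }
  f65 <- inclusion_filter(boundary(39))  # 39 / 60 = 0.65 exactly
  expect_equal(attr(f65, "proportion"), 0.65)
  expect_false(f65[1])
  expect_true(inclusion_filter(boundary(40))[1])
  # a random responder is excluded with near-certainty
  sess <- simulate_session("RW", c(alpha = 0.3, beta = 0),
                           build_schedule(4, 10, seed = 81), seed = 82)
  expect_false(inclusion_filter(sess)[1])
  # binomial tail: P(X/240 > 0.65) under p = 0.5 is vanishing
  expect_lt(pbinom(0.65 * 240, 240, 0.5, lower.tail = FALSE), 1e-5)
  only_risk <- perfect[perfect$condition != "different", ]
  expect_warning(out <- inclusion_filter(only_risk), "excluded")
  expect_false(out[1])
})

test_that("accuracy traces aggregate participant means first", {
  cohort <- rbind(make_trials(choose_high_value, participant = 1),
                  make_trials(function(f, s, t) if (1 %in% c(f, s) || 2 %in% c(f, s))
                    choose_high_value(f, s, t) else min(f, s), participant = 2,
                    seed = 2))
  acc <- accuracy_trace(cohort, bin_width = 10)
  expect_equal(nrow(acc), 12)
  expect_true(all(acc$mean == 1))
  expect_true(all(acc$se == 0))
  expect_error(accuracy_trace(cohort, bin_width = 7), "divide")
  # a learning cohort's accuracy rises from first to last bin
  coh <- generate_cohort("RW", 6, source = "default", seed = 83,
                         sanity_filter = FALSE)
  acc2 <- accuracy_trace(cohort_trials(coh))
  expect_gt(acc2$mean[12], acc2$mean[1])
})

test_that("condition contrasts match a textbook t computation", {
  set.seed(9)
  coh <- generate_cohort("PEIRS", 8, source = "default", seed = 84,
                         sanity_filter = FALSE)
  ct <- condition_tests(coh)
  rs <- ct$summary
  ref <- oracle_t(rs$both_high - rs$both_low, 0)
  expect_equal(ct$paired$t, ref$t, tolerance = 1e-10)
  expect_equal(ct$paired$df, ref$df)
  expect_equal(ct$paired$p, ref$p, tolerance = 1e-10)
  ref_bh <- oracle_t(rs$both_high, 0.5)
  expect_equal(ct$both_high_vs_chance$t, ref_bh$t, tolerance = 1e-10)
})

test_that("degenerate preference cohorts are guarded, not errors", {
  # every participant always picks the risky option: paired difference 0/0
  cohort <- rbind(
    make_trials(function(f, s, t) if (f %in% c(1, 3)) f else s, 1),
    make_trials(function(f, s, t) if (f %in% c(1, 3)) f else s, 2, seed = 2))
  ct <- condition_tests(cohort)
  expect_equal(ct$paired$t, 0)
  expect_equal(ct$paired$p, 1)
  # constant at 1.0 vs chance 0.5: infinite t, p = 0
  expect_true(is.infinite(ct$both_high_vs_chance$t))
  expect_equal(ct$both_high_vs_chance$p, 0)
})

test_that("emergence test contrasts value against risk learning speed", {
  # RW learns values only: value slopes should exceed risk slopes
  coh <- generate_cohort("RW", 8, source = "default", seed = 85,
                         sanity_filter = FALSE)
  em <- emergence_test(coh)
  expect_gt(em$mean_diff, 0)
  expect_equal(nrow(em$slopes), 8)
  # beta = 0: no learning expressed in choice, both slopes near zero
  flat <- generate_cohort("RW", 6, source = "fixed",
                          fixed = replicate(6, c(alpha = 0.3, beta = 0),
                                            simplify = FALSE),
                          seed = 86, sanity_filter = FALSE)
  em0 <- emergence_test(flat)
  expect_lt(abs(em0$mean_diff), 0.01)
  expect_true(all(abs(em0$slopes$value_slope) < 0.02))
})

test_that("perfectly separated choice sequences are clipped with a flag", {
  # switches deterministically at mid-block: logistic fit separates
  switcher <- make_trials(function(f, s, t) {
    pair <- c(f, s)
    hv <- pair[pair %in% c(1, 2)]
    lv <- pair[pair %in% c(3, 4)]
    if (t > 60) (if (length(hv)) hv[1] else pair[1])
    else (if (length(lv)) lv[1] else pair[2])
  })
  em <- emergence_test(rbind(switcher,
                             transform(switcher, participant = 2)))
  expect_true(any(em$slopes$value_clipped))
  expect_true(all(abs(em$slopes$value_slope) <= 1))
})

test_that("the analysis battery drops excluded participants everywhere", {
  good1 <- make_trials(choose_high_value, 1)
  good2 <- make_trials(choose_high_value, 2, seed = 2)
  bad <- simulate_session("RW", c(alpha = 0.3, beta = 0),
                          build_schedule(4, 10, seed = 87), seed = 88)$trials
  bad$participant <- 3
  res <- analyze_cohort(rbind(good1, good2, bad))
  expect_equal(sort(res$included), c(1, 2))
  expect_equal(res$excluded, 3)
  expect_equal(sort(unique(res$tests$summary$participant)), c(1, 2))
  # disabling the filter changes membership but not per-participant values
  res_all <- analyze_cohort(rbind(good1, good2, bad), filter = FALSE)
  joint <- merge(res$tests$summary, res_all$tests$summary,
                 by = "participant")
  expect_equal(joint$both_high.x, joint$both_high.y)
})
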