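test_that("percentile follows the mid-point convention and matches median at 50", {
  expect_equal(percentile(c(1, 3), 50), 2)
  expect_equal(percentile(1:10, 50), median(1:10))
  for (i in 1:20) {
    x <- withr::with_seed(i, rnorm(sample(3:30, 1)))
    expect_equal(percentile(x, 50), median(x))
  }
  # clamped at the extremes
  expect_equal(percentile(1:5, 0), 1)
  expect_equal(percentile(1:5, 100), 5)
  expect_error(percentile(numeric(0), 50), "nonempty")
})

test_that("exact Wilcoxon signed-rank test matches brute-force enumeration", {
  expect_equal(wilcoxon_paired(1:5, 1:5)$p_value, 1)

  # randomized cases, n <= 10, with and without ties and zero differences
  for (i in 1:25) {
    d <- withr::with_seed(100 + i, {
      n <- sample(4:10, 1)
      round(rnorm(n), sample(0:1, 1))
    })
    x <- d; y <- numeric(length(d))
    if (all(d == 0)) next
    expect_equal(wilcoxon_paired(x, y)$p_value, enumeration_wilcoxon(x, y),
                 tolerance = 1e-12, label = paste("case", i))
  }

  # tie-free data agree with stats::wilcox.test exact p-values
  for (i in 1:10) {
    pair <- withr::with_seed(200 + i, list(x = rnorm(12), y = rnorm(12)))
    ours <- wilcoxon_paired(pair$x, pair$y)
    ref <- wilcox.test(pair$x, pair$y, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(unname(ours$statistic), unname(ref$statistic))
  }
})

test_that("Wolpaw bit rate has its analytic values and shape", {
  # perfect four-choice selection every 10 s: the 12 bit/min ceiling
  expect_equal(wolpaw_bitrate(1, 4, 10), 12)
  # chance level carries no information
  expect_equal(wolpaw_bitrate(0.25, 4, 10), 0)
  # direct formula evaluation at an interior accuracy
  p <- 0.951
  b <- log2(4) + p * log2(p) + (1 - p) * log2((1 - p) / 3)
  expect_equal(wolpaw_bitrate(p, 4, 10), b * 6)
  # nonnegative and monotone on [1/N, 1]
  ps <- seq(0.25, 1, length.out = 50)
  rates <- wolpaw_bitrate(ps, 4, 10)
  expect_true(all(rates >= 0))
  expect_true(all(diff(rates) > 0))
})

test_that("the circle game follows the step/timeout rules", {
  # perfect classifier: 4 target flashes = 4 steps, session ends at the 4th
  sched <- rep(1:4, 4)  # 4 blocks, desired arrow = 2
  preds <- ifelse(sched == 2, "target", "nontarget")
  s <- simulate_session(preds, sched, desired_direction = 2)
  expect_equal(s$terminated, "reached")
  expect_true(s$success)
  expect_equal(s$flash_count, which(sched == 2)[4])

  # all-nontarget classifier: timeout at 92 flashes
  long_sched <- rep(1:4, 23)
  s <- simulate_session(rep("nontarget", 92), long_sched, 1)
  expect_equal(s$terminated, "timeout")
  expect_equal(s$flash_count, 92)

  # false positives on a wrong arrow drive the circle to the wrong image
  s <- simulate_session(rep("target", 4), rep(3, 4), desired_direction = 1)
  expect_equal(s$terminated, "reached")
  expect_equal(s$reached_direction, 3L)
  expect_false(s$success)

  # session never exceeds the timeout even with longer streams
  s <- simulate_session(rep("nontarget", 200), rep(1, 200), 1)
  expect_equal(s$flash_count, 92)
})

test_that("day evaluation trains on preceding days only and scores per flash", {
  study <- generate_study(1, sessions_per_day = 1, n_testing_days = 1,
                          snr_db_range = c(6, 6), seed = 51)
  cfg <- pipeline_config(grid = tibble::tibble(C = 4, width = 4^-4), n_splits = 2)
  res <- run_day_evaluation(study, 1, cfg, seed = 1)
  expect_equal(nrow(res), 1)
  expect_equal(res$n_flashes, 16)  # one 4-block testing session
  expect_equal(res$accuracy, 100 * res$n_correct / res$n_flashes)
  expect_true(res$gamma_star > 0)
  # a day that does not exist in the study errors
  expect_error(run_day_evaluation(study, 3, cfg), "T3")
})
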