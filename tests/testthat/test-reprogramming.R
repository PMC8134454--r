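test_that("signature deltas measure mean absolute change from day 0", {
  # 3 CpGs, 1 donor, hand-computable course
  v <- cbind(d0 = c(0.1, 0.5, 0.9), d10 = c(0.1, 0.5, 0.9),
             d20 = c(0.6, 0.3, 0.9))
  m <- toy_beta(v, samples = colnames(v))
  s <- sample_sheet(colnames(v), passage = 0, donor = "D1",
                    timepoint_days = c(0, 10, 20))
  sig <- signature_set("culture", cpg_ids(m))
  d <- signature_delta(m, s, sig)
  expect_equal(d$mean_abs_delta, c(0, 0, mean(c(0.5, 0.2, 0))))
  expect_equal(d$timepoint, c(0, 10, 20))

  # constant course -> all-zero deltas
  const <- toy_beta(matrix(0.4, 2, 3), samples = colnames(v))
  expect_equal(signature_delta(const, s, signature_set("x", cpg_ids(const)))$mean_abs_delta,
               rep(0, 3))

  # step function: single CpG jumping 0 -> 1 at t = 20
  step <- toy_beta(matrix(c(0, 0, 1), 1, 3), samples = colnames(v))
  expect_equal(signature_delta(step, s, signature_set("s", cpg_ids(step)))$mean_abs_delta,
               c(0, 0, 1))

  s_no0 <- sample_sheet(colnames(v), 0, donor = "D1", timepoint_days = c(5, 10, 20))
  expect_error(signature_delta(m, s_no0, sig), "day-0")
})

test_that("trajectory correlation is symmetric and scale invariant", {
  a <- c(0, 0.05, 0.2, 0.4, 0.45)
  expect_equal(trajectory_correlation(a, 2 * a), 1, tolerance = 1e-12)
  expect_equal(trajectory_correlation(a, rev(a)),
               trajectory_correlation(rev(a), a))
  # reversing an evenly spaced monotone series flips the correlation exactly
  lin <- seq(0, 0.5, length.out = 6)
  expect_equal(trajectory_correlation(lin, rev(lin)), -1, tolerance = 1e-12)
  b <- c(0.01, 0.1, 0.18, 0.3, 0.5)
  expect_equal(trajectory_correlation(a, b), trajectory_correlation(b, a))
  expect_equal(trajectory_correlation(a, b), cor(a, b), tolerance = 1e-12)
  expect_warning(r <- trajectory_correlation(a, rep(0.2, 5)), "zero variance")
  expect_true(is.na(r))
  expect_error(trajectory_correlation(a[1:2], a[1:2]), ">= 3")
})

test_that("mean univariate passage estimates average per-CpG predictions", {
  pred <- data.frame(cpg_id = c("cg01", "cg02"),
                     intercept = c(0, 10), slope = c(100, 20))
  sig <- signature_set("clock", pred$cpg_id, predictors = pred)
  m <- toy_beta(rbind(c(0.25, 0.1), c(0.5, NA)))
  est <- mean_univariate_passage(m, sig)
  expect_equal(unname(est[1]), mean(c(100 * 0.25, 10 + 20 * 0.5)))
  expect_equal(unname(est[2]), 100 * 0.1)   # missing CpG skipped

  # inverted-regression predictors track passage via the dominant CpG
  lc <- linear_cohort(n = 20, sd = 0)
  up <- fit_univariate_predictors(lc$beta, lc$sheet, "cg_b")
  sig2 <- signature_set("one", "cg_b", predictors = up)
  est2 <- mean_univariate_passage(lc$beta, sig2)
  expect_gt(cor(est2, lc$sheet$passage), 0.9)

  f <- withr::local_tempfile(fileext = ".json")
  write_signature_set(sig, f)
  back <- read_signature_set(f)
  expect_equal(back$predictors$slope, pred$slope)
})

test_that("logistic time-course simulation resets all signatures together", {
  cfg <- sim_config(seed = 9)
  tc <- simulate_timecourse(cfg)
  d_cult <- signature_delta(tc$beta, tc$sheet, tc$signatures$culture)
  d_age <- signature_delta(tc$beta, tc$sheet, tc$signatures$age)
  d_plur <- signature_delta(tc$beta, tc$sheet, tc$signatures$pluripotency)
  expect_equal(d_cult$mean_abs_delta[d_cult$timepoint == 0], 0)
  # shared switch day: trajectories nearly perfectly correlated
  expect_gt(trajectory_correlation(d_cult, d_plur), 0.99)
  expect_gt(trajectory_correlation(d_age, d_plur), 0.99)
  # deltas are small before the switch and large after it
  expect_lt(d_cult$mean_abs_delta[d_cult$timepoint == 7], 0.1)
  expect_gt(d_cult$mean_abs_delta[d_cult$timepoint == 49], 0.4)
  # the switch happens between day 15 and day 20 (inflection near t0)
  mid <- (max(d_cult$mean_abs_delta) + min(d_cult$mean_abs_delta)) / 2
  crossing <- d_cult$timepoint[which(d_cult$mean_abs_delta > mid)[1]]
  expect_true(crossing %in% c(15, 20))
  # passage estimates decline through the switch: pick culture CpGs that
  # re-methylate (start low, end high) with predictors mapping low beta ->
  # high passage, as for culture-hypomethylated sites
  cult <- tc$truth[tc$truth$signature == "culture" & tc$truth$end > tc$truth$start, ]
  up <- data.frame(cpg_id = cult$cpg_id, intercept = 30, slope = -30)
  sig_p <- signature_set("est", up$cpg_id, predictors = up)
  est <- mean_univariate_passage(tc$beta, sig_p)
  pre <- mean(est[tc$sheet$timepoint_days <= 11])
  post <- mean(est[tc$sheet$timepoint_days >= 28])
  expect_gt(pre, post)
})
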