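test_that("per-CpG passage correlation matches the brute-force formula", {
  p <- 1:10
  v <- rbind(exact = 0.01 * p,
             const = rep(0.5, 10),
             noisy = c(0.2, 0.25, 0.21, 0.3, 0.28, 0.33, 0.31, 0.38, 0.36, 0.41))
  m <- toy_beta(v, cpgs = c("exact", "const", "noisy"))
  s <- sample_sheet(sample_ids(m), p)
  st <- correlate_cpgs(m, s)

  expect_equal(st$r[st$cpg_id == "exact"], 1, tolerance = 1e-12)
  expect_equal(st$slope[st$cpg_id == "exact"], 0.01, tolerance = 1e-12)
  expect_true(st$undefined[st$cpg_id == "const"])

  # brute-force Pearson on the noisy row
  b <- v["noisy", ]
  r_hand <- sum((b - mean(b)) * (p - mean(p))) /
    sqrt(sum((b - mean(b))^2) * sum((p - mean(p))^2))
  expect_equal(st$r[st$cpg_id == "noisy"], r_hand, tolerance = 1e-12)
  m_hand <- sum((b - mean(b)) * (p - mean(p))) / sum((p - mean(p))^2)
  expect_equal(st$slope[st$cpg_id == "noisy"], m_hand, tolerance = 1e-12)

  # invariant to sample-column permutation
  perm <- sample(ncol(v))
  st2 <- correlate_cpgs(toy_beta(v[, perm], cpgs = rownames(v),
                                 samples = sample_ids(m)[perm]), s)
  expect_equal(st2$r, st$r)

  expect_error(correlate_cpgs(m, sample_sheet(sample_ids(m), rep(3, 10))),
               "identical")
})

test_that("candidate filtering applies r, slope and top-n rules", {
  st <- data.frame(
    cpg_id = sprintf("cg%02d", 1:6),
    r = c(0.9, 0.75, -0.85, -0.72, 0.3, NA),
    slope = c(0.03, 0.01, -0.05, -0.03, 0.01, NA),
    intercept = 0, n = 10,
    direction = c("hyper", "hyper", "hypo", "hypo", "hyper", "none"),
    undefined = c(rep(FALSE, 5), TRUE))
  cs <- filter_candidates(st, r_cut = 0.7)
  expect_equal(cs$hyper, c("cg01", "cg02"))
  expect_equal(cs$hypo, c("cg03", "cg04"))

  cs2 <- filter_candidates(st, r_cut = 0.7, slope_cut = 0.02)
  expect_equal(cs2$hyper, "cg01")
  expect_equal(cs2$hypo, c("cg03", "cg04"))

  cs3 <- filter_candidates(st, r_cut = 0.7, top_n = 1)
  expect_equal(lengths(cs3[c("hyper", "hypo")]), c(hyper = 1L, hypo = 1L))

  # monotone in r_cut
  for (rc in c(0.71, 0.8, 0.92)) {
    tighter <- filter_candidates(st, rc)
    expect_true(all(tighter$hyper %in% cs$hyper))
    expect_true(all(tighter$hypo %in% cs$hypo))
  }
  expect_error(filter_candidates(st, 1.2), "r_cut")

  f <- withr::local_tempfile(fileext = ".json")
  write_candidate_set(cs, f)
  expect_equal(read_candidate_set(f)$hyper, cs$hyper)
})

test_that("exhaustive best-subset search finds the planted model", {
  lc <- linear_cohort(n = 30, sd = 0)
  cs <- structure(list(hyper = c("cg_a", "cg_d1", "cg_d2"),
                       hypo = c("cg_b", "cg_d3", "cg_d4"),
                       r_cut = 0.5, slope_cut = NULL, top_n = NULL),
                  class = "CandidateSet")
  best <- best_subset_model(lc$beta, lc$sheet, cs)
  expect_true(all(c("cg_a", "cg_b") %in% best$cpg_ids))
  expect_equal(attr(best, "subset_r2"), 1, tolerance = 1e-10)
  expect_equal(unname(best$coefficients["cg_a"]), 5, tolerance = 1e-8)
  expect_equal(unname(best$coefficients["cg_b"]), -20, tolerance = 1e-8)

  # independent enumeration oracle: best R^2 over all 2+2 subsets
  rss_of <- function(cpgs) {
    X <- cbind(1, t(lc$beta$values[cpgs, ]))
    sum(stats::lm.fit(X, lc$sheet$passage)$residuals^2)
  }
  combos <- expand.grid(h = utils::combn(cs$hyper, 2, simplify = FALSE),
                        o = utils::combn(cs$hypo, 2, simplify = FALSE))
  all_rss <- mapply(function(h, o) rss_of(c(h, o)), combos$h, combos$o)
  X <- cbind(1, t(lc$beta$values[best$cpg_ids, ]))
  expect_equal(sum(stats::lm.fit(X, lc$sheet$passage)$residuals^2),
               min(all_rss), tolerance = 1e-9)

  # nesting: best subset R^2 >= any single-candidate R^2
  single_r2 <- vapply(c(cs$hyper, cs$hypo), function(cg) {
    summary(stats::lm(lc$sheet$passage ~ lc$beta$values[cg, ]))$r.squared
  }, numeric(1))
  expect_true(attr(best, "subset_r2") >= max(single_r2) - 1e-12)

  # forced choice with exactly 2+2 candidates equals a plain OLS fit
  cs4 <- structure(list(hyper = c("cg_a", "cg_d1"), hypo = c("cg_b", "cg_d3"),
                        r_cut = 0.5, slope_cut = NULL, top_n = NULL),
                   class = "CandidateSet")
  forced <- best_subset_model(lc$beta, lc$sheet, cs4)
  direct <- train_model(lc$beta, lc$sheet, sort(c("cg_a", "cg_d1", "cg_b", "cg_d3")))
  expect_equal(forced$coefficients, direct$coefficients, tolerance = 1e-8)
})

test_that("outlier samples are flagged by the studentized-residual test", {
  lc <- linear_cohort(n = 30, sd = 0.5, seed = 1)
  mod <- train_model(lc$beta, lc$sheet, c("cg_a", "cg_b"))
  expect_length(detect_outlier_samples(lc$beta, lc$sheet, mod, 0.05), 0)

  sh <- lc$sheet
  sh$passage[5] <- sh$passage[5] + 10 * 0.5
  flagged <- detect_outlier_samples(lc$beta, sh, mod, 0.05)
  expect_identical(flagged, "s5")
  expect_length(detect_outlier_samples(lc$beta, sh, mod, 0), 0)
})

test_that("hydroxymethylation is the BS minus OxBS difference", {
  bs <- toy_beta(matrix(c(0.5, 0.4, 0.9, 0.1), nrow = 2))
  oxbs <- toy_beta(matrix(c(0.2, 0.5, 0.9, 0.05), nrow = 2))
  h <- estimate_hydroxymethylation(bs, oxbs)
  expect_equal(unname(h[1, 1]), 0.3)
  expect_equal(unname(h[2, 1]), -0.1)   # negative estimates kept
  expect_true(all(estimate_hydroxymethylation(bs, bs) == 0))
  expect_equal(hydroxymethylation_summary(h, c("cg01", "cg02")),
               mean(bs$values - oxbs$values))

  mismatch <- toy_beta(matrix(runif(4), 2), cpgs = c("cg01", "cgXX"))
  expect_error(estimate_hydroxymethylation(bs, mismatch), "cgXX")
})
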