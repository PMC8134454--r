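test_that("pattern spectra count epialleles and exclude incomplete reads", {
  rps <- read_pattern_set(rbind(c(1L, 1L), c(1L, 1L), c(0L, 1L), c(0L, NA)),
                          counts = c(5L, 5L, 10L, 3L))
  spec <- pattern_spectrum(rps)
  expect_equal(sum(spec$frequencies), 1, tolerance = 1e-12)
  expect_equal(unname(spec$frequencies[c("11", "01")]), c(0.5, 0.5))
  expect_equal(spec$n_excluded, 3L)

  one <- pattern_spectrum(read_pattern_set(matrix(1L, 10, 3)))
  expect_equal(unname(one$frequencies), 1)

  # frequencies match brute-force counting on random reads
  withr::with_seed(4, states <- matrix(rbinom(100 * 3, 1, 0.4), ncol = 3))
  sp <- pattern_spectrum(read_pattern_set(states))
  hand <- table(apply(states, 1, paste, collapse = "")) / 100
  expect_equal(sp$frequencies[names(hand)], c(hand)[names(hand)],
               tolerance = 1e-12, ignore_attr = TRUE)

  all_missing <- read_pattern_set(matrix(NA_integer_, 2, 3))
  expect_error(pattern_spectrum(all_missing), "complete")
})

test_that("Shannon index hits its closed-form bounds", {
  expect_equal(shannon_index(c(1)), 0)
  expect_equal(shannon_index(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-12)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.03972077, tolerance = 1e-7)
  # counts are normalized; zero categories contribute nothing
  expect_equal(shannon_index(c(10, 10, 0)), log(2), tolerance = 1e-12)
  # always within [0, log(n)]
  withr::with_seed(2, for (i in 1:20) {
    p <- runif(sample(2:8, 1)); h <- shannon_index(p)
    expect_gte(h, 0); expect_lte(h, log(length(p)) + 1e-12)
  })
})

test_that("neighbor correlation separates coherent from independent reads", {
  # perfectly coherent: alternating all-1 / all-0 reads
  coh <- read_pattern_set(rbind(matrix(1L, 10, 4), matrix(0L, 10, 4)))
  cc <- neighbor_correlation(coh)
  expect_true(all(abs(cc[upper.tri(cc)] - 1) < 1e-12))

  # 2-CpG phi-coefficient closed form: n11=40 n10=10 n01=10 n00=40 -> 0.6
  states <- rbind(matrix(c(1L, 1L), 40, 2, byrow = TRUE),
                  matrix(c(1L, 0L), 10, 2, byrow = TRUE),
                  matrix(c(0L, 1L), 10, 2, byrow = TRUE),
                  matrix(c(0L, 0L), 40, 2, byrow = TRUE))
  cc2 <- neighbor_correlation(read_pattern_set(states))
  expect_equal(cc2[1, 2], 0.6, tolerance = 1e-12)

  # zero-variance CpG flagged undefined
  zv <- read_pattern_set(cbind(rep(1L, 20), rbinom(20, 1, 0.5)))
  cc3 <- neighbor_correlation(zv)
  expect_true(1 %in% attr(cc3, "zero_variance"))
  expect_true(all(is.na(cc3[1, ])))
})

test_that("read-level methylation fractions track passage", {
  cfg <- sim_config(seed = 41, reads_per_sample = 500)
  ps <- c(2, 5, 8, 11)
  sets <- lapply(ps, function(p) simulate_reads(cfg, 5, p, sample_id = paste0("S", p)))
  sheet <- sample_sheet(paste0("S", ps), ps)
  r <- cpg_passage_correlation(sets, sheet)
  truth <- attr(sets[[1]], "truth")
  # sign of the correlation follows the generating slope at every CpG
  expect_equal(sign(r), sign(truth$slopes), ignore_attr = TRUE)
})

test_that("the single-read passage predictor maximizes the grid likelihood", {
  srm <- structure(list(intercepts = c(0.1, 0.9), slopes = c(0.01, -0.01),
                        passage_grid = 0:50, clip_eps = 0.001),
                   class = "SingleReadModel")
  # brute-force oracle over the grid
  brute <- function(x) {
    ll <- vapply(0:50, function(p) {
      m <- pmin(pmax(srm$intercepts + srm$slopes * p, 0.001), 0.999)
      sum(x * log(m) + (1 - x) * log(1 - m), na.rm = TRUE)
    }, numeric(1))
    (0:50)[which.max(ll)]
  }
  expect_equal(predict_read(srm, c(1, 0))$best_passage, brute(c(1, 0)))
  expect_equal(predict_read(srm, c(1, 0))$best_passage, 50)
  expect_equal(predict_read(srm, c(0, 1))$best_passage, 0)
  # invariant to CpG ordering
  srm_rev <- srm; srm_rev$intercepts <- rev(srm$intercepts)
  srm_rev$slopes <- rev(srm$slopes)
  expect_equal(predict_read(srm_rev, c(0, 1))$best_passage,
               predict_read(srm, c(1, 0))$best_passage)

  # flat model: tie broken toward the smallest grid passage
  flat <- srm; flat$slopes <- c(0, 0)
  expect_equal(predict_read(flat, c(1, 1))$best_passage, 0)

  # monotone model + all-methylated read -> top of the grid
  mono <- srm; mono$slopes <- c(0.01, 0.012); mono$intercepts <- c(0.1, 0.05)
  expect_equal(predict_read(mono, c(1, 1))$best_passage, 50)

  # missing states are skipped, all-missing is unpredictable
  expect_equal(predict_read(srm, c(1, NA))$best_passage, 50)
  expect_true(is.na(predict_read(srm, c(NA, NA))$best_passage))
})

test_that("per-CpG line fitting and sample-level prediction recover truth", {
  # exact fractions 0.1 + 0.01 p
  ps <- c(0, 10, 20, 30)
  sets <- lapply(ps, function(p) {
    k <- round(100 * (0.1 + 0.01 * p))
    read_pattern_set(cbind(rep(c(1L, 0L), c(k, 100 - k))),
                     sample_id = paste0("S", p))
  })
  sheet <- sample_sheet(paste0("S", ps), ps)
  srm <- fit_single_read_model(sets, sheet)
  expect_equal(srm$intercepts, 0.1, tolerance = 1e-10)
  expect_equal(srm$slopes, 0.01, tolerance = 1e-10)

  # constant fractions give zero slope
  flat_sets <- lapply(ps, function(p)
    read_pattern_set(cbind(rep(c(1L, 0L), c(50, 50))), sample_id = paste0("S", p)))
  expect_equal(fit_single_read_model(flat_sets, sheet)$slopes, 0, tolerance = 1e-12)

  expect_error(fit_single_read_model(sets[1:2], sheet), ">= 3")
  expect_error(fit_single_read_model(sets, sheet, clip_eps = 0.7), "clip_eps")

  # mean over reads equals the brute-force average of per-read predictions
  cfg <- sim_config(seed = 7, reads_per_sample = 200)
  tr <- lapply(c(2, 6, 10), function(p) simulate_reads(cfg, 9, p, sample_id = paste0("T", p)))
  tsheet <- sample_sheet(paste0("T", c(2, 6, 10)), c(2, 6, 10))
  m2 <- fit_single_read_model(tr, tsheet)
  res <- predict_sample_from_reads(m2, tr[[2]])
  per_read <- rep(res$per_pattern$best_passage, res$per_pattern$count)
  expect_equal(res$mean_passage, mean(per_read), tolerance = 1e-12)
})
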