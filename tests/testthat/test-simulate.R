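test_that("generators are pure functions of the config seed", {
  cfg <- sim_config(seed = 5)
  expect_identical(simulate_cohort(cfg)$beta$values,
                   simulate_cohort(cfg)$beta$values)
  expect_identical(simulate_reads(cfg, 6, 5)$states,
                   simulate_reads(cfg, 6, 5)$states)
  expect_identical(simulate_hairpin(cfg, 4, n_molecules = 50)$umi,
                   simulate_hairpin(cfg, 4, n_molecules = 50)$umi)
  expect_identical(simulate_timecourse(cfg)$beta$values,
                   simulate_timecourse(cfg)$beta$values)
  cfg2 <- sim_config(seed = 6)
  expect_false(identical(simulate_cohort(cfg)$beta$values,
                         simulate_cohort(cfg2)$beta$values))
  # generators do not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_cohort(cfg)); after <- runif(1)
  expect_identical(before, after)
  expect_error(sim_config(seed = 1, writer_error = 1.5), "outside")
})

test_that("cohort drift is linear with planted slopes", {
  cfg <- sim_config(seed = 30, noise_sd = 0)
  sim <- simulate_cohort(cfg)
  st <- correlate_cpgs(sim$beta, sim$sheet)
  drift <- sim$truth$drifting
  expect_equal(abs(st$r[drift]), rep(1, sum(drift)), tolerance = 1e-9)
  # planted slopes recovered exactly at zero noise
  expect_equal(st$slope[drift], sim$truth$slope[drift], tolerance = 1e-10)
  # stable CpGs are flat (zero variance -> undefined correlation)
  expect_true(all(st$undefined[!drift]))
  # betas stay inside [0,1] even with noise
  simN <- simulate_cohort(sim_config(seed = 31, noise_sd = 0.05))
  expect_true(all(simN$beta$values >= 0 & simN$beta$values <= 1))
})

test_that("read simulation honours its generative model", {
  # writer_error = 0: every read is an all-0 or all-1 block
  cfgW <- sim_config(seed = 8, model = "targeted_writer", writer_error = 0,
                     reads_per_sample = 400)
  rw <- simulate_reads(cfgW, 5, 10)
  expect_true(all(rowSums(rw$states) %in% c(0, 5)))

  # independent model: per-CpG mean within 3 binomial s.e. of the line
  cfgI <- sim_config(seed = 9, reads_per_sample = 10000)
  ri <- simulate_reads(cfgI, 6, 7)
  truth <- attr(ri, "truth")
  p <- pmin(pmax(truth$intercepts + truth$slopes * 7, 0.001), 0.999)
  se <- sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(methylation_fractions(ri) - p) <= 3 * se))

  # pattern diversity grows as probabilities move toward 0.5
  cfgH <- sim_config(seed = 10, reads_per_sample = 4000)
  h <- vapply(c(1, 10, 25), function(p)
    shannon_index(pattern_spectrum(simulate_reads(cfgH, 6, p))), numeric(1))
  expect_true(h[1] < h[2] && h[2] < h[3])
})

test_that("clonal culture loses diversity through bottlenecks", {
  # frozen single clone: identical patterns at all passages
  cfg1 <- sim_config(seed = 2, n_clones = 1, epimutation_rate = 0,
                     reads_per_sample = 50)
  cl1 <- simulate_clonal_culture(cfg1, n_cpgs = 6, n_passages = 5)
  for (p in 2:5) expect_identical(cl1$patterns[[p]], cl1$patterns[[1]])

  # frequencies are a distribution at every passage
  cfg <- sim_config(seed = 3, bottleneck_frac = 0.02, n_cells = 5000,
                    reads_per_sample = 200)
  cl <- simulate_clonal_culture(cfg, n_cpgs = 6, n_passages = 8)
  expect_equal(colSums(cl$frequencies), rep(1, 8), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(nrow(cl$barcodes), cfg$n_clones)
  expect_true(all(nchar(cl$barcodes$barcode) == 16))

  # strong bottlenecks erode clonal Shannon diversity in >= 9 of 10 seeds
  drops <- vapply(1:10, function(sd) {
    c2 <- sim_config(seed = 100 + sd, bottleneck_frac = 0.02, n_cells = 5000,
                     reads_per_sample = 50)
    fr <- simulate_clonal_culture(c2, n_cpgs = 4, n_passages = 8)$frequencies
    shannon_index(fr[, 8]) < shannon_index(fr[, 1])
  }, logical(1))
  expect_gte(sum(drops), 9)
})

test_that("hairpin simulation recovers the planted hemimethylation rate", {
  cfg <- sim_config(seed = 14, hemi_rate = 0.1, reads_per_sample = 100)
  hp <- simulate_hairpin(cfg, 5, n_molecules = 4000)
  truth <- attr(hp, "truth")
  # molecule-level discordance matches h within binomial sampling error
  disc <- colMeans(truth$top != truth$bottom)
  expect_true(all(abs(disc - 0.1) <= 3 * sqrt(0.1 * 0.9 / 4000)))
})

test_that("logistic time course has the right asymptotes and midpoint", {
  cfg <- sim_config(seed = 16, noise_sd = 0, timepoints = c(0, 17.5, 100),
                    n_donors = 1)
  tc <- simulate_timecourse(cfg, signatures = list(culture = 10))
  v <- tc$beta$values
  tr <- tc$truth
  # far below / above the switch: close to start / end levels
  expect_equal(unname(v[, 1]), tr$start, tolerance = 2e-4)
  expect_equal(unname(v[, 3]), tr$end, tolerance = 1e-6)
  # symmetric logistic at t0: exactly the midpoint
  expect_equal(unname(v[, 2]), (tr$start + tr$end) / 2, tolerance = 1e-9)
})

test_that("synthetic FASTQ reads are callable end to end", {
  amp <- toy_amplicon()
  cfg <- sim_config(seed = 18, reads_per_sample = 120)
  rps <- simulate_reads(cfg, amp, 6)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_reads_fastq(rps, amp, fq)
  called <- call_read_patterns(fq, amp)
  expect_identical(called$states, rps$states)
  expect_identical(called$counts, rps$counts)
})
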