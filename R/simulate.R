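#' Simulation configuration
#'
#' One configuration object drives every generator. A single root `seed`
#' spawns deterministic per-component substreams, so each generator is a pure
#' function of the config (bit-reproducible), and modules can be re-run
#' independently with identical outputs.
#'
#' Defaults describe a typical long-term-culture study: a cohort of 24
#' samples at passages 2-13 from two donors; 200 array CpGs of which 10 drift
#' hypermethylated and 10 hypomethylated at 0.02 beta per passage with 0.01
#' beta noise; amplicon reads at 2000 per sample; and a reprogramming switch
#' centred between day 15 and day 20.
#'
#' @param seed integer root seed (< 2^31).
#' @param n_cpgs total CpGs in a simulated cohort matrix.
#' @param n_drift_hyper,n_drift_hypo numbers of drifting CpGs per direction.
#' @param slope_range range (min, max) of |drift slope|, beta per passage.
#' @param noise_sd Gaussian beta noise s.d.
#' @param passages integer passages of the cohort samples.
#' @param reads_per_sample amplicon reads simulated per sample.
#' @param model read-level generative model: `"independent_drift"` (each CpG
#'   an independent Bernoulli of its drift line) or `"targeted_writer"` (a
#'   latent all-or-none block state flipped per CpG with `writer_error`).
#' @param writer_error per-CpG flip probability of the targeted-writer model.
#' @param read_slope_range range of |per-CpG read-level drift slope|.
#' @param n_clones,epimutation_rate,bottleneck_frac clonal-culture parameters:
#'   founding clones, per-CpG pattern mutation probability per passage, and
#'   fraction of cells sampled through each passage bottleneck.
#' @param n_cells cell population size of the clonal simulation.
#' @param hemi_rate per-CpG probability that the bottom strand state differs
#'   from the top strand (hemimethylation).
#' @param umi_length,pcr_duplication_mean,umi_error_rate hairpin parameters:
#'   UMI length (nt), mean PCR duplicates per molecule, per-base UMI
#'   substitution error rate.
#' @param switch_day,tau reprogramming logistic switch midpoint (days) and
#'   time scale.
#' @param timepoints days sampled in a reprogramming time course.
#' @param n_donors donors per time course.
#' @return List of class `SimConfig`.
#' @export
sim_config <- function(seed,
                       n_cpgs = 200, n_drift_hyper = 10, n_drift_hypo = 10,
                       slope_range = c(0.02, 0.02), noise_sd = 0.01,
                       passages = rep(2:13, 2),
                       reads_per_sample = 2000,
                       model = c("independent_drift", "targeted_writer"),
                       writer_error = 0.05,
                       read_slope_range = c(0.008, 0.015),
                       n_clones = 100, epimutation_rate = 0.01,
                       bottleneck_frac = 0.1, n_cells = 10000,
                       hemi_rate = 0.05,
                       umi_length = 10, pcr_duplication_mean = 4,
                       umi_error_rate = 0.005,
                       switch_day = 17.5, tau = 2,
                       timepoints = c(0, 1, 3, 7, 11, 15, 20, 28, 35, 42, 49),
                       n_donors = 3) {
  model <- match.arg(model)
  probs <- c(writer_error = writer_error, epimutation_rate = epimutation_rate,
             bottleneck_frac = bottleneck_frac, hemi_rate = hemi_rate,
             umi_error_rate = umi_error_rate)
  if (any(probs < 0 | probs > 1))
    stop("probability parameter(s) outside [0,1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "))
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer")
  rm(probs)
  structure(as.list(environment()), class = "SimConfig")
}

# deterministic substream seed from the root seed and a component label
substream <- function(cfg, ...) {
  label <- paste(c(...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147480009
  as.integer((abs(cfg$seed) * 7919 + h) %% 2147480009)
}

clip01 <- function(x, eps = 0) pmin(pmax(x, eps), 1 - eps)

#' Simulate a culture-expansion cohort of beta profiles
#'
#' Generates a CpG x sample beta matrix in which drifting CpGs change
#' linearly with passage number (hypermethylating CpGs start low and gain,
#' hypomethylating CpGs start high and lose methylation) under Gaussian
#' noise, while the remaining CpGs are stable. Values are clipped to \[0,1\].
#' Ground-truth slopes are returned for recovery tests.
#'
#' @param cfg a `SimConfig`.
#' @return List: `beta` (a `BetaMatrix`), `sheet` (a `SampleSheet`), `truth`
#'   (data.frame of `cpg_id`, `slope`, `baseline`, `drifting`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  n_s <- length(cfg$passages)
  n_drift <- cfg$n_drift_hyper + cfg$n_drift_hypo
  if (n_drift > cfg$n_cpgs) stop("more drifting CpGs than CpGs")
  withr::with_seed(substream(cfg, "cohort"), {
    ids <- sprintf("cg%07d", seq_len(cfg$n_cpgs))
    slopes <- numeric(cfg$n_cpgs)
    drift_idx <- seq_len(n_drift)
    mag <- stats::runif(n_drift, cfg$slope_range[1], cfg$slope_range[2])
    sign_v <- rep(c(1, -1), c(cfg$n_drift_hyper, cfg$n_drift_hypo))
    slopes[drift_idx] <- mag * sign_v
    baseline <- stats::runif(cfg$n_cpgs, 0.05, 0.95)
    # keep drift inside [0,1] over the passage range
    pmax_p <- max(cfg$passages)
    baseline[drift_idx][sign_v > 0] <-
      stats::runif(cfg$n_drift_hyper, 0.05, 0.9 - cfg$slope_range[2] * pmax_p)
    baseline[drift_idx][sign_v < 0] <-
      stats::runif(cfg$n_drift_hypo, 0.1 + cfg$slope_range[2] * pmax_p, 0.95)
    mu <- baseline + outer(slopes, cfg$passages)
    eps <- matrix(stats::rnorm(cfg$n_cpgs * n_s, 0, cfg$noise_sd),
                  nrow = cfg$n_cpgs)
    v <- clip01(mu + eps)
    dimnames(v) <- list(ids, sprintf("S%02d", seq_len(n_s)))
    sheet <- sample_sheet(colnames(v), cfg$passages,
                          donor = paste0("D", rep_len(1:2, n_s)),
                          cell_type = "MSC")
    list(beta = beta_matrix(v),
         sheet = sheet,
         truth = data.frame(cpg_id = ids, slope = slopes, baseline = baseline,
                            drifting = seq_len(cfg$n_cpgs) %in% drift_idx,
                            stringsAsFactors = FALSE))
  })
}

# per-CpG read-level drift lines for an amplicon, deterministic per (cfg, name)
read_drift_params <- function(cfg, n_cpgs, name = "amplicon") {
  withr::with_seed(substream(cfg, "read-params", name), {
    b <- stats::runif(n_cpgs, cfg$read_slope_range[1], cfg$read_slope_range[2]) *
      sample(c(-1, 1), n_cpgs, replace = TRUE)
    a <- ifelse(b > 0, stats::runif(n_cpgs, 0.05, 0.2),
                stats::runif(n_cpgs, 0.8, 0.95))
    list(intercepts = a, slopes = b)
  })
}

#' Simulate bisulfite amplicon reads for one sample
#'
#' Two generative models contrast stochastic drift with targeted writing:
#' under `"independent_drift"` every CpG of every read is an independent
#' Bernoulli draw from its drift line at the sample's passage; under
#' `"targeted_writer"` a latent block state (all CpGs modified or none) is
#' drawn per read and then flipped per CpG with probability `writer_error`.
#' Probabilities are clipped to \[0.001, 0.999\] before drawing.
#'
#' @param cfg a `SimConfig`.
#' @param amp an `AmpliconDef`, or an integer number of CpGs for an abstract
#'   amplicon.
#' @param passage the sample's passage number.
#' @param sample_id label for the returned set.
#' @return A `ReadPatternSet`; the generating per-CpG lines (or block
#'   probability) are attached as attribute `"truth"`.
#' @export
simulate_reads <- function(cfg, amp, passage, sample_id = sprintf("P%02d", passage)) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (inherits(amp, "AmpliconDef")) {
    n_cpgs <- length(amp$cpg_offsets); name <- amp$name
  } else {
    n_cpgs <- as.integer(amp); name <- "amplicon"
  }
  pars <- read_drift_params(cfg, n_cpgs, name)
  n <- cfg$reads_per_sample
  states <- withr::with_seed(substream(cfg, "reads", name, passage), {
    if (cfg$model == "independent_drift") {
      p <- clip01(pars$intercepts + pars$slopes * passage, eps = 0.001)
      matrix(stats::rbinom(n * n_cpgs, 1, rep(p, each = n)), nrow = n)
    } else {
      q <- clip01(0.05 + 0.015 * passage, eps = 0.001)
      z <- stats::rbinom(n, 1, q)
      flips <- matrix(stats::rbinom(n * n_cpgs, 1, cfg$writer_error), nrow = n)
      (matrix(z, nrow = n, ncol = n_cpgs) + flips) %% 2L
    }
  })
  rps <- read_pattern_set(states, amplicon = name, sample_id = sample_id)
  attr(rps, "truth") <- c(pars, list(model = cfg$model, passage = passage))
  rps
}

#' Simulate an RGB-barcoded oligoclonal culture
#'
#' Founding clones carry a heritable methylation pattern, a random 16-nt
#' barcode and an RGB colour label. Each passage, every clone's pattern
#' mutates per CpG with probability `epimutation_rate`, and the population
#' passes a bottleneck: `bottleneck_frac x n_cells` cells are drawn
#' multinomially from the current clone frequencies and regrown. Repeated
#' bottlenecks erode clonal diversity, so late passages become oligoclonal.
#'
#' @param cfg a `SimConfig`.
#' @param n_cpgs CpGs per clone pattern (default 9).
#' @param n_passages passages to follow (default 10).
#' @return List: `frequencies` (clone x passage matrix, columns sum to 1),
#'   `barcodes` (data.frame of clone, barcode, colour), `reads` (per-passage
#'   `ReadPatternSet` of `reads_per_sample` reads drawn from the clones),
#'   `patterns` (list of clone-pattern matrices per passage).
#' @export
simulate_clonal_culture <- function(cfg, n_cpgs = 9, n_passages = 10) {
  stopifnot(inherits(cfg, "SimConfig"))
  withr::with_seed(substream(cfg, "clonal"), {
    k <- cfg$n_clones
    barcodes <- data.frame(
      clone = sprintf("clone%03d", seq_len(k)),
      barcode = vapply(seq_len(k), function(i)
        paste(sample(c("A", "C", "G", "T"), 16, replace = TRUE), collapse = ""),
        character(1)),
      colour = sample(c("R", "G", "B"), k, replace = TRUE),
      stringsAsFactors = FALSE)
    pat <- matrix(stats::rbinom(k * n_cpgs, 1, 0.3), nrow = k,
                  dimnames = list(barcodes$clone, NULL))
    freq <- rep(1 / k, k)
    freqs <- matrix(NA_real_, nrow = k, ncol = n_passages,
                    dimnames = list(barcodes$clone, sprintf("P%02d", seq_len(n_passages))))
    pats <- vector("list", n_passages)
    reads <- vector("list", n_passages)
    n_draw <- max(1L, round(cfg$bottleneck_frac * cfg$n_cells))
    for (p in seq_len(n_passages)) {
      if (p > 1) {
        counts <- stats::rmultinom(1, n_draw, freq)[, 1]
        freq <- counts / sum(counts)
        flips <- matrix(stats::rbinom(k * n_cpgs, 1, cfg$epimutation_rate),
                        nrow = k)
        pat <- (pat + flips) %% 2L
      }
      freqs[, p] <- freq
      pats[[p]] <- pat
      draw <- stats::rmultinom(1, cfg$reads_per_sample, freq)[, 1]
      reads[[p]] <- read_pattern_set(
        pat[rep(seq_len(k), draw), , drop = FALSE],
        amplicon = "clonal", sample_id = sprintf("P%02d", p))
    }
    list(frequencies = freqs, barcodes = barcodes,
         reads = stats::setNames(reads, colnames(freqs)),
         patterns = stats::setNames(pats, colnames(freqs)))
  })
}

#' Simulate hairpin bisulfite molecules with UMIs and PCR duplication
#'
#' Each molecule's top strand is drawn as in [simulate_reads()]; the bottom
#' strand copies the top with per-CpG flip probability `hemi_rate`. Each
#' molecule receives a random UMI and is observed `1 + Poisson(mean - 1)`
#' times (PCR duplicates), with per-base UMI substitution errors at
#' `umi_error_rate`.
#'
#' @param cfg a `SimConfig`.
#' @param amp an `AmpliconDef` or an integer number of CpGs.
#' @param passage passage number of the sample (default 5).
#' @param n_molecules original molecules to simulate (default
#'   `reads_per_sample`).
#' @return A `HairpinReads` of all duplicated reads; attribute `"truth"`
#'   carries the molecule-level states and UMIs before duplication.
#' @export
simulate_hairpin <- function(cfg, amp, passage = 5,
                             n_molecules = cfg$reads_per_sample) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (inherits(amp, "AmpliconDef")) {
    n_cpgs <- length(amp$cpg_offsets); name <- amp$name
  } else {
    n_cpgs <- as.integer(amp); name <- "amplicon"
  }
  pars <- read_drift_params(cfg, n_cpgs, name)
  withr::with_seed(substream(cfg, "hairpin", name, passage), {
    p <- clip01(pars$intercepts + pars$slopes * passage, eps = 0.001)
    top <- matrix(stats::rbinom(n_molecules * n_cpgs, 1, rep(p, each = n_molecules)),
                  nrow = n_molecules)
    flips <- matrix(stats::rbinom(n_molecules * n_cpgs, 1, cfg$hemi_rate),
                    nrow = n_molecules)
    bottom <- (top + flips) %% 2L
    umis <- vapply(seq_len(n_molecules), function(i)
      paste(sample(c("A", "C", "G", "T"), cfg$umi_length, replace = TRUE),
            collapse = ""), character(1))
    dup <- 1L + stats::rpois(n_molecules, max(0, cfg$pcr_duplication_mean - 1))
    rows <- rep(seq_len(n_molecules), dup)
    obs_umi <- umis[rows]
    if (cfg$umi_error_rate > 0) {
      obs_umi <- vapply(obs_umi, function(u) {
        ch <- strsplit(u, "")[[1]]
        err <- stats::runif(length(ch)) < cfg$umi_error_rate
        if (any(err))
          ch[err] <- vapply(ch[err], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    out <- hairpin_reads(obs_umi, top[rows, , drop = FALSE],
                         bottom[rows, , drop = FALSE])
    attr(out, "truth") <- list(umis = umis, top = top, bottom = bottom,
                               duplication = dup)
    out
  })
}

#' Simulate a reprogramming time course of signature betas
#'
#' Every CpG moves from a start beta to an end beta along a shared logistic
#' switch: beta(t) = start + (end - start) * logistic((t - switch_day) / tau),
#' plus Gaussian noise, for each donor. Culture-associated CpGs that are
#' hypomethylated in expanded cells re-methylate through the switch;
#' signatures passed in share the same switch day, which is what makes their
#' trajectories nearly perfectly correlated.
#'
#' @param cfg a `SimConfig`.
#' @param signatures named list: signature name -> number of CpGs, or a list
#'   of `SignatureSet` objects (their CpG counts are used; fresh CpG ids are
#'   generated). Default: culture (40), age (20), pluripotency (30).
#' @return List: `beta` (a `BetaMatrix` over day x donor samples), `sheet`
#'   (a `SampleSheet` with `timepoint_days`), `signatures` (list of
#'   `SignatureSet` naming the simulated CpGs), `truth` (per-CpG start/end).
#' @export
simulate_timecourse <- function(cfg,
                                signatures = list(culture = 40, age = 20,
                                                  pluripotency = 30)) {
  stopifnot(inherits(cfg, "SimConfig"))
  sizes <- vapply(signatures, function(x)
    if (inherits(x, "SignatureSet")) length(x$cpgs) else as.integer(x),
    integer(1))
  n_cpg <- sum(sizes)
  withr::with_seed(substream(cfg, "timecourse"), {
    ids <- sprintf("tc%05d", seq_len(n_cpg))
    sig_of <- rep(names(sizes), sizes)
    start <- stats::runif(n_cpg, 0.05, 0.35)
    end <- stats::runif(n_cpg, 0.65, 0.95)
    flip <- stats::runif(n_cpg) < 0.5   # half the CpGs switch downwards
    tmp <- start[flip]; start[flip] <- end[flip]; end[flip] <- tmp
    grid <- expand.grid(day = cfg$timepoints, donor = seq_len(cfg$n_donors))
    smp <- sprintf("d%d_day%g", grid$donor, grid$day)
    lg <- stats::plogis((grid$day - cfg$switch_day) / cfg$tau)
    mu <- outer(end - start, lg) + start
    v <- clip01(mu + matrix(stats::rnorm(length(mu), 0, cfg$noise_sd),
                            nrow = n_cpg))
    dimnames(v) <- list(ids, smp)
    sheet <- sample_sheet(smp, passage = 0,
                          donor = paste0("D", grid$donor),
                          cell_type = "fibroblast",
                          timepoint_days = grid$day)
    sigs <- lapply(unique(sig_of), function(nm)
      signature_set(nm, ids[sig_of == nm]))
    list(beta = beta_matrix(v), sheet = sheet,
         signatures = stats::setNames(sigs, unique(sig_of)),
         truth = data.frame(cpg_id = ids, signature = sig_of,
                            start = start, end = end, stringsAsFactors = FALSE))
  })
}

#' Write simulated amplicon reads as FASTQ
#'
#' Renders a pattern set's reads as bisulfite-converted sequences of the
#' amplicon reference (non-CpG Cs converted to T; CpG Cs kept as C when
#' methylated, converted to T otherwise) and writes them with uniform quality
#' to a FASTQ file. Useful to exercise [call_read_patterns()] end to end.
#'
#' @param rps a `ReadPatternSet`.
#' @param amp the matching `AmpliconDef`.
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(rps, amp, path) {
  stopifnot(inherits(rps, "ReadPatternSet"), inherits(amp, "AmpliconDef"))
  states <- expand_states(rps)
  ref <- strsplit(amp$reference_seq, "")[[1]]
  is_cpg_c <- rep(FALSE, length(ref))
  is_cpg_c[amp$cpg_offsets + 1L] <- TRUE
  conv <- ref
  conv[conv == "C" & !is_cpg_c] <- "T"
  lines <- character(4L * nrow(states))
  for (i in seq_len(nrow(states))) {
    sq <- conv
    st <- states[i, ]
    sq[amp$cpg_offsets + 1L] <- ifelse(is.na(st), "N", ifelse(st == 1, "C", "T"))
    lines[4 * i - 3] <- sprintf("@%s_read%d", rps$sample_id, i)
    lines[4 * i - 2] <- paste(sq, collapse = "")
    lines[4 * i - 1] <- "+"
    lines[4 * i] <- strrep("I", length(sq))
  }
  writeLines(lines, path)
  invisible(path)
}
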