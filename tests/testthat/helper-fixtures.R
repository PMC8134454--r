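# shared fixture builders; everything is generated in code

toy_beta <- function(values, cpgs = NULL, samples = NULL, ann = NULL) {
  m <- as.matrix(values)
  rownames(m) <- cpgs %||% sprintf("cg%02d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  beta_matrix(m, cpg_annotation = ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_amplicon <- function() {
  # 24 bp, CpGs at 0-based offsets 1, 6, 11, 17, 20; primer ACGTT at 0
  amplicon_def("toy", "ACGTTACGGATCGATTACGCCGAT", "ACGTT", "CGAT",
               c(1, 6, 11, 17, 20))
}

# cohort where passage is an exact linear function of two CpGs plus noise
linear_cohort <- function(n = 30, sd = 0, seed = 42) {
  withr::with_seed(seed, {
    ba <- stats::runif(n, 0.1, 0.9)
    bb <- stats::runif(n, 0.1, 0.9)
    decoys <- matrix(stats::runif(4 * n), nrow = 4)
    v <- rbind(ba, bb, decoys)
    rownames(v) <- c("cg_a", "cg_b", paste0("cg_d", 1:4))
    colnames(v) <- paste0("s", seq_len(n))
    pass <- 10 + 5 * ba - 20 * bb + stats::rnorm(n, 0, sd)
    pass <- pass - min(pass)
    list(beta = beta_matrix(v),
         sheet = sample_sheet(colnames(v), pass),
         coef = c(cg_a = 5, cg_b = -20))
  })
}
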