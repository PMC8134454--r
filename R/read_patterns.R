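#' Pattern spectrum of an amplicon's reads
#'
#' The frequency distribution of complete methylation patterns (epialleles)
#' among a sample's reads. Reads with any missing CpG state are excluded from
#' the spectrum (they still contribute to likelihood-based prediction, see
#' [predict_read()]); the number excluded is reported.
#'
#' @param rps a `ReadPatternSet`.
#' @return List of class `PatternSpectrum`: `amplicon`, `sample_id`,
#'   `frequencies` (named by pattern string, summing to 1), `total_reads`,
#'   `n_excluded`.
#' @export
pattern_spectrum <- function(rps) {
  stopifnot(inherits(rps, "ReadPatternSet"))
  complete <- rowSums(is.na(rps$states)) == 0
  if (!any(complete))
    stop("no complete reads (every read has missing CpG states)")
  counts <- rps$counts[complete]
  freq <- counts / sum(counts)
  names(freq) <- rownames(rps$states)[complete]
  structure(list(amplicon = rps$amplicon, sample_id = rps$sample_id,
                 frequencies = freq, total_reads = sum(counts),
                 n_excluded = sum(rps$counts[!complete])),
            class = "PatternSpectrum")
}

#' @export
print.PatternSpectrum <- function(x, ...) {
  cat(sprintf("PatternSpectrum '%s' sample '%s': %d patterns over %d reads (H' = %.3f)\n",
              x$amplicon, x$sample_id, length(x$frequencies), x$total_reads,
              shannon_index(x)))
  invisible(x)
}

#' Shannon diversity index
#'
#' H' = -sum p_i ln(p_i) in nats, with 0 ln 0 taken as 0. Accepts a
#' `PatternSpectrum` or a raw vector of proportions (or counts, which are
#' normalized). H' is 0 for a single pattern and ln(n) for a uniform
#' distribution over n patterns; used both for epiallele-pattern diversity and
#' for clonal (barcode) diversity.
#'
#' @param x a `PatternSpectrum` or numeric vector of proportions/counts.
#' @return H' in nats.
#' @export
shannon_index <- function(x) {
  p <- if (inherits(x, "PatternSpectrum")) x$frequencies else as.numeric(x)
  if (any(p < 0)) stop("proportions must be non-negative")
  s <- sum(p)
  if (s <= 0) stop("proportions sum to zero")
  p <- p / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Pairwise correlation of methylation states at neighboring CpGs
#'
#' Pools reads (optionally across samples) and computes the Pearson
#' correlation between the binary methylation states of every CpG pair. Under
#' stochastic, independent drift these correlations vanish with read depth;
#' a targeted epigenetic writer coherently modifying a region produces high
#' correlations between all neighbors. CpGs with zero state variance yield
#' undefined entries and are flagged.
#'
#' @param sets a `ReadPatternSet` or list of them (same amplicon).
#' @return CpG x CpG correlation matrix with attribute `zero_variance`
#'   (indices of flagged CpGs). Diagonal is 1 for defined CpGs.
#' @export
neighbor_correlation <- function(sets) {
  if (inherits(sets, "ReadPatternSet")) sets <- list(sets)
  states <- do.call(rbind, lapply(sets, expand_states))
  if (nrow(states) < 2) stop("need >= 2 reads for neighbor correlation")
  suppressWarnings(
    cc <- stats::cor(states, use = "pairwise.complete.obs"))
  vars <- apply(states, 2, function(x) stats::var(x, na.rm = TRUE))
  zv <- which(is.na(vars) | vars == 0)
  cc[zv, ] <- NA_real_; cc[, zv] <- NA_real_
  diag(cc)[setdiff(seq_len(ncol(cc)), zv)] <- 1
  dimnames(cc) <- list(paste0("cpg", seq_len(ncol(states))),
                       paste0("cpg", seq_len(ncol(states))))
  attr(cc, "zero_variance") <- as.integer(zv)
  cc
}

#' Per-CpG correlation of read-level methylation with passage
#'
#' For each CpG of an amplicon, the sample-level methylated fraction (from
#' reads) is correlated with passage number across samples.
#'
#' @param sets list of `ReadPatternSet` objects, one per sample.
#' @param s a `SampleSheet` covering the sets' sample ids.
#' @return Numeric vector of Pearson correlations, one per CpG (`NA` where
#'   undefined).
#' @export
cpg_passage_correlation <- function(sets, s) {
  if (inherits(sets, "ReadPatternSet")) sets <- list(sets)
  ids <- vapply(sets, function(r) r$sample_id, character(1))
  idx <- match(ids, s$sample_id)
  if (anyNA(idx))
    stop("read-pattern sample(s) absent from sample sheet: ",
         paste(ids[is.na(idx)], collapse = ", "))
  if (length(sets) < 3) stop("need >= 3 samples to correlate with passage")
  p <- s$passage[idx]
  if (length(unique(p)) < 2) stop("all passage numbers identical")
  fr <- do.call(rbind, lapply(sets, methylation_fractions))
  apply(fr, 2, function(b) {
    ok <- !is.na(b)
    if (sum(ok) < 3 || stats::sd(b[ok]) == 0 || stats::sd(p[ok]) == 0) return(NA_real_)
    stats::cor(b[ok], p[ok])
  })
}

#' Fit the per-CpG linear models behind the single-read passage predictor
#'
#' Regresses each CpG's sample-level methylated fraction on passage number
#' across training samples. The fitted lines give, for any candidate passage
#' p, the expected methylation probability of each CpG, from which a read's
#' likelihood over the passage grid is computed.
#'
#' @param sets list of training `ReadPatternSet` objects, one per sample.
#' @param s a `SampleSheet` with passages for those samples.
#' @param max_passage upper end of the passage grid (default 50, i.e. grid
#'   0..50).
#' @param clip_eps probability floor/ceiling applied before taking logs
#'   (default 0.001); prevents a single incompatible CpG from annihilating a
#'   read's likelihood.
#' @return List of class `SingleReadModel`: `intercepts`, `slopes` (per CpG),
#'   `passage_grid`, `clip_eps`.
#' @export
fit_single_read_model <- function(sets, s, max_passage = 50, clip_eps = 0.001) {
  if (clip_eps <= 0 || clip_eps >= 0.5) stop("'clip_eps' must lie in (0, 0.5)")
  if (inherits(sets, "ReadPatternSet")) sets <- list(sets)
  ids <- vapply(sets, function(r) r$sample_id, character(1))
  idx <- match(ids, s$sample_id)
  if (anyNA(idx))
    stop("training sample(s) absent from sample sheet: ",
         paste(ids[is.na(idx)], collapse = ", "))
  p <- s$passage[idx]
  if (length(sets) < 3) stop("need >= 3 training samples")
  if (length(unique(p)) < 2) stop("training passages span < 2 distinct values")
  fr <- do.call(rbind, lapply(sets, methylation_fractions))
  ab <- apply(fr, 2, function(b) {
    ok <- !is.na(b)
    slope <- stats::cov(b[ok], p[ok]) / stats::var(p[ok])
    c(intercept = mean(b[ok]) - slope * mean(p[ok]), slope = slope)
  })
  structure(list(intercepts = unname(ab["intercept", ]),
                 slopes = unname(ab["slope", ]),
                 passage_grid = 0:max_passage,
                 clip_eps = clip_eps),
            class = "SingleReadModel")
}

#' @export
print.SingleReadModel <- function(x, ...) {
  cat(sprintf("SingleReadModel: %d CpGs, passage grid %d..%d, clip_eps = %g\n",
              length(x$slopes), min(x$passage_grid), max(x$passage_grid),
              x$clip_eps))
  invisible(x)
}

# grid x cpg matrix of clipped per-CpG methylation probabilities
.srm_probs <- function(model) {
  M <- outer(model$passage_grid, model$slopes) +
    matrix(model$intercepts, nrow = length(model$passage_grid),
           ncol = length(model$slopes), byrow = TRUE)
  pmin(pmax(M, model$clip_eps), 1 - model$clip_eps)
}

#' Assign a single read to its most likely passage
#'
#' Treats the read's binary CpG states as independent Bernoulli draws with
#' per-CpG probabilities given by the fitted lines at each candidate passage,
#' and maximizes the log-likelihood over the integer passage grid. Missing
#' states are skipped; ties go to the smallest passage.
#'
#' @param model a `SingleReadModel`.
#' @param pattern integer vector of 0/1/`NA` aligned to the model's CpGs.
#' @return List: `best_passage` (integer, `NA` if every state is missing) and
#'   `loglik` (vector over the passage grid).
#' @export
predict_read <- function(model, pattern) {
  stopifnot(inherits(model, "SingleReadModel"))
  if (length(pattern) != length(model$slopes))
    stop(sprintf("pattern has %d states but model has %d CpGs",
                 length(pattern), length(model$slopes)))
  obs <- which(!is.na(pattern))
  if (length(obs) == 0)
    return(list(best_passage = NA_integer_,
                loglik = rep(NA_real_, length(model$passage_grid))))
  M <- .srm_probs(model)[, obs, drop = FALSE]
  x <- pattern[obs]
  ll <- as.numeric(log(M) %*% x + log1p(-M) %*% (1 - x))
  list(best_passage = model$passage_grid[which.max(ll)], loglik = ll)
}

#' Mean single-read passage prediction for a sample
#'
#' Predicts every read of the sample with [predict_read()] and averages the
#' per-read best passages (weighted by pattern counts). The per-pattern
#' predictions and the likelihood matrix are retained for heatmap-style
#' summaries of read-level heterogeneity.
#'
#' @param model a `SingleReadModel`.
#' @param rps a `ReadPatternSet`.
#' @return List: `mean_passage`, `per_pattern` (data.frame of pattern, count,
#'   best_passage), `loglik` (patterns x grid matrix), `n_unpredictable`.
#' @export
predict_sample_from_reads <- function(model, rps) {
  stopifnot(inherits(rps, "ReadPatternSet"))
  preds <- lapply(seq_len(nrow(rps$states)), function(i)
    predict_read(model, rps$states[i, ]))
  best <- vapply(preds, function(p) as.numeric(p$best_passage)[1], numeric(1))
  ll <- do.call(rbind, lapply(preds, function(p) p$loglik))
  rownames(ll) <- rownames(rps$states)
  ok <- !is.na(best)
  if (!any(ok)) stop("no predictable reads (all states missing)")
  list(mean_passage = sum(best[ok] * rps$counts[ok]) / sum(rps$counts[ok]),
       per_pattern = data.frame(pattern = rownames(rps$states),
                                count = rps$counts, best_passage = best,
                                stringsAsFactors = FALSE, row.names = NULL),
       loglik = ll,
       n_unpredictable = sum(rps$counts[!ok]))
}
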