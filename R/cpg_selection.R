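#' Correlate per-CpG methylation with passage number
#'
#' For every CpG, computes the Pearson correlation of beta values with passage
#' number across samples, together with the ordinary-least-squares slope and
#' intercept of beta on passage. CpGs with fewer than 3 complete samples or
#' zero beta variance get an undefined correlation (`NA`) and are flagged in
#' the `undefined` column; downstream filters exclude them.
#'
#' @param m a `BetaMatrix`.
#' @param s a `SampleSheet` covering the matrix's samples.
#' @param target column of `s` to correlate against (default `"passage"`).
#' @return A `data.frame` with columns `cpg_id`, `r`, `slope`, `intercept`,
#'   `n`, `direction` (`"hyper"`/`"hypo"`/`"none"`), `undefined`.
#' @export
correlate_cpgs <- function(m, s, target = "passage") {
  stopifnot(inherits(m, "BetaMatrix"))
  p <- if (target == "passage") passages_for(m, s) else
    stats::setNames(s[[target]][match(sample_ids(m), s$sample_id)], sample_ids(m))
  if (length(unique(p[!is.na(p)])) < 2)
    stop("all passage numbers identical; correlation undefined")
  v <- m$values
  res <- lapply(seq_len(nrow(v)), function(i) {
    b <- v[i, ]
    ok <- !is.na(b) & !is.na(p)
    n <- sum(ok)
    if (n < 3 || stats::sd(b[ok]) == 0 || stats::sd(p[ok]) == 0)
      return(c(r = NA_real_, slope = NA_real_, intercept = NA_real_, n = n))
    r <- stats::cor(b[ok], p[ok])
    slope <- stats::cov(b[ok], p[ok]) / stats::var(p[ok])
    c(r = r, slope = slope, intercept = mean(b[ok]) - slope * mean(p[ok]), n = n)
  })
  res <- do.call(rbind, res)
  out <- data.frame(cpg_id = cpg_ids(m), r = res[, "r"], slope = res[, "slope"],
                    intercept = res[, "intercept"], n = as.integer(res[, "n"]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$direction <- ifelse(is.na(out$slope), "none",
                          ifelse(out$slope > 0, "hyper",
                                 ifelse(out$slope < 0, "hypo", "none")))
  out$undefined <- is.na(out$r)
  out
}

#' Write a CpG statistics table to TSV
#' @param stats data.frame from [correlate_cpgs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cpg_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select culture-associated candidate CpGs
#'
#' Splits CpGs into hypermethylated (`r > r_cut`) and hypomethylated
#' (`r < -r_cut`) candidates; optionally also requires `|slope| > slope_cut`
#' (beta per passage) and keeps only the `top_n` CpGs per direction ranked by
#' `|r|`. Undefined correlations are excluded.
#'
#' @param stats data.frame from [correlate_cpgs()].
#' @param r_cut Pearson-correlation threshold in (0, 1).
#' @param slope_cut optional absolute-slope threshold.
#' @param top_n optional cap per direction.
#' @return List of class `CandidateSet`: `hyper` and `hypo` (CpG ids ordered
#'   by decreasing `|r|`) plus the thresholds used.
#' @export
filter_candidates <- function(stats, r_cut, slope_cut = NULL, top_n = NULL) {
  if (r_cut <= 0 || r_cut >= 1) stop("'r_cut' must lie in (0, 1)")
  ok <- !stats$undefined
  pass_slope <- if (is.null(slope_cut)) rep(TRUE, nrow(stats))
                else !is.na(stats$slope) & abs(stats$slope) > slope_cut
  pick <- function(cond) {
    sel <- stats[ok & cond & pass_slope, , drop = FALSE]
    sel <- sel[order(-abs(sel$r), sel$cpg_id), , drop = FALSE]
    if (!is.null(top_n)) sel <- utils::head(sel, top_n)
    sel$cpg_id
  }
  structure(list(hyper = pick(stats$r > r_cut),
                 hypo = pick(stats$r < -r_cut),
                 r_cut = r_cut, slope_cut = slope_cut, top_n = top_n),
            class = "CandidateSet")
}

#' @export
print.CandidateSet <- function(x, ...) {
  cat(sprintf("CandidateSet: %d hypermethylated, %d hypomethylated CpGs (r_cut = %g%s%s)\n",
              length(x$hyper), length(x$hypo), x$r_cut,
              if (!is.null(x$slope_cut)) sprintf(", slope_cut = %g", x$slope_cut) else "",
              if (!is.null(x$top_n)) sprintf(", top_n = %d", x$top_n) else ""))
  invisible(x)
}

#' Write / read a CandidateSet (JSON)
#' @param cs a `CandidateSet`.
#' @param path JSON file path.
#' @return `read_candidate_set`: a `CandidateSet`.
#' @export
write_candidate_set <- function(cs, path) {
  jsonlite::write_json(unclass(cs), path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_candidate_set
#' @export
read_candidate_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(hyper = as.character(obj$hyper), hypo = as.character(obj$hypo),
                 r_cut = obj$r_cut, slope_cut = obj$slope_cut,
                 top_n = obj$top_n),
            class = "CandidateSet")
}

#' Exhaustive best-subset passage model over candidate CpGs
#'
#' Enumerates every combination of `n_hyper` hypermethylated and `n_hypo`
#' hypomethylated candidates, fits passage on each subset's beta values by
#' OLS, and returns the subset with the smallest residual sum of squares
#' (equivalently the largest R^2). Ties are broken by lexicographic order of
#' the sorted CpG ids; singular designs are skipped with a warning.
#'
#' @param m a `BetaMatrix`.
#' @param s a `SampleSheet`.
#' @param candidates a `CandidateSet`.
#' @param n_hyper,n_hypo subset sizes per direction (default 2 + 2).
#' @return The winning `PassageModel`; its `subset_r2` attribute carries the
#'   training R^2 (1 - RSS/SST).
#' @export
best_subset_model <- function(m, s, candidates, n_hyper = 2, n_hypo = 2) {
  stopifnot(inherits(candidates, "CandidateSet"))
  if (length(candidates$hyper) < n_hyper || length(candidates$hypo) < n_hypo)
    stop(sprintf("need >= %d hyper and >= %d hypo candidates (have %d / %d)",
                 n_hyper, n_hypo, length(candidates$hyper), length(candidates$hypo)))
  y <- passages_for(m, s)
  n_par <- n_hyper + n_hypo
  if (length(y) < n_par + 2)
    stop(sprintf("need >= %d samples for a %d-CpG subset model", n_par + 2, n_par))
  hy <- utils::combn(sort(candidates$hyper), n_hyper, simplify = FALSE)
  ho <- utils::combn(sort(candidates$hypo), n_hypo, simplify = FALSE)
  sst <- sum((y - mean(y))^2)
  best <- NULL; best_rss <- Inf; best_key <- NULL
  for (a in hy) for (b in ho) {
    cpgs <- sort(c(a, b))
    X <- cbind(1, t(m$values[cpgs, , drop = FALSE]))
    if (anyNA(X)) next
    fit <- stats::lm.fit(X, as.numeric(y))
    if (fit$rank < ncol(X)) {
      warning("skipping singular subset: ", paste(cpgs, collapse = ", "))
      next
    }
    rss <- sum(fit$residuals^2)
    key <- paste(cpgs, collapse = "|")
    if (rss < best_rss - 1e-12 ||
        (abs(rss - best_rss) <= 1e-12 && !is.null(best_key) && key < best_key)) {
      best_rss <- rss; best_key <- key
      best <- passage_model(cpgs, fit$coefficients[-1], fit$coefficients[1],
                            provenance = sprintf(
                              "best %d+%d subset of %d hyper x %d hypo candidates",
                              n_hyper, n_hypo, length(candidates$hyper),
                              length(candidates$hypo)))
    }
  }
  if (is.null(best)) stop("no fittable subset found")
  attr(best, "subset_r2") <- 1 - best_rss / sst
  best
}

#' Flag outlier samples of a passage regression
#'
#' Bonferroni-adjusted test on the externally studentized residuals of the
#' passage-on-betas regression (the standard linear-model outlier test).
#' Samples with adjusted p < `alpha` are returned.
#'
#' @param m a `BetaMatrix`.
#' @param s a `SampleSheet`.
#' @param model a `PassageModel` naming the regression CpGs.
#' @param alpha significance level (default 0.05).
#' @return Character vector of outlier sample ids (possibly empty).
#' @export
detect_outlier_samples <- function(m, s, model, alpha = 0.05) {
  stopifnot(inherits(model, "PassageModel"))
  y <- passages_for(m, s)
  X <- t(m$values[model$cpg_ids, , drop = FALSE])
  n <- nrow(X)
  if (n < length(model$cpg_ids) + 3)
    stop("too few samples for an outlier test on this model")
  if (alpha <= 0) return(character(0))
  df <- data.frame(..passage = as.numeric(y), X, check.names = FALSE)
  rownames(df) <- sample_ids(m)
  fit <- stats::lm(..passage ~ ., data = df)
  ot <- car::outlierTest(fit, cutoff = alpha, n.max = n, order = TRUE)
  flagged <- names(ot$bonf.p)[!is.na(ot$bonf.p) & ot$bonf.p < alpha]
  flagged
}

#' Estimate 5-hydroxymethylcytosine from paired BS / OxBS profiles
#'
#' Oxidative bisulfite (OxBS) reads out only 5mC, while conventional bisulfite
#' (BS) reads 5mC + 5hmC; the per-CpG, per-sample difference BS - OxBS
#' therefore estimates the 5hmC fraction. Estimates may be negative through
#' measurement noise and are reported as-is.
#'
#' @param bs,oxbs `BetaMatrix` objects with identical CpG and sample ids.
#' @return Numeric matrix of 5hmC estimates (CpG x sample).
#' @export
estimate_hydroxymethylation <- function(bs, oxbs) {
  stopifnot(inherits(bs, "BetaMatrix"), inherits(oxbs, "BetaMatrix"))
  dcpg <- c(setdiff(cpg_ids(bs), cpg_ids(oxbs)), setdiff(cpg_ids(oxbs), cpg_ids(bs)))
  dsmp <- c(setdiff(sample_ids(bs), sample_ids(oxbs)),
            setdiff(sample_ids(oxbs), sample_ids(bs)))
  if (length(dcpg) > 0 || length(dsmp) > 0)
    stop("BS / OxBS matrices do not match; differing ids: ",
         paste(utils::head(c(dcpg, dsmp), 10), collapse = ", "))
  bs$values - oxbs$values[cpg_ids(bs), sample_ids(bs), drop = FALSE]
}

#' Mean 5hmC level over a CpG set
#' @param hmc matrix from [estimate_hydroxymethylation()].
#' @param cpgs CpG ids to average over (default: all).
#' @return Mean 5hmC estimate (single number), `NA`s removed.
#' @export
hydroxymethylation_summary <- function(hmc, cpgs = rownames(hmc)) {
  miss <- setdiff(cpgs, rownames(hmc))
  if (length(miss) > 0)
    stop("CpG(s) absent from 5hmC matrix: ", paste(utils::head(miss, 10), collapse = ", "))
  mean(hmc[cpgs, , drop = FALSE], na.rm = TRUE)
}
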