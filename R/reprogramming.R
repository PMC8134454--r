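#' SignatureSet: a named CpG signature with optional univariate predictors
#'
#' A signature is a set of CpGs tracked together through a time course
#' (culture-associated, age-associated, pluripotency-associated, or custom).
#' Optionally each CpG carries a univariate linear predictor mapping its beta
#' value to a passage estimate (intercept + slope x beta), obtained by
#' regressing passage on beta in a training cohort.
#'
#' @param name signature label.
#' @param cpgs unique CpG ids.
#' @param predictors optional data.frame with columns `cpg_id`, `intercept`,
#'   `slope` (passage units / passage per beta).
#' @return An object of class `SignatureSet`.
#' @export
signature_set <- function(name, cpgs, predictors = NULL) {
  cpgs <- as.character(cpgs)
  if (anyDuplicated(cpgs)) stop("signature CpG ids must be unique")
  if (!is.null(predictors)) {
    if (!all(c("cpg_id", "intercept", "slope") %in% colnames(predictors)))
      stop("predictors need columns cpg_id, intercept, slope")
    if (!all(is.finite(predictors$intercept)) || !all(is.finite(predictors$slope)))
      stop("predictor coefficients must be finite")
  }
  structure(list(name = name, cpgs = cpgs, predictors = predictors),
            class = "SignatureSet")
}

#' @export
print.SignatureSet <- function(x, ...) {
  cat(sprintf("SignatureSet '%s': %d CpGs%s\n", x$name, length(x$cpgs),
              if (!is.null(x$predictors)) " (with univariate predictors)" else ""))
  invisible(x)
}

#' Read / write a SignatureSet (JSON)
#' @param path JSON file path.
#' @return `read_signature_set`: a `SignatureSet`.
#' @export
read_signature_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pred <- if (!is.null(obj$predictors)) as.data.frame(obj$predictors) else NULL
  signature_set(obj$name, obj$cpgs, predictors = pred)
}

#' @rdname read_signature_set
#' @param sig a `SignatureSet`.
#' @export
write_signature_set <- function(sig, path) {
  jsonlite::write_json(list(name = sig$name, cpgs = sig$cpgs,
                            predictors = sig$predictors),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Fit univariate per-CpG passage predictors
#'
#' For each CpG, regresses passage on that CpG's beta values across a training
#' cohort, giving an inverted drift line usable as a one-CpG passage
#' predictor (see [mean_univariate_passage()]).
#'
#' @param m a training `BetaMatrix`.
#' @param s a `SampleSheet`.
#' @param cpgs CpG ids to fit.
#' @return Data.frame with `cpg_id`, `intercept`, `slope`.
#' @export
fit_univariate_predictors <- function(m, s, cpgs) {
  p <- passages_for(m, s)
  miss <- setdiff(cpgs, cpg_ids(m))
  if (length(miss) > 0)
    stop("CpG(s) absent from beta matrix: ", paste(miss, collapse = ", "))
  res <- lapply(cpgs, function(cg) {
    b <- m$values[cg, ]
    ok <- !is.na(b)
    if (sum(ok) < 3 || stats::sd(b[ok]) == 0)
      stop("cannot fit univariate predictor for ", cg,
           " (too few samples or zero beta variance)")
    slope <- stats::cov(p[ok], b[ok]) / stats::var(b[ok])
    data.frame(cpg_id = cg, intercept = mean(p[ok]) - slope * mean(b[ok]),
               slope = slope, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Mean absolute methylation difference to day 0 along a time course
#'
#' For each timepoint, computes per donor the mean absolute beta difference of
#' the signature's CpGs relative to that donor's day-0 sample, then averages
#' across donors. This is the standard summary for asking when a signature is
#' reset during reprogramming.
#'
#' @param m a `BetaMatrix` over the time course samples.
#' @param s a `SampleSheet` with `timepoint_days` (and `donor`) filled in.
#' @param sig a `SignatureSet`; CpGs absent from `m` raise an error.
#' @return Data.frame: `timepoint`, `mean_abs_delta`, `n_donors`.
#' @export
signature_delta <- function(m, s, sig) {
  stopifnot(inherits(sig, "SignatureSet"))
  miss <- setdiff(sig$cpgs, cpg_ids(m))
  if (length(miss) > 0)
    stop("signature CpG(s) absent from beta matrix: ",
         paste(utils::head(miss, 10), collapse = ", "))
  info <- s[match(sample_ids(m), s$sample_id), ]
  if (anyNA(info$timepoint_days))
    stop("timepoint_days missing for some samples")
  if (!any(info$timepoint_days == 0))
    stop("no day-0 sample in the time course")
  donors <- unique(info$donor)
  v <- m$values[sig$cpgs, , drop = FALSE]
  tps <- sort(unique(info$timepoint_days))
  per_tp <- lapply(tps, function(t) {
    deltas <- vapply(donors, function(d) {
      ref_cols <- which(info$donor == d & info$timepoint_days == 0)
      cols <- which(info$donor == d & info$timepoint_days == t)
      if (length(ref_cols) == 0 || length(cols) == 0) return(NA_real_)
      ref <- rowMeans(v[, ref_cols, drop = FALSE], na.rm = TRUE)
      cur <- rowMeans(v[, cols, drop = FALSE], na.rm = TRUE)
      mean(abs(cur - ref), na.rm = TRUE)
    }, numeric(1))
    data.frame(timepoint = t, mean_abs_delta = mean(deltas, na.rm = TRUE),
               n_donors = sum(!is.na(deltas)))
  })
  do.call(rbind, per_tp)
}

#' Pearson correlation between two signature trajectories
#'
#' Quantifies whether two signatures (e.g. culture-associated and
#' pluripotency-associated) are reset along the same kinetics: the Pearson
#' correlation of their per-timepoint mean-absolute-difference series.
#' Symmetric and invariant to scaling of either series.
#'
#' @param delta_a,delta_b numeric series over the same timepoints (>= 3), or
#'   data.frames from [signature_delta()] (matched on `timepoint`).
#' @return Pearson r (`NA` with a warning when a series has zero variance).
#' @export
trajectory_correlation <- function(delta_a, delta_b) {
  val <- function(d) if (is.data.frame(d)) d$mean_abs_delta else as.numeric(d)
  if (is.data.frame(delta_a) && is.data.frame(delta_b)) {
    if (!identical(delta_a$timepoint, delta_b$timepoint))
      stop("trajectories cover different timepoints")
  }
  a <- val(delta_a); b <- val(delta_b)
  if (length(a) != length(b)) stop("series lengths differ")
  if (length(a) < 3) stop("need >= 3 timepoints")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in a trajectory; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Mean univariate passage estimate per sample
#'
#' Averages the one-CpG passage predictions (intercept_i + slope_i x beta_i)
#' over the signature's CpGs for every sample; CpGs missing in a sample are
#' skipped. Samples with no observed signature CpG are unpredictable (`NA`,
#' flagged in the `"unpredictable"` attribute).
#'
#' @param m a `BetaMatrix`.
#' @param sig a `SignatureSet` carrying univariate predictors.
#' @return Named numeric vector of mean predicted passages.
#' @export
mean_univariate_passage <- function(m, sig) {
  stopifnot(inherits(sig, "SignatureSet"))
  if (is.null(sig$predictors))
    stop("signature '", sig$name, "' carries no univariate predictors")
  pred <- sig$predictors
  present <- intersect(pred$cpg_id, cpg_ids(m))
  if (length(present) == 0)
    stop("none of the signature's predictor CpGs are in the beta matrix")
  pred <- pred[match(present, pred$cpg_id), ]
  b <- m$values[present, , drop = FALSE]
  est <- pred$intercept + pred$slope * b     # CpG x sample, recycled by column
  out <- colMeans(est, na.rm = TRUE)
  none <- colSums(!is.na(b)) == 0
  out[none] <- NA_real_
  if (any(none)) attr(out, "unpredictable") <- names(out)[none]
  out
}
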