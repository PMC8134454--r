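#' PassageModel: a multivariable linear passage predictor
#'
#' Predicted passage = intercept + sum over CpGs of coefficient x beta. Betas
#' are methylation fractions in \[0,1\]; pyrosequencing percentages must be
#' divided by 100 before use (the coefficient scale of the published model
#' makes this unambiguous: a unit swing in the TNNI3K beta moves the estimate
#' by ~39 passages).
#'
#' @param cpg_ids ordered CpG identifiers.
#' @param coefficients numeric coefficients (passages per beta unit), same
#'   length and order as `cpg_ids`.
#' @param intercept numeric intercept (passages).
#' @param provenance free-text note on how the model was obtained.
#' @return An object of class `PassageModel`.
#' @export
passage_model <- function(cpg_ids, coefficients, intercept, provenance = "") {
  if (length(cpg_ids) != length(coefficients))
    stop("one coefficient per CpG id required")
  if (!all(is.finite(coefficients)) || !is.finite(intercept))
    stop("model coefficients and intercept must be finite")
  structure(list(cpg_ids = as.character(cpg_ids),
                 coefficients = stats::setNames(as.numeric(coefficients),
                                                as.character(cpg_ids)),
                 intercept = as.numeric(intercept),
                 provenance = provenance),
            class = "PassageModel")
}

#' @export
print.PassageModel <- function(x, ...) {
  cat(sprintf("PassageModel (%d CpGs): passage = %.4f", length(x$cpg_ids), x$intercept))
  for (i in seq_along(x$cpg_ids))
    cat(sprintf(" %s %.4f*[%s]", ifelse(x$coefficients[i] < 0, "-", "+"),
                abs(x$coefficients[i]), x$cpg_ids[i]))
  cat("\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' The published four-CpG pyrosequencing passage clock
#'
#' Multivariable linear model trained on pyrosequencing beta values of four
#' culture-associated CpGs: ALOX12 (cg03762994), DOK6 (cg25968937), LTC4S
#' (cg26683398) and TNNI3K (cg05264232):
#'
#' predicted passage = 39.0341 - 10.9266 a - 0.4219 b + 5.8979 g - 38.889 d
#'
#' where a, b, g, d are the beta values (fractions) at the four CpGs in the
#' order above.
#'
#' @return A `PassageModel`.
#' @export
published_model <- function() {
  passage_model(
    cpg_ids = c("cg03762994", "cg25968937", "cg26683398", "cg05264232"),
    coefficients = c(-10.9266, -0.4219, 5.8979, -38.889),
    intercept = 39.0341,
    provenance = "published four-CpG pyrosequencing passage predictor (ALOX12, DOK6, LTC4S, TNNI3K)")
}

#' Predict passage numbers from beta values
#'
#' Applies a linear passage model to each sample of a beta matrix. Predictions
#' are not clipped: negative estimates are possible and returned as-is.
#' Samples missing a beta value at any model CpG are reported as
#' unpredictable (`NA`, listed in the `"unpredictable"` attribute) rather than
#' silently dropped.
#'
#' @param model a `PassageModel`.
#' @param m a `BetaMatrix` containing the model's CpGs.
#' @return Named numeric vector of predicted passages per sample.
#' @export
predict_passage <- function(model, m) {
  stopifnot(inherits(model, "PassageModel"), inherits(m, "BetaMatrix"))
  miss <- setdiff(model$cpg_ids, cpg_ids(m))
  if (length(miss) > 0)
    stop("model CpG(s) absent from beta matrix: ", paste(miss, collapse = ", "))
  b <- m$values[model$cpg_ids, , drop = FALSE]
  pred <- model$intercept + as.numeric(crossprod(b, model$coefficients))
  names(pred) <- sample_ids(m)
  bad <- colSums(is.na(b)) > 0
  pred[bad] <- NA_real_
  if (any(bad)) attr(pred, "unpredictable") <- names(pred)[bad]
  pred
}

#' Train a linear passage model by ordinary least squares
#'
#' Fits passage ~ beta values at the given CpGs across the samples shared by
#' the beta matrix and sample sheet.
#'
#' @param m a `BetaMatrix`.
#' @param s a `SampleSheet` with passage numbers.
#' @param cpgs CpG ids to use as predictors.
#' @param target column of `s` to regress on (default `"passage"`; e.g.
#'   `"cpd"` if cumulative population doublings were recorded there).
#' @return A `PassageModel`; the underlying `lm` fit is attached as attribute
#'   `"fit"`.
#' @export
train_model <- function(m, s, cpgs, target = "passage") {
  stopifnot(inherits(m, "BetaMatrix"))
  miss <- setdiff(cpgs, cpg_ids(m))
  if (length(miss) > 0)
    stop("training CpG(s) absent from beta matrix: ", paste(miss, collapse = ", "))
  y <- if (target == "passage") passages_for(m, s) else {
    stats::setNames(s[[target]][match(sample_ids(m), s$sample_id)], sample_ids(m))
  }
  X <- t(m$values[cpgs, , drop = FALSE])
  keep <- stats::complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (nrow(X) < length(cpgs) + 2)
    stop(sprintf("need at least %d complete samples to fit %d CpGs, got %d",
                 length(cpgs) + 2, length(cpgs), nrow(X)))
  if (stats::var(y) == 0) stop("passage target is constant; nothing to fit")
  df <- data.frame(..passage = y, X, check.names = FALSE)
  fit <- stats::lm(..passage ~ ., data = df)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    stop("rank-deficient design; collinear CpG(s): ",
         paste(gsub("`", "", names(co)[is.na(co)]), collapse = ", "))
  }
  mod <- passage_model(cpgs, co[-1], co[1],
                       provenance = sprintf("OLS fit on %d samples", nrow(X)))
  attr(mod, "fit") <- fit
  mod
}

#' Compare predicted and true passage numbers
#'
#' `r2` is the squared Pearson correlation between predictions and truth
#' (matching the predicted-vs-real convention of clock scatter plots);
#' `r2_explained` additionally reports 1 - SSE/SST since publications do not
#' always state which convention they used. RMSE and MAE are in passages.
#'
#' @param pred,truth numeric vectors of equal length (>= 2), `NA`s dropped
#'   pairwise.
#' @return List with `r2`, `r2_explained`, `rmse`, `mae`, `n`.
#' @export
evaluate_predictions <- function(pred, truth) {
  ok <- !is.na(pred) & !is.na(truth)
  pred <- pred[ok]; truth <- truth[ok]
  if (length(pred) < 2) stop("need >= 2 paired predictions")
  err <- pred - truth
  r2 <- if (stats::sd(pred) == 0 || stats::sd(truth) == 0) NA_real_
        else stats::cor(pred, truth)^2
  sst <- sum((truth - mean(truth))^2)
  list(r2 = r2,
       r2_explained = if (sst == 0) NA_real_ else 1 - sum(err^2) / sst,
       rmse = sqrt(mean(err^2)),
       mae = mean(abs(err)),
       n = length(pred))
}

#' Repeated k-fold cross-validation of a passage model
#'
#' For each repeat, samples are shuffled and split into `folds` nearly equal
#' folds (remainder samples go to the first folds); each fold is predicted by
#' a model trained on the others. Metrics are pooled over all held-out
#' predictions of all repeats. Deterministic for a given `seed`.
#'
#' @param m a `BetaMatrix`.
#' @param s a `SampleSheet`.
#' @param cpgs predictor CpG ids.
#' @param folds number of folds (default 10).
#' @param repeats number of repetitions (default 10).
#' @param seed integer seed for fold assignment.
#' @return List of class `CVReport`: `r2`, `r2_explained`, `rmse`, `mae`,
#'   `folds`, `repeats`, `seed`, `n`, plus per-sample held-out `predictions`
#'   (matrix repeats x samples).
#' @export
cross_validate <- function(m, s, cpgs, folds = 10, repeats = 10, seed = 1) {
  stopifnot(inherits(m, "BetaMatrix"))
  y <- passages_for(m, s)
  n <- length(y)
  if (folds < 2) stop("need >= 2 folds")
  if (folds > n) stop(sprintf("folds (%d) exceeds sample count (%d)", folds, n))
  preds <- matrix(NA_real_, nrow = repeats, ncol = n,
                  dimnames = list(NULL, sample_ids(m)))
  withr::with_seed(seed, {
    for (rep_i in seq_len(repeats)) {
      idx <- sample.int(n)
      sizes <- rep(n %/% folds, folds)
      extra <- n %% folds
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      stops <- cumsum(sizes)
      starts <- c(1L, utils::head(stops, -1) + 1L)
      for (f in seq_len(folds)) {
        test <- idx[starts[f]:stops[f]]
        train <- setdiff(seq_len(n), test)
        sub <- beta_matrix(m$values[, train, drop = FALSE])
        mod <- train_model(sub, s, cpgs)
        preds[rep_i, test] <- predict_passage(
          mod, beta_matrix(m$values[, test, drop = FALSE]))[sample_ids(m)[test]]
      }
    }
  })
  pooled <- evaluate_predictions(as.numeric(preds),
                                 rep(as.numeric(y), each = repeats))
  structure(list(r2 = pooled$r2, r2_explained = pooled$r2_explained,
                 rmse = pooled$rmse, mae = pooled$mae,
                 folds = folds, repeats = repeats, seed = seed, n = n,
                 predictions = preds),
            class = "CVReport")
}

#' @export
print.CVReport <- function(x, ...) {
  cat(sprintf("CVReport: %dx %d-fold CV on %d samples (seed %d)\n",
              x$repeats, x$folds, x$n, x$seed))
  cat(sprintf("  R2 = %.3f  (1-SSE/SST = %.3f)  RMSE = %.3f  MAE = %.3f passages\n",
              x$r2, x$r2_explained, x$rmse, x$mae))
  invisible(x)
}

#' Serialize / deserialize a PassageModel (JSON)
#'
#' Lossless round trip of CpG ids, coefficients, intercept and provenance.
#' Unknown fields in the file are ignored with a warning, so files written by
#' newer versions remain readable.
#'
#' @param model a `PassageModel`.
#' @param path JSON file path.
#' @return `read_model`: a `PassageModel`. `write_model`: `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "PassageModel"))
  jsonlite::write_json(
    list(type = "PassageModel",
         cpg_ids = model$cpg_ids,
         coefficients = unname(model$coefficients),
         intercept = model$intercept,
         provenance = model$provenance),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("cannot parse model JSON '", path,
                                           "': ", conditionMessage(e)))
  req <- c("cpg_ids", "coefficients", "intercept")
  miss <- setdiff(req, names(obj))
  if (length(miss) > 0)
    stop("model JSON missing field(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(obj), c(req, "provenance", "type"))
  if (length(extra) > 0)
    warning("ignoring unknown model field(s): ", paste(extra, collapse = ", "))
  passage_model(obj$cpg_ids, obj$coefficients, obj$intercept,
                provenance = if (is.null(obj$provenance)) "" else obj$provenance)
}
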