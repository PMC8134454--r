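#' BetaMatrix: CpG x sample methylation fractions
#'
#' A `BetaMatrix` holds DNA methylation beta values (fraction methylated, in
#' \[0,1\]) for a set of CpG sites (rows) across samples (columns). Missing
#' values are allowed and represented as `NA`. An optional per-CpG chromosome
#' annotation supports sex-chromosome filtering.
#'
#' @param values numeric matrix with unique rownames (CpG ids) and unique
#'   colnames (sample ids); entries in \[0,1\] or `NA`.
#' @param cpg_annotation optional named character vector mapping CpG id to a
#'   chromosome label (e.g. `"chr1"`, `"chrX"`).
#' @return An object of class `BetaMatrix`.
#' @export
beta_matrix <- function(values, cpg_annotation = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values))))
    stop("'values' must have rownames (cpg ids) and colnames (sample ids)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate cpg_id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample_id: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("beta value out of [0,1] at cpg '%s', sample '%s' (value %g)",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
                 values[bad[1, , drop = FALSE]]))
  }
  if (!is.null(cpg_annotation)) {
    if (is.null(names(cpg_annotation)))
      stop("'cpg_annotation' must be a named character vector (cpg_id -> chromosome)")
    cpg_annotation <- cpg_annotation[intersect(names(cpg_annotation), rownames(values))]
  }
  structure(list(values = values, cpg_annotation = cpg_annotation),
            class = "BetaMatrix")
}

#' @export
dim.BetaMatrix <- function(x) dim(x$values)

#' @export
print.BetaMatrix <- function(x, ...) {
  cat(sprintf("BetaMatrix: %d CpGs x %d samples (%d missing values)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  if (!is.null(x$cpg_annotation))
    cat(sprintf("  chromosome annotation for %d CpGs\n", length(x$cpg_annotation)))
  invisible(x)
}

#' CpG and sample identifiers of a BetaMatrix
#' @param m a `BetaMatrix`.
#' @return Character vector of identifiers.
#' @export
cpg_ids <- function(m) rownames(m$values)

#' @rdname cpg_ids
#' @export
sample_ids <- function(m) colnames(m$values)

#' Read a beta-value matrix from TSV
#'
#' The file must have a header line starting with a `cpg_id` column followed by
#' one column per sample. Cells are decimal numbers in \[0,1\]; missing values
#' are written as `.` or left empty.
#'
#' @param path path to a tab-separated file.
#' @param cpg_annotation optional named chromosome map passed on to
#'   [beta_matrix()].
#' @return A `BetaMatrix`.
#' @export
read_beta_matrix <- function(path, cpg_annotation = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", na.strings = c(".", ""),
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2)
    stop("beta matrix TSV needs a cpg_id column plus at least one sample column: ", path)
  ids <- tab[[1]]
  samples <- colnames(tab)[-1]
  vals <- suppressWarnings(
    vapply(tab[-1], function(col) as.numeric(col), numeric(nrow(tab))))
  vals <- matrix(vals, nrow = nrow(tab), ncol = length(samples),
                 dimnames = list(ids, samples))
  nonnum <- which(is.na(vals) & !is.na(as.matrix(tab[-1])), arr.ind = TRUE)
  if (nrow(nonnum) > 0)
    stop(sprintf("non-numeric beta value at cpg '%s', sample '%s' in %s",
                 ids[nonnum[1, 1]], samples[nonnum[1, 2]], path))
  beta_matrix(vals, cpg_annotation = cpg_annotation)
}

#' Write a beta-value matrix to TSV
#'
#' Missing values are written as `.`. Writing then re-reading returns an
#' equivalent matrix, and the textual form is stable after one read/write pass.
#'
#' @param m a `BetaMatrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(m, path) {
  stopifnot(inherits(m, "BetaMatrix"))
  v <- m$values
  txt <- matrix(as.character(v), nrow = nrow(v))
  txt[is.na(txt)] <- "."
  lines <- c(paste(c("cpg_id", colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(rownames(v)[i], txt[i, ]), collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Drop CpGs on excluded chromosomes
#'
#' Sex chromosomes are routinely excluded before correlating methylation with
#' passage number, since X/Y CpGs confound donor sex with culture effects.
#'
#' @param m a `BetaMatrix` with chromosome annotation covering all CpGs.
#' @param excluded character vector of chromosome labels to drop
#'   (e.g. `c("chrX", "chrY")`).
#' @return A `BetaMatrix` without CpGs on the excluded chromosomes; row order
#'   otherwise preserved. An empty result is allowed.
#' @export
filter_cpgs_by_chromosome <- function(m, excluded) {
  stopifnot(inherits(m, "BetaMatrix"))
  if (length(excluded) == 0) return(m)
  ann <- m$cpg_annotation
  missing_ann <- setdiff(cpg_ids(m), names(ann))
  if (length(missing_ann) > 0)
    stop("missing chromosome annotation for CpG(s): ",
         paste(utils::head(missing_ann, 10), collapse = ", "))
  keep <- !(ann[cpg_ids(m)] %in% excluded)
  kept_ids <- cpg_ids(m)[keep]
  beta_matrix(m$values[keep, , drop = FALSE],
              cpg_annotation = ann[names(ann) %in% kept_ids])
}

#' k-nearest-neighbor imputation of missing beta values
#'
#' Each missing entry is replaced by the mean of the `k` nearest CpG rows
#' (Euclidean distance over the columns observed in both rows) that have an
#' observed value in the missing entry's column. Observed entries are left
#' untouched; imputed values are clipped to \[0,1\]. Ties in distance are
#' broken by row order.
#'
#' @param m a `BetaMatrix`.
#' @param k number of neighbors (>= 1).
#' @return A `BetaMatrix` with no missing values.
#' @export
knn_impute <- function(m, k = 10) {
  stopifnot(inherits(m, "BetaMatrix"))
  if (k < 1) stop("'k' must be >= 1")
  v <- m$values
  if (!anyNA(v)) return(m)
  all_missing <- rowSums(!is.na(v)) == 0
  if (any(all_missing))
    stop("CpG row(s) entirely missing, cannot impute: ",
         paste(utils::head(rownames(v)[all_missing], 10), collapse = ", "))
  out <- v
  need <- which(rowSums(is.na(v)) > 0)
  for (i in need) {
    obs_i <- !is.na(v[i, ])
    # squared distances to every other row over shared observed columns
    diffs <- sweep(v[, obs_i, drop = FALSE], 2, v[i, obs_i], "-")
    d2 <- rowSums(diffs^2, na.rm = TRUE)
    shared <- rowSums(!is.na(diffs))
    d2[shared == 0] <- Inf
    d2[i] <- Inf
    for (j in which(is.na(v[i, ]))) {
      cand <- which(!is.na(v[, j]) & is.finite(d2))
      if (length(cand) < k)
        stop(sprintf("fewer than k=%d candidate neighbor rows observed for cpg '%s', sample '%s'",
                     k, rownames(v)[i], colnames(v)[j]))
      nn <- cand[order(d2[cand], cand)][seq_len(k)]
      out[i, j] <- min(1, max(0, mean(v[nn, j])))
    }
  }
  beta_matrix(out, cpg_annotation = m$cpg_annotation)
}

#' Quantile normalization across samples
#'
#' Classical quantile normalization: values are ranked within each sample and
#' replaced by the mean, across samples, of the values at each rank. Tied
#' values receive the mean of the tied ranks' reference values, so every output
#' column has an identical sorted value vector. The transform is idempotent.
#'
#' @param m a `BetaMatrix` with no missing values (impute first, see
#'   [knn_impute()]).
#' @return A quantile-normalized `BetaMatrix`.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "BetaMatrix"))
  v <- m$values
  if (anyNA(v))
    stop("beta matrix contains missing values; run knn_impute() before quantile_normalize()")
  n <- nrow(v)
  ref <- rowMeans(apply(v, 2, sort))
  out <- apply(v, 2, function(col) {
    o <- order(col)
    r <- rank(col, ties.method = "average")
    # non-integer average ranks (tie groups) take the mean of the spanned
    # reference values
    lo <- floor(r); hi <- ceiling(r)
    val <- (ref[lo] + ref[hi]) / 2
    # exact tie groups larger than 2 need the full mean over their rank span
    if (anyDuplicated(col)) {
      for (u in unique(col[duplicated(col)])) {
        idx <- which(col == u)
        span <- seq(min(rank(col, ties.method = "min")[idx]),
                    max(rank(col, ties.method = "max")[idx]))
        val[idx] <- mean(ref[span])
      }
    }
    val
  })
  dimnames(out) <- dimnames(v)
  beta_matrix(out, cpg_annotation = m$cpg_annotation)
}
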