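#' HairpinReads: UMI-labelled strand pairs of bisulfite hairpin molecules
#'
#' Hairpin ligation covalently joins the two complementary strands of one DNA
#' molecule, so a single read reports the CpG methylation states of both
#' strands of the same CpG dyads; a unique molecular identifier (UMI) in the
#' hairpin loop distinguishes original molecules from PCR duplicates.
#'
#' @param umi character vector of UMIs (equal length strings), one per read.
#' @param top,bottom integer matrices (reads x CpGs) of 0/1/`NA` methylation
#'   states on the top and bottom strand; coordinates are reported on the top
#'   strand.
#' @return An object of class `HairpinReads`.
#' @export
hairpin_reads <- function(umi, top, bottom) {
  top <- as.matrix(top); bottom <- as.matrix(bottom)
  storage.mode(top) <- "integer"; storage.mode(bottom) <- "integer"
  if (!all(dim(top) == dim(bottom)))
    stop("top and bottom strand matrices must have identical dimensions")
  if (length(umi) != nrow(top))
    stop("one UMI per read required")
  if (length(unique(nchar(umi))) > 1)
    stop("UMIs of mixed lengths")
  structure(list(umi = as.character(umi), top = top, bottom = bottom),
            class = "HairpinReads")
}

#' @export
print.HairpinReads <- function(x, ...) {
  cat(sprintf("HairpinReads: %d reads (%d distinct UMIs), %d CpGs\n",
              length(x$umi), length(unique(x$umi)), ncol(x$top)))
  invisible(x)
}

#' Directional clustering of UMIs
#'
#' Groups UMIs that differ by sequencing error using the directional
#' adjacency rule: a directed edge runs from UMI u to UMI v when their Hamming
#' distance is at most `max_mismatch` and count(u) >= 2 * count(v) - 1.
#' Clusters are the sets reachable from count-descending roots; each cluster
#' reports its root UMI and total read count. With `max_mismatch = 0` every
#' distinct UMI is its own cluster. The result is invariant to input order
#' (ties in count are broken lexicographically).
#'
#' @param umi_counts named integer vector: UMI -> read count.
#' @param max_mismatch maximum Hamming distance for an edge (default 1).
#' @return List of clusters, each `list(root, umis, count)`, ordered by
#'   decreasing total count.
#' @export
cluster_umis <- function(umi_counts, max_mismatch = 1) {
  if (is.null(names(umi_counts))) stop("'umi_counts' must be named by UMI")
  umis <- names(umi_counts)
  if (length(unique(nchar(umis))) > 1) stop("UMIs of mixed lengths")
  counts <- as.integer(umi_counts)
  ord <- order(-counts, umis)
  umis <- umis[ord]; counts <- counts[ord]
  n <- length(umis)
  assigned <- rep(NA_integer_, n)
  mat <- do.call(rbind, strsplit(umis, ""))
  cluster_id <- 0L
  for (i in seq_len(n)) {
    if (!is.na(assigned[i])) next
    cluster_id <- cluster_id + 1L
    queue <- i; assigned[i] <- cluster_id
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      cand <- which(is.na(assigned))
      if (length(cand) == 0) break
      hd <- rowSums(mat[cand, , drop = FALSE] !=
                      matrix(mat[u, ], nrow = length(cand), ncol = ncol(mat),
                             byrow = TRUE))
      hit <- cand[hd <= max_mismatch & counts[u] >= 2L * counts[cand] - 1L]
      if (length(hit) > 0) {
        assigned[hit] <- cluster_id
        queue <- c(queue, hit)
      }
    }
  }
  clusters <- lapply(seq_len(cluster_id), function(k) {
    mem <- which(assigned == k)
    list(root = umis[mem[1]], umis = umis[mem], count = sum(counts[mem]))
  })
  clusters[order(-vapply(clusters, function(cl) cl$count, numeric(1)),
                 vapply(clusters, function(cl) cl$root, character(1)))]
}

#' Collapse PCR duplicates to one consensus molecule per UMI cluster
#'
#' Within each cluster, the consensus state at every CpG of each strand is
#' the majority state over member reads (missing states ignored; exact ties
#' become missing). Output has one consensus read per cluster.
#'
#' @param reads a `HairpinReads`.
#' @param clusters result of [cluster_umis()] on the reads' UMI counts; if
#'   `NULL`, computed with the default `max_mismatch = 1`.
#' @return A deduplicated `HairpinReads` (UMI = cluster root).
#' @export
dedupe_by_umi <- function(reads, clusters = NULL) {
  stopifnot(inherits(reads, "HairpinReads"))
  if (is.null(clusters))
    clusters <- cluster_umis(table(reads$umi))
  majority <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_integer_)
    ones <- sum(x); zeros <- length(x) - ones
    if (ones > zeros) 1L else if (zeros > ones) 0L else NA_integer_
  }
  cons <- lapply(clusters, function(cl) {
    rows <- which(reads$umi %in% cl$umis)
    list(top = apply(reads$top[rows, , drop = FALSE], 2, majority),
         bottom = apply(reads$bottom[rows, , drop = FALSE], 2, majority))
  })
  hairpin_reads(vapply(clusters, function(cl) cl$root, character(1)),
                do.call(rbind, lapply(cons, `[[`, "top")),
                do.call(rbind, lapply(cons, `[[`, "bottom")))
}

#' Per-CpG hemimethylation rates from strand pairs
#'
#' For every CpG dyad, counts molecules that are methylated on both strands
#' (`n_mm`), unmethylated on both (`n_uu`), or discordant (hemimethylated:
#' methylated on exactly one strand). The hemimethylation rate is
#' discordant / informative, where a molecule is informative at a CpG when
#' both strand states were called. Run after [dedupe_by_umi()] so PCR
#' duplicates are not double-counted.
#'
#' @param reads a `HairpinReads` (typically deduplicated).
#' @return Data.frame of class `HemiResult`: `cpg_index`, `n_mm`, `n_uu`,
#'   `n_discordant`, `n_informative`, `rate` (`NA` where no molecule is
#'   informative, flagged in the `undefined` column).
#' @export
hemimethylation_rates <- function(reads) {
  stopifnot(inherits(reads, "HairpinReads"))
  ncpg <- ncol(reads$top)
  res <- lapply(seq_len(ncpg), function(j) {
    t_ <- reads$top[, j]; b_ <- reads$bottom[, j]
    ok <- !is.na(t_) & !is.na(b_)
    n_mm <- sum(t_[ok] == 1 & b_[ok] == 1)
    n_uu <- sum(t_[ok] == 0 & b_[ok] == 0)
    n_disc <- sum(ok) - n_mm - n_uu
    data.frame(cpg_index = j, n_mm = n_mm, n_uu = n_uu,
               n_discordant = n_disc, n_informative = sum(ok),
               rate = if (sum(ok) > 0) n_disc / sum(ok) else NA_real_)
  })
  out <- do.call(rbind, res)
  out$undefined <- out$n_informative == 0
  class(out) <- c("HemiResult", "data.frame")
  out
}

#' Read / write hairpin reads (TSV)
#'
#' Flat text format: `umi<TAB>top<TAB>bottom` with strand patterns as strings
#' of `0`, `1` and `.`.
#'
#' @param path TSV file path.
#' @return `read_hairpin_tsv`: a `HairpinReads`.
#' @export
read_hairpin_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  hairpin_reads(tab$umi,
                do.call(rbind, lapply(tab$top, pattern_vector)),
                do.call(rbind, lapply(tab$bottom, pattern_vector)))
}

#' @rdname read_hairpin_tsv
#' @param reads a `HairpinReads`.
#' @export
write_hairpin_tsv <- function(reads, path) {
  tab <- data.frame(umi = reads$umi,
                    top = apply(reads$top, 1, pattern_string),
                    bottom = apply(reads$bottom, 1, pattern_string),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write hemimethylation results to TSV
#' @param hemi a `HemiResult`.
#' @param path output path.
#' @param amplicon amplicon label for the output table.
#' @return `path`, invisibly.
#' @export
write_hemi_tsv <- function(hemi, path, amplicon = "amplicon") {
  tab <- cbind(amplicon = amplicon, as.data.frame(hemi))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
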