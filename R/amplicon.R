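#' Amplicon definition for bisulfite amplicon sequencing
#'
#' Describes one PCR amplicon on the unconverted (+) reference: its sequence,
#' primers, and the 0-based offsets of the C of each CpG dyad. Reads are
#' anchored to the reference by the forward primer, so no genome-wide
#' alignment is needed for these short, primer-defined fragments.
#'
#' @param name amplicon name (e.g. `"GRM7"`).
#' @param reference_seq unconverted genomic sequence (A/C/G/T).
#' @param forward_primer,reverse_primer primer subsequences of `reference_seq`.
#' @param cpg_offsets 0-based offsets of each CpG's C in `reference_seq`,
#'   strictly increasing.
#' @param strand `"+"` or `"-"` (coordinates always reported on the top
#'   strand).
#' @return An object of class `AmpliconDef`.
#' @export
amplicon_def <- function(name, reference_seq, forward_primer, reverse_primer,
                         cpg_offsets, strand = "+") {
  reference_seq <- toupper(reference_seq)
  if (grepl("[^ACGT]", reference_seq))
    stop("reference_seq must contain only A/C/G/T")
  cpg_offsets <- as.integer(cpg_offsets)
  if (any(diff(cpg_offsets) <= 0) && length(cpg_offsets) > 1)
    stop("cpg_offsets must be strictly increasing")
  chars <- strsplit(reference_seq, "")[[1]]
  for (o in cpg_offsets) {
    if (o < 0 || o + 2 > length(chars) || chars[o + 1] != "C" || chars[o + 2] != "G")
      stop(sprintf("cpg_offset %d does not point at a CpG (C followed by G) in '%s'",
                   o, name))
  }
  fwd_at <- regexpr(toupper(forward_primer), reference_seq, fixed = TRUE)
  if (fwd_at < 0) stop("forward_primer not found in reference_seq for '", name, "'")
  if (!grepl(toupper(reverse_primer), reference_seq, fixed = TRUE) &&
      !grepl(revcomp(toupper(reverse_primer)), reference_seq, fixed = TRUE))
    stop("reverse_primer not found in reference_seq for '", name, "'")
  structure(list(name = name, reference_seq = reference_seq,
                 forward_primer = toupper(forward_primer),
                 reverse_primer = toupper(reverse_primer),
                 cpg_offsets = cpg_offsets, strand = strand,
                 primer_offset = as.integer(fwd_at - 1L)),
            class = "AmpliconDef")
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' @export
print.AmpliconDef <- function(x, ...) {
  cat(sprintf("AmpliconDef '%s': %d bp, %d CpGs, strand %s\n",
              x$name, nchar(x$reference_seq), length(x$cpg_offsets), x$strand))
  invisible(x)
}

#' Read / write an amplicon panel (JSON)
#'
#' A panel is a JSON array of amplicon records (`name`, `reference_seq`,
#' `forward_primer`, `reverse_primer`, `cpg_offsets`, `strand`). Reference
#' sequences may alternatively be supplied in a companion FASTA keyed by
#' amplicon name.
#'
#' @param path JSON file path.
#' @param fasta optional FASTA file with reference sequences by amplicon name.
#' @return A named list of `AmpliconDef` objects.
#' @export
read_amplicon_panel <- function(path, fasta = NULL) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  seqs <- NULL
  if (!is.null(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    seqs <- stats::setNames(as.character(ss), names(ss))
  }
  amps <- lapply(recs, function(r) {
    ref <- if (!is.null(r$reference_seq)) r$reference_seq else seqs[[r$name]]
    if (is.null(ref)) stop("no reference sequence for amplicon '", r$name, "'")
    amplicon_def(r$name, ref, r$forward_primer, r$reverse_primer,
                 unlist(r$cpg_offsets), strand = if (is.null(r$strand)) "+" else r$strand)
  })
  stats::setNames(amps, vapply(amps, function(a) a$name, character(1)))
}

#' @rdname read_amplicon_panel
#' @param amps named list of `AmpliconDef` objects.
#' @export
write_amplicon_panel <- function(amps, path) {
  recs <- lapply(amps, function(a)
    list(name = a$name, reference_seq = a$reference_seq,
         forward_primer = a$forward_primer, reverse_primer = a$reverse_primer,
         cpg_offsets = a$cpg_offsets, strand = a$strand))
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' ReadPatternSet: per-read binary methylation patterns
#'
#' Stores the methylation call at each CpG of an amplicon for every read, as
#' distinct patterns with read counts. States are `1` (methylated), `0`
#' (unmethylated) or `NA` (missing/unreadable).
#'
#' @param states integer matrix (patterns x CpGs) of 0/1/`NA`.
#' @param counts integer vector of reads per pattern (>= 1).
#' @param amplicon amplicon name.
#' @param sample_id sample identifier.
#' @return An object of class `ReadPatternSet`. Duplicate pattern rows are
#'   collapsed with their counts summed.
#' @export
read_pattern_set <- function(states, counts = rep(1L, nrow(states)),
                             amplicon = "amplicon", sample_id = "sample") {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (length(counts) != nrow(states)) stop("one count per pattern row required")
  if (any(counts < 1)) stop("pattern counts must be >= 1")
  key <- apply(states, 1, pattern_string)
  agg <- rowsum(as.numeric(counts), key)
  ord <- order(-agg[, 1], rownames(agg))
  keys <- rownames(agg)[ord]
  mat <- do.call(rbind, lapply(keys, pattern_vector))
  rownames(mat) <- keys
  structure(list(amplicon = amplicon, sample_id = sample_id,
                 states = mat, counts = as.integer(agg[ord, 1])),
            class = "ReadPatternSet")
}

#' @export
print.ReadPatternSet <- function(x, ...) {
  cat(sprintf("ReadPatternSet '%s' sample '%s': %d reads, %d distinct patterns, %d CpGs\n",
              x$amplicon, x$sample_id, sum(x$counts), nrow(x$states), ncol(x$states)))
  invisible(x)
}

pattern_string <- function(v) {
  paste(ifelse(is.na(v), ".", as.character(v)), collapse = "")
}

pattern_vector <- function(s) {
  ch <- strsplit(s, "")[[1]]
  v <- suppressWarnings(as.integer(ch))
  v
}

# expand collapsed patterns back to one row per read
expand_states <- function(rps) {
  rps$states[rep(seq_len(nrow(rps$states)), rps$counts), , drop = FALSE]
}

#' Total read count of a ReadPatternSet
#' @param rps a `ReadPatternSet`.
#' @return Integer.
#' @export
n_reads <- function(rps) sum(rps$counts)

#' Per-CpG methylated fraction of a ReadPatternSet
#'
#' Count-weighted mean of the binary states per CpG, ignoring missing states.
#'
#' @param rps a `ReadPatternSet`.
#' @return Numeric vector, one fraction per CpG.
#' @export
methylation_fractions <- function(rps) {
  w <- rps$counts
  vapply(seq_len(ncol(rps$states)), function(j) {
    x <- rps$states[, j]
    ok <- !is.na(x)
    if (!any(ok)) return(NA_real_)
    sum(w[ok] * x[ok]) / sum(w[ok])
  }, numeric(1))
}

#' Call per-read CpG methylation patterns from bisulfite amplicon reads
#'
#' Reads are anchored by matching the forward primer (allowing C->T bisulfite
#' conversion at reference cytosines, and up to one other mismatch). At each
#' CpG offset, a read base `C` is called methylated, `T` unmethylated, and
#' anything else missing. Bisulfite conversion is verified at the covered
#' non-CpG cytosines of the reference: reads whose non-converted fraction
#' exceeds `max_mismatch_frac` are discarded.
#'
#' @param reads character vector of read sequences, or the path to a FASTQ
#'   file (Phred+33), in forward-primer orientation.
#' @param amp an `AmpliconDef`.
#' @param max_mismatch_frac maximum tolerated fraction of unconverted /
#'   mismatching non-CpG cytosine positions per read (default 0.1).
#' @param sample_id sample label for the returned set.
#' @return A `ReadPatternSet` with attributes `n_discarded` (failed
#'   conversion check) and `n_unanchored` (no primer match).
#' @export
call_read_patterns <- function(reads, amp, max_mismatch_frac = 0.1,
                               sample_id = "sample") {
  stopifnot(inherits(amp, "AmpliconDef"))
  if (length(reads) == 1 && file.exists(reads) && grepl("\\.(fastq|fq)(\\.gz)?$", reads)) {
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = "fastq"))
  }
  if (length(reads) == 0) stop("no reads supplied")
  ref <- strsplit(amp$reference_seq, "")[[1]]
  plen <- nchar(amp$forward_primer)
  pref <- strsplit(amp$forward_primer, "")[[1]]
  # reference Cs may appear as C or T in a converted read
  is_cpg_c <- rep(FALSE, length(ref))
  is_cpg_c[amp$cpg_offsets + 1L] <- TRUE
  nonconv_check <- which(ref == "C" & !is_cpg_c)  # expected T after conversion

  anchored <- 0L
  discarded <- 0L
  pats <- vector("list", length(reads))
  for (r in seq_along(reads)) {
    rd <- strsplit(toupper(reads[[r]]), "")[[1]]
    pos <- anchor_primer(rd, pref, max_mm = 1L)
    if (is.na(pos)) next
    anchored <- anchored + 1L
    # map reference offset o (0-based) to read index
    map <- function(o) pos + (o - amp$primer_offset)
    covered <- nonconv_check[map(nonconv_check - 1L) >= 1 &
                             map(nonconv_check - 1L) <= length(rd)]
    if (length(covered) > 0) {
      rb <- rd[map(covered - 1L)]
      if (mean(rb != "T") > max_mismatch_frac) {
        discarded <- discarded + 1L
        next
      }
    }
    idx <- map(amp$cpg_offsets)
    st <- rep(NA_integer_, length(idx))
    inr <- idx >= 1 & idx <= length(rd)
    b <- rd[idx[inr]]
    st[inr] <- ifelse(b == "C", 1L, ifelse(b == "T", 0L, NA_integer_))
    pats[[r]] <- st
  }
  if (anchored < 0.01 * length(reads))
    stop(sprintf("forward primer of '%s' not found in %.1f%% of reads; wrong amplicon?",
                 amp$name, 100 * (1 - anchored / length(reads))))
  pats <- pats[!vapply(pats, is.null, logical(1))]
  if (length(pats) == 0)
    stop("no reads passed anchoring and conversion checks for '", amp$name, "'")
  rps <- read_pattern_set(do.call(rbind, pats), amplicon = amp$name,
                          sample_id = sample_id)
  attr(rps, "n_discarded") <- discarded
  attr(rps, "n_unanchored") <- length(reads) - anchored
  rps
}

# first read position (1-based) where the primer matches, allowing C->T at
# reference Cs plus up to max_mm other mismatches; NA if none
anchor_primer <- function(rd, pref, max_mm = 1L) {
  plen <- length(pref)
  if (length(rd) < plen) return(NA_integer_)
  allow_t <- pref == "C"
  for (pos in seq_len(length(rd) - plen + 1L)) {
    seg <- rd[pos:(pos + plen - 1L)]
    mm <- sum(seg != pref & !(allow_t & seg == "T"))
    if (mm <= max_mm) return(pos)
  }
  NA_integer_
}

#' Read / write pattern tables (TSV)
#'
#' Flat text exchange format for read patterns:
#' `sample_id<TAB>amplicon<TAB>pattern<TAB>count`, with patterns as strings of
#' `0`, `1` and `.` (missing).
#'
#' @param path TSV file path.
#' @return `read_pattern_tsv`: a list of `ReadPatternSet` objects, one per
#'   (sample, amplicon) pair.
#' @export
read_pattern_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character", "character", "integer"))
  split_by <- interaction(tab$sample_id, tab$amplicon, drop = TRUE)
  lapply(split(tab, split_by), function(g) {
    read_pattern_set(do.call(rbind, lapply(g$pattern, pattern_vector)),
                     counts = g$count, amplicon = g$amplicon[1],
                     sample_id = g$sample_id[1])
  })
}

#' @rdname read_pattern_tsv
#' @param sets a `ReadPatternSet` or list of them.
#' @export
write_pattern_tsv <- function(sets, path) {
  if (inherits(sets, "ReadPatternSet")) sets <- list(sets)
  rows <- do.call(rbind, lapply(sets, function(rps)
    data.frame(sample_id = rps$sample_id, amplicon = rps$amplicon,
               pattern = rownames(rps$states), count = rps$counts,
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
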