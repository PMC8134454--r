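#' Sample sheet: per-sample culture metadata
#'
#' A sample sheet is a data.frame with one row per sample carrying at least
#' `sample_id` and `passage` (integer >= 0), plus optional `donor`,
#' `cell_type`, `timepoint_days` (for reprogramming time courses) and `group`
#' (e.g. train/validation).
#'
#' @param sample_id character vector of unique identifiers.
#' @param passage integer vector of passage numbers (>= 0).
#' @param donor,cell_type,group optional labels, recycled to length.
#' @param timepoint_days optional integer time points (days).
#' @return A `data.frame` of class `SampleSheet`.
#' @export
sample_sheet <- function(sample_id, passage, donor = NA_character_,
                         cell_type = NA_character_, timepoint_days = NA_integer_,
                         group = NA_character_) {
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  passage <- as.numeric(passage)
  if (any(!is.na(passage) & passage < 0))
    stop("passage numbers must be >= 0")
  s <- data.frame(sample_id = as.character(sample_id), passage = passage,
                  donor = donor, cell_type = cell_type,
                  timepoint_days = timepoint_days, group = group,
                  stringsAsFactors = FALSE)
  class(s) <- c("SampleSheet", "data.frame")
  s
}

#' Read a sample sheet from CSV
#'
#' Expected header: `sample_id,passage,donor,cell_type,timepoint_days,group`
#' (columns after `passage` optional).
#'
#' @param path path to a CSV file.
#' @return A `SampleSheet`.
#' @export
read_sample_sheet <- function(path) {
  tab <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  if (!all(c("sample_id", "passage") %in% colnames(tab)))
    stop("sample sheet must have 'sample_id' and 'passage' columns: ", path)
  get <- function(col, default) if (col %in% colnames(tab)) tab[[col]] else default
  sample_sheet(tab$sample_id, tab$passage,
               donor = get("donor", NA_character_),
               cell_type = get("cell_type", NA_character_),
               timepoint_days = get("timepoint_days", NA_integer_),
               group = get("group", NA_character_))
}

#' Write a sample sheet to CSV
#' @param s a `SampleSheet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(s, path) {
  utils::write.csv(as.data.frame(s), path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

# passage vector aligned to the columns of a BetaMatrix
passages_for <- function(m, s) {
  idx <- match(sample_ids(m), s$sample_id)
  if (anyNA(idx))
    stop("samples absent from sample sheet: ",
         paste(utils::head(sample_ids(m)[is.na(idx)], 10), collapse = ", "))
  stats::setNames(s$passage[idx], sample_ids(m))
}
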