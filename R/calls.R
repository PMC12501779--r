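# SubtypeCall container: one row per sample with per-subtype scores and
# bookkeeping flags, plus its TSV round-trip.

# Build the calls data frame from components; label (when not NA) must be
# an argmax of the scores.
make_calls <- function(sample_id, label, scores, method,
                       tie = FALSE, low_coverage = FALSE,
                       skipped_rules = 0L) {
  stopifnot(nrow(scores) == length(sample_id))
  df <- data.frame(sample_id = as.character(sample_id),
                   method = method,
                   label = as.character(label),
                   scores,
                   tie = rep_len(tie, length(sample_id)),
                   low_coverage = rep_len(low_coverage, length(sample_id)),
                   skipped_rules = rep_len(as.integer(skipped_rules),
                                           length(sample_id)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("SubtypeCalls", "data.frame"))
}

score_columns <- function(calls) {
  intersect(subtype_labels(), colnames(calls))
}

#' Write subtype calls to TSV
#'
#' Columns: `sample_id`, `method`, `label`, one score column per subtype,
#' `tie`, `low_coverage`, `skipped_rules`.
#'
#' @param calls A `SubtypeCalls` data frame (from [classify_nc()] or
#'   [classify_ssp()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  df <- as.data.frame(calls)
  df$tie <- tolower(as.character(df$tie))
  df$low_coverage <- tolower(as.character(df$low_coverage))
  write_tsv_strict(df, path)
  invisible(path)
}

#' Read subtype calls from TSV
#'
#' @param path Path to a TSV written by [write_calls()].
#' @return A `SubtypeCalls` data frame.
#' @export
read_calls <- function(path) {
  df <- read_tsv_strict(path)
  sc <- intersect(subtype_labels(), colnames(df))
  make_calls(df$sample_id, df$label,
             as.matrix(df[, sc, drop = FALSE]),
             method = df$method,
             tie = df$tie %in% c("true", "TRUE"),
             low_coverage = df$low_coverage %in% c("true", "TRUE"),
             skipped_rules = df$skipped_rules)
}
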