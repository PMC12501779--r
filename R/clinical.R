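# ClinicalTable: per-sample ER/PR/HER2 biomarker status plus an explicit
# triple-negative declaration. Statuses are normalized to pos/neg/unknown.

.status_pos <- c("pos", "positive", "1", "+")
.status_neg <- c("neg", "negative", "0", "-", "−")
.tn_true <- c("true", "t", "1", "yes", "y")
.tn_false <- c("false", "f", "0", "no", "n", "")

normalize_status <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(key))
  out[key %in% .status_pos] <- "pos"
  out[key %in% .status_neg] <- "neg"
  out[is.na(x)] <- "unknown"
  out
}

normalize_tn <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(key))
  out[key %in% .tn_true] <- TRUE
  out[key %in% .tn_false | is.na(x)] <- FALSE
  if (any(is.na(out))) {
    stop("unparseable tn value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' Construct a clinical biomarker table
#'
#' A triple-negative (TN) declaration is only accepted when the sample is
#' IHC-defined TN, i.e. ER-, PR- and HER2-; any other combination is
#' rejected.
#'
#' @param sample_id Unique sample identifiers.
#' @param er,pr,her2 Status vectors; normalized to `pos`/`neg`/`unknown`
#'   (accepted synonyms, case-insensitive: pos/positive/1/+ and
#'   neg/negative/0/-; anything else becomes unknown).
#' @param tn Logical TN declaration (default all `FALSE`).
#' @return A `ClinicalTable` data frame.
#' @export
clinical_table <- function(sample_id, er, pr, her2,
                           tn = rep(FALSE, length(sample_id))) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id in clinical table: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  df <- data.frame(sample_id = sample_id,
                   er = normalize_status(er),
                   pr = normalize_status(pr),
                   her2 = normalize_status(her2),
                   tn = normalize_tn(tn),
                   stringsAsFactors = FALSE)
  bad <- df$tn & !(df$er == "neg" & df$pr == "neg" & df$her2 == "neg")
  if (any(bad)) {
    stop("tn declared for sample(s) not IHC-defined TN (ER-/PR-/HER2-): ",
         paste(df$sample_id[bad], collapse = ", "))
  }
  structure(df, class = c("ClinicalTable", "data.frame"))
}

#' Read a clinical biomarker TSV
#'
#' Expected columns: `sample_id`, `er`, `pr`, `her2`, optional `tn`.
#' Unrecognized columns trigger a warning and are ignored.
#'
#' @param path Path to a TSV file.
#' @return A `ClinicalTable`.
#' @export
read_clinical <- function(path) {
  df <- read_tsv_strict(path)
  colnames(df) <- tolower(colnames(df))
  needed <- c("sample_id", "er", "pr", "her2")
  missing <- setdiff(needed, colnames(df))
  if (length(missing)) {
    stop("clinical TSV missing column(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(colnames(df), c(needed, "tn"))
  if (length(extra)) {
    warning("ignoring unknown clinical column(s): ",
            paste(extra, collapse = ", "))
  }
  tn <- if ("tn" %in% colnames(df)) df$tn else rep(FALSE, nrow(df))
  clinical_table(df$sample_id, df$er, df$pr, df$her2, tn)
}

#' Write a clinical table to TSV
#'
#' @param x A `ClinicalTable`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(x, path) {
  df <- as.data.frame(x)
  df$tn <- tolower(as.character(df$tn))
  write_tsv_strict(df, path)
  invisible(path)
}

# ER/HER2 subgroup label for each sample ("ER+/HER2-" etc.), NA when either
# status is unknown.
erher2_subgroup <- function(clinical) {
  er <- clinical$er
  her2 <- clinical$her2
  out <- rep(NA_character_, nrow(clinical))
  known <- er != "unknown" & her2 != "unknown"
  out[known] <- paste0("ER", ifelse(er[known] == "pos", "+", "-"),
                       "/HER2", ifelse(her2[known] == "pos", "+", "-"))
  out
}
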