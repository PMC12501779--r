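# Shared internal helpers.

#' Canonical intrinsic subtype labels
#'
#' The five canonical breast-cancer intrinsic molecular subtypes, in the
#' order used for deterministic tie-breaking throughout the package.
#'
#' @return Character vector `c("LumA", "LumB", "Her2", "Basal", "Normal")`.
#' @export
subtype_labels <- function() {
  c("LumA", "LumB", "Her2", "Basal", "Normal")
}

# Long-form aliases accepted in model files, normalized on load.
.subtype_aliases <- c(
  "luma" = "LumA", "luminal a" = "LumA", "luminala" = "LumA",
  "lumb" = "LumB", "luminal b" = "LumB", "luminalb" = "LumB",
  "her2" = "Her2", "her2-enriched" = "Her2", "her2enriched" = "Her2",
  "her2e" = "Her2",
  "basal" = "Basal", "basal-like" = "Basal", "basallike" = "Basal",
  "normal" = "Normal", "normal-like" = "Normal", "normallike" = "Normal"
)

normalize_subtype <- function(x) {
  key <- tolower(trimws(x))
  out <- unname(.subtype_aliases[key])
  bad <- is.na(out)
  if (any(bad)) {
    stop("unknown subtype label(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  out
}

# Canonical clinical subgroup labels (ASCII hyphens; unicode minus accepted
# on input).
.subgroups <- c("ER+", "ER-", "TN",
                "ER+/HER2-", "ER+/HER2+", "ER-/HER2+", "ER-/HER2-")

normalize_subgroup <- function(x) {
  y <- gsub("−", "-", trimws(x))
  bad <- !(y %in% .subgroups)
  if (any(bad)) {
    stop("unknown subgroup label(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  y
}

geometric_mean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop unless all values are finite numerics.
assert_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(what, " must be finite numeric values")
  }
  invisible(TRUE)
}

read_tsv_strict <- function(path, comment.char = "#") {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = comment.char,
                    na.strings = c("NA", ""), quote = "")
}

write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
}

# Parse header metadata lines of the form "# key: value" at the top of a
# model file.
read_header_meta <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  out <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- trimws(m[3])
  }
  out
}
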