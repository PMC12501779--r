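# ExpressionMatrix: a genes x samples matrix with declared scale, units and
# platform, the container every engine consumes.

.platforms <- data.frame(
  platform = c("rnaseq_counts", "rnaseq_log2fpkm", "microarray", "ncounter"),
  scale    = c("linear", "log2", "log2", "log2"),
  units    = c("counts", "fpkm", "normalized_intensity", "normalized_intensity"),
  stringsAsFactors = FALSE
)

#' Construct an expression matrix with declared scale, units and platform
#'
#' @param values Numeric matrix, genes in rows (rownames = gene/probe IDs),
#'   samples in columns (colnames = sample IDs).
#' @param platform One of `"rnaseq_counts"`, `"rnaseq_log2fpkm"`,
#'   `"microarray"`, `"ncounter"`.
#' @param scale `"linear"` or `"log2"`; defaults to the platform's
#'   convention.
#' @param units One of `"counts"`, `"cpm"`, `"fpkm"`,
#'   `"normalized_intensity"`; defaults to the platform's convention.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, platform, scale = NULL, units = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!platform %in% .platforms$platform) {
    stop("unknown platform: ", platform)
  }
  row <- .platforms[.platforms$platform == platform, ]
  obj <- structure(
    list(values = values,
         scale = scale %||% row$scale,
         units = units %||% row$units,
         platform = platform),
    class = "ExpressionMatrix")
  validate_expression_matrix(obj)
  obj
}

validate_expression_matrix <- function(x) {
  v <- x$values
  if (is.null(rownames(v)) || is.null(colnames(v))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(v))) {
    dup <- unique(rownames(v)[duplicated(rownames(v))])
    stop("duplicate gene IDs: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (anyDuplicated(colnames(v))) {
    dup <- unique(colnames(v)[duplicated(colnames(v))])
    stop("duplicate sample IDs: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (any(!is.finite(v))) {
    idx <- which(!is.finite(v), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 rownames(v)[idx[1]], colnames(v)[idx[2]]))
  }
  if (!x$scale %in% c("linear", "log2")) stop("scale must be linear or log2")
  if (!x$units %in% c("counts", "cpm", "fpkm", "normalized_intensity")) {
    stop("unknown units: ", x$units)
  }
  if (x$platform == "rnaseq_counts" &&
      !(x$units == "counts" && x$scale == "linear")) {
    stop("platform rnaseq_counts implies units=counts, scale=linear")
  }
  if (x$units == "counts" && x$scale == "linear") {
    if (any(v < 0)) {
      idx <- which(v < 0, arr.ind = TRUE)[1, ]
      stop(sprintf("negative count at gene '%s', sample '%s'",
                   rownames(v)[idx[1]], colnames(v)[idx[2]]))
    }
    if (any(abs(v - round(v)) > 1e-8)) {
      stop("counts must be integral")
    }
  }
  invisible(x)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s, %s, %s]\n",
              nrow(x$values), ncol(x$values), x$platform, x$scale, x$units))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an expression matrix by gene and/or sample
#'
#' @param x An `ExpressionMatrix`.
#' @param genes,samples Character or integer indices; `NULL` keeps all.
#' @return A new `ExpressionMatrix` with the same scale/units/platform.
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  out <- x
  out$values <- v
  out
}

#' Read an expression matrix from TSV
#'
#' Expects genes in rows and samples in columns: a header row of sample IDs
#' and a first column of gene (or probe) identifiers. All parsing is
#' locale-independent: UTF-8, tab-delimited, `.` decimal separator.
#'
#' @param path Path to a TSV file.
#' @param platform Platform tag (see [expression_matrix()]); determines the
#'   declared scale and units.
#' @param transpose If `TRUE` the file is samples-in-rows and is transposed
#'   on load.
#' @return An `ExpressionMatrix`.
#' @export
read_expression <- function(path, platform, transpose = FALSE) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  if (ncol(df) < 2L) stop("expression TSV needs an ID column plus >=1 sample")
  ids <- df[[1]]
  sample_ids <- colnames(df)[-1]  # before subsetting, which dedups names
  num <- df[, -1, drop = FALSE]
  vals <- matrix(NA_real_, nrow(num), ncol(num),
                 dimnames = list(ids, sample_ids))
  for (j in seq_len(ncol(num))) {
    parsed <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(parsed))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric value '%s' at row '%s', column '%s' of %s",
        num[[j]][bad[1]], ids[bad[1]], sample_ids[j], path))
    }
    vals[, j] <- parsed
  }
  if (transpose) vals <- t(vals)
  expression_matrix(vals, platform = platform)
}

#' Write an expression matrix to TSV
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
  invisible(path)
}

#' Gene length table for FPKM normalization
#'
#' @param gene_id Character vector of gene identifiers.
#' @param length Positive integer lengths in base pairs.
#' @return A `GeneLengths` data frame.
#' @export
gene_lengths <- function(gene_id, length) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("duplicate gene_id in lengths")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("gene lengths must be positive")
  }
  structure(data.frame(gene_id = gene_id, length = as.numeric(length),
                       stringsAsFactors = FALSE),
            class = c("GeneLengths", "data.frame"))
}

#' Read gene lengths from a two-column TSV (gene_id, length)
#'
#' @param path Path to a TSV file.
#' @return A `GeneLengths` data frame.
#' @export
read_gene_lengths <- function(path) {
  df <- read_tsv_strict(path)
  if (!all(c("gene_id", "length") %in% colnames(df))) {
    stop("lengths TSV needs columns gene_id, length")
  }
  gene_lengths(df$gene_id, df$length)
}
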