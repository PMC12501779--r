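# Probe-to-Entrez mapping and the method-family-specific normalization
# routes. Nearest-centroid methods consume log2-scale data (upper-quartile
# log2-CPM when starting from raw counts); single-sample predictors consume
# linear-scale data (FPKM from raw counts, 2^x otherwise).

#' Map a probe-level expression matrix to Entrez gene IDs
#'
#' Probes without an annotation entry are dropped and reported. When
#' several probes map to the same gene, the probe with the largest
#' interquartile range across samples is kept (ties broken by larger mean,
#' then lexicographically smallest probe ID) — variance-retaining
#' collapsing preserves classifier contrast.
#'
#' @param expr `ExpressionMatrix` keyed by probe ID.
#' @param annotation Data frame with columns `probe_id` and `entrez_id`.
#' @param required_genes Optional character vector of genes a downstream
#'   model needs; those absent from the mapped output are listed in the
#'   report.
#' @return List with elements `expr` (gene-keyed `ExpressionMatrix`) and
#'   `report` (a `MappingReport`: `n_input_probes`, `n_mapped_genes`,
#'   `dropped_unmapped`, `duplicates_collapsed`, `missing_model_genes`).
#' @export
map_to_entrez <- function(expr, annotation, required_genes = NULL) {
  if (!all(c("probe_id", "entrez_id") %in% colnames(annotation))) {
    stop("annotation needs columns probe_id, entrez_id")
  }
  v <- expr$values
  probes <- rownames(v)
  ann <- annotation[!is.na(annotation$entrez_id) &
                      nzchar(as.character(annotation$entrez_id)), ]
  ann <- ann[!duplicated(ann$probe_id), ]
  hit <- match(probes, as.character(ann$probe_id))
  entrez <- rep(NA_character_, length(probes))
  entrez[!is.na(hit)] <- as.character(ann$entrez_id[hit[!is.na(hit)]])
  if (all(is.na(entrez))) {
    stop("no input probe has an Entrez annotation")
  }
  dropped <- probes[is.na(entrez)]

  keep_idx <- integer(0)
  dup_records <- list()
  for (g in unique(entrez[!is.na(entrez)])) {
    idx <- which(!is.na(entrez) & entrez == g)
    if (length(idx) == 1L) {
      keep_idx <- c(keep_idx, idx)
      next
    }
    iqr <- apply(v[idx, , drop = FALSE], 1, stats::IQR)
    mu <- rowMeans(v[idx, , drop = FALSE])
    ord <- order(-iqr, -mu, probes[idx])
    keep <- idx[ord[1]]
    keep_idx <- c(keep_idx, keep)
    dup_records[[g]] <- data.frame(
      gene = g, kept = probes[keep],
      discarded = paste(probes[setdiff(idx, keep)], collapse = ","),
      stringsAsFactors = FALSE)
  }
  out_v <- v[keep_idx, , drop = FALSE]
  rownames(out_v) <- entrez[keep_idx]
  out <- expr
  out$values <- out_v
  validate_expression_matrix(out)

  duplicates <- if (length(dup_records)) {
    do.call(rbind, unname(dup_records))
  } else {
    data.frame(gene = character(0), kept = character(0),
               discarded = character(0), stringsAsFactors = FALSE)
  }
  n_discarded <- if (nrow(duplicates)) {
    sum(lengths(strsplit(duplicates$discarded, ",")))
  } else 0L
  report <- structure(
    list(n_input_probes = length(probes),
         n_mapped_genes = nrow(out_v),
         n_duplicates_discarded = n_discarded,
         dropped_unmapped = dropped,
         duplicates_collapsed = duplicates,
         missing_model_genes = setdiff(required_genes %||% character(0),
                                       rownames(out_v))),
    class = "MappingReport")
  stopifnot(report$n_input_probes ==
              report$n_mapped_genes + length(dropped) + n_discarded)
  list(expr = out, report = report)
}

#' Upper-quartile log2-CPM normalization of raw counts
#'
#' Per sample j, the upper-quartile factor is computed from the 75th
#' percentile q_j of that sample's nonzero counts: with raw library size
#' L_j, factors f_j = (q_j / L_j) / geomean(q / L) are rescaled to unit
#' geometric mean, the effective library is E_j = L_j * f_j, and the output
#' is log2(counts * 1e6 / E_j + offset). Percentiles use linear
#' interpolation between order statistics (R quantile type 7).
#'
#' @param counts `ExpressionMatrix` with `units = "counts"`.
#' @param offset Pseudocount added inside the log (default 1).
#' @return `ExpressionMatrix` with `scale = "log2"`, `units = "cpm"`.
#' @export
upper_quartile_log2cpm <- function(counts, offset = 1) {
  if (counts$units != "counts") stop("input must be raw counts")
  v <- counts$values
  lib <- colSums(v)
  zero <- colSums(v > 0) == 0
  if (any(zero)) {
    stop("all-zero sample(s): ", paste(colnames(v)[zero], collapse = ", "))
  }
  uq <- vapply(seq_len(ncol(v)), function(j) {
    x <- v[, j]
    stats::quantile(x[x > 0], probs = 0.75, names = FALSE, type = 7)
  }, 0)
  ratio <- uq / lib
  f <- ratio / geometric_mean(ratio)
  eff <- lib * f
  out_v <- log2(sweep(v, 2, eff, "/") * 1e6 + offset)
  out <- counts
  out$values <- out_v
  out$scale <- "log2"
  out$units <- "cpm"
  out$platform <- counts$platform
  out
}

#' Linear FPKM from raw counts and gene lengths
#'
#' FPKM_ij = counts_ij * 1e9 / (L_j * len_i) with L_j the raw column sum.
#' No cohort-level scaling is applied, so each sample's values depend only
#' on that sample.
#'
#' @param counts `ExpressionMatrix` with `units = "counts"`.
#' @param lengths A `GeneLengths` table covering every gene in `counts`.
#' @return `ExpressionMatrix` with `scale = "linear"`, `units = "fpkm"`.
#' @export
linear_fpkm <- function(counts, lengths) {
  if (counts$units != "counts") stop("input must be raw counts")
  v <- counts$values
  idx <- match(rownames(v), lengths$gene_id)
  if (any(is.na(idx))) {
    stop("missing gene length(s): ",
         paste(utils::head(rownames(v)[is.na(idx)], 10), collapse = ", "))
  }
  len <- lengths$length[idx]
  lib <- colSums(v)
  out_v <- sweep(sweep(v, 2, lib, "/"), 1, len, "/") * 1e9
  out <- counts
  out$values <- out_v
  out$scale <- "linear"
  out$units <- "fpkm"
  out
}

#' Route an expression matrix through the normalization required by a
#' method family
#'
#' Dispatch table (by platform and family): raw RNA-seq counts go to
#' upper-quartile log2-CPM for NC methods and to linear FPKM for SSP
#' methods; log2 inputs (precomputed log2-FPKM, microarray, nCounter) are
#' ingested unchanged for NC and back-transformed elementwise to the linear
#' scale (2^x, no pseudocount) for SSP. Already-prepared matrices pass
#' through unchanged, so the NC route is idempotent on normalized
#' platforms.
#'
#' @param expr An `ExpressionMatrix`.
#' @param lengths `GeneLengths`, required only for the counts-to-FPKM
#'   route.
#' @param family `"NC"` or `"SSP"`.
#' @param offset Pseudocount for the log2-CPM route.
#' @return An `ExpressionMatrix` on the scale the family consumes.
#' @export
prepare_matrix <- function(expr, lengths = NULL, family = c("NC", "SSP"),
                           offset = 1) {
  family <- match.arg(family)
  if (expr$units == "counts") {
    if (family == "NC") return(upper_quartile_log2cpm(expr, offset = offset))
    if (is.null(lengths)) {
      stop("gene lengths are required for the SSP route on raw counts")
    }
    return(linear_fpkm(expr, lengths))
  }
  if (family == "NC") {
    if (expr$scale != "log2") {
      stop("NC route expects log2-scale input for platform ", expr$platform)
    }
    return(expr)
  }
  # SSP on an already-normalized log2 matrix: back-transform elementwise.
  if (expr$scale == "log2") {
    out <- expr
    out$values <- 2^expr$values
    out$scale <- "linear"
    return(out)
  }
  expr
}
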