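# Nearest-centroid classification: a sample is assigned the subtype whose
# centroid profile it correlates with most strongly.

#' Classify samples by nearest centroid
#'
#' Per sample, the score for subtype k is the Spearman or Pearson
#' correlation (per the model) between the sample's centered profile and
#' centroid k over the genes shared by input and model. The label is the
#' argmax; exact score ties are broken by the model's subtype column order
#' and flagged. Gene coverage below 100% but at or above
#' `min_gene_fraction` sets the low-coverage flag; below the threshold the
#' run errors, listing the missing genes.
#'
#' @param centered Centered log2 `ExpressionMatrix` (see
#'   [apply_centering()]).
#' @param model A `CentroidModel`.
#' @return A `SubtypeCalls` data frame with per-subtype score columns.
#' @export
classify_nc <- function(centered, model) {
  v <- centered$values
  shared <- intersect(rownames(model$centroids), rownames(v))
  frac <- length(shared) / nrow(model$centroids)
  if (frac < model$min_gene_fraction) {
    missing <- setdiff(rownames(model$centroids), rownames(v))
    stop(sprintf(
      "gene coverage %.2f below minimum %.2f; missing model genes: %s",
      frac, model$min_gene_fraction,
      paste(utils::head(missing, 20), collapse = ", ")))
  }
  low_cov <- frac < 1
  cent <- model$centroids[shared, , drop = FALSE]
  x <- v[shared, , drop = FALSE]
  method <- if (model$correlation_kind == "spearman") "spearman" else "pearson"
  n <- ncol(v)
  scores <- matrix(NA_real_, n, length(model$subtypes),
                   dimnames = list(colnames(v), model$subtypes))
  # A constant centered profile (e.g. a singleton centering subgroup) has
  # no defined correlation: NA call rather than a warning.
  ok <- apply(x, 2, stats::sd) > 0
  if (any(ok)) {
    scores[ok, ] <- stats::cor(x[, ok, drop = FALSE], cent, method = method)
  }

  label <- rep(NA_character_, n)
  tie <- logical(n)
  for (i in which(ok)) {
    s <- scores[i, ]
    best <- which(s == max(s))
    label[i] <- model$subtypes[best[1]]  # model order breaks exact ties
    tie[i] <- length(best) > 1L
  }
  make_calls(colnames(v), label, scores, method = "nc",
             tie = tie, low_coverage = low_cov)
}
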