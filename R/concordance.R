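# Agreement statistics across classifiers: per-sample Shannon entropy of
# the label multiset, pairwise unweighted Cohen's kappa, and accuracy
# against a reference labeling.

#' Shannon entropy of a label multiset
#'
#' `H = -sum p_k log2 p_k` with `p_k` the label fractions over non-NA
#' calls; 0 bits means unanimity, `log2(m)` bits means `m` methods all
#' disagree. NA calls are excluded from the denominator; an all-NA input
#' returns NA with the `"all_na"` attribute set.
#'
#' @param labels Character vector of subtype labels (NA allowed).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0L) {
    return(structure(NA_real_, all_na = TRUE))
  }
  p <- as.numeric(table(labels)) / length(labels)
  -sum(p * log2(p))
}

#' Unweighted Cohen's kappa between two label vectors
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with `p_o` the observed agreement and
#' `p_e` the chance agreement from the two marginal label distributions.
#' Pairs with NA in either vector are dropped (count recorded in the
#' `"dropped"` attribute). In the degenerate case `p_e = 1` (both vectors
#' constant on one shared label) kappa is defined as 1 when `p_o = 1` and
#' 0 otherwise, with the `"degenerate"` attribute set.
#'
#' @param a,b Equal-length label vectors.
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  keep <- !is.na(a) & !is.na(b)
  dropped <- sum(!keep)
  a <- as.character(a[keep])
  b <- as.character(b[keep])
  n <- length(a)
  if (n < 2L) stop("fewer than 2 usable (non-NA) pairs")
  labs <- sort(unique(c(a, b)))
  pa <- as.numeric(table(factor(a, labs))) / n
  pb <- as.numeric(table(factor(b, labs))) / n
  po <- mean(a == b)
  pe <- sum(pa * pb)
  if (abs(1 - pe) < .Machine$double.eps * 8) {
    k <- if (po == 1) 1 else 0
    return(structure(k, dropped = dropped, degenerate = TRUE))
  }
  structure((po - pe) / (1 - pe), dropped = dropped, degenerate = FALSE)
}

#' Percent agreement with a reference labeling
#'
#' @param a Label vector to score.
#' @param ref Reference label vector of the same length.
#' @return Percentage of matching pairs over usable (non-NA) pairs, with
#'   the `"dropped"` attribute counting NA pairs.
#' @export
accuracy <- function(a, ref) {
  if (length(a) != length(ref)) stop("label vectors must have equal length")
  keep <- !is.na(a) & !is.na(ref)
  if (sum(keep) < 1L) stop("no usable (non-NA) pairs")
  structure(100 * mean(a[keep] == ref[keep]), dropped = sum(!keep))
}

#' Concordance report for a call matrix
#'
#' @param calls Samples x methods matrix (or data frame) of subtype
#'   labels, NA allowed.
#' @param reference Optional reference label vector (one per sample) for
#'   accuracy/kappa columns.
#' @return A `ConcordanceReport`: per-sample `entropy` (bits),
#'   `mean_entropy`, symmetric `kappa` matrix over methods (unit
#'   diagonal), and, when a reference is given, per-method `accuracy` and
#'   `kappa_vs_reference`.
#' @export
concordance_report <- function(calls, reference = NULL) {
  m <- as.matrix(calls)
  ent <- apply(m, 1, function(r) as.numeric(shannon_entropy(r)))
  methods <- colnames(m)
  k <- matrix(NA_real_, length(methods), length(methods),
              dimnames = list(methods, methods))
  for (i in seq_along(methods)) {
    k[i, i] <- 1
    for (j in seq_len(i - 1L)) {
      kij <- tryCatch(as.numeric(cohens_kappa(m[, i], m[, j])),
                      error = function(e) NA_real_)
      k[i, j] <- kij
      k[j, i] <- kij
    }
  }
  out <- list(entropy = stats::setNames(ent, rownames(m)),
              mean_entropy = mean(ent, na.rm = TRUE),
              kappa = k)
  if (!is.null(reference)) {
    out$accuracy <- vapply(methods, function(mm) {
      tryCatch(as.numeric(accuracy(m[, mm], reference)),
               error = function(e) NA_real_)
    }, 0)
    out$kappa_vs_reference <- vapply(methods, function(mm) {
      tryCatch(as.numeric(cohens_kappa(m[, mm], reference)),
               error = function(e) NA_real_)
    }, 0)
  }
  structure(out, class = "ConcordanceReport")
}
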