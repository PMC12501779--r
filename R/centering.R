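# Cohort-centering strategies for the nearest-centroid engine. The choice
# of centering is what distinguishes the eight NC registry methods: a
# centroid model lives in reference-median-centered space, and each
# strategy is a different estimator of that reference median.

#' Specify a centering strategy
#'
#' @param strategy One of `"median"`, `"robust_scale"`, `"cihc"`,
#'   `"cihc_iterative"`, `"pca_guided"`, `"ssbc_quantile"`.
#' @param target_er_prop Target ER+ proportion for the IHC-guided
#'   strategies; default 54/118, the ER+ fraction of the PAM50 training
#'   cohort (UNC232).
#' @param quantiles `QuantileTable` for `"ssbc_quantile"`.
#' @param subgroup Subgroup label forcing a single centering group for
#'   `"ssbc_quantile"`; when `NULL` each sample is assigned its subgroup
#'   from the clinical table according to `version`.
#' @param version Subgroup scheme for `"ssbc_quantile"`: 1 = ER side
#'   (ER+/ER-/TN), 2 = ER/HER2 combination.
#' @param max_iter Iteration cap for `"cihc_iterative"` (default 100).
#' @return A `CenteringSpec`.
#' @export
centering_spec <- function(strategy = c("median", "robust_scale", "cihc",
                                        "cihc_iterative", "pca_guided",
                                        "ssbc_quantile"),
                           target_er_prop = 54 / 118,
                           quantiles = NULL, subgroup = NULL, version = 1L,
                           max_iter = 100L) {
  strategy <- match.arg(strategy)
  if (target_er_prop <= 0 || target_er_prop >= 1) {
    stop("target_er_prop must be in (0, 1)")
  }
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (strategy == "ssbc_quantile" && is.null(quantiles)) {
    stop("ssbc_quantile centering needs a quantile table")
  }
  if (!is.null(subgroup)) subgroup <- normalize_subgroup(subgroup)
  structure(list(strategy = strategy, target_er_prop = target_er_prop,
                 quantiles = quantiles, subgroup = subgroup,
                 version = as.integer(version), max_iter = as.integer(max_iter)),
            class = "CenteringSpec")
}

# Deterministic, seeded draw of a subcohort whose ER+ fraction matches the
# target: all of the group that is scarce relative to the target is kept
# and the other group is subsampled without replacement.
draw_ihc_subcohort <- function(er, target, seed) {
  pos <- which(er == "pos")
  neg <- which(er == "neg")
  if (length(pos) == 0L || length(neg) == 0L) {
    stop(sprintf(
      "cannot form an ER-balanced subcohort: %d ER+ and %d ER- samples",
      length(pos), length(neg)))
  }
  frac <- length(pos) / (length(pos) + length(neg))
  withr::with_seed(seed, {
    if (frac > target) {
      k <- min(length(pos), max(1L, round(target / (1 - target) * length(neg))))
      sel <- c(sample(pos, k), neg)
    } else {
      k <- min(length(neg), max(1L, round((1 - target) / target * length(pos))))
      sel <- c(pos, sample(neg, k))
    }
    sort(sel)
  })
}

center_by_medians <- function(v, idx) {
  med <- apply(v[, idx, drop = FALSE], 1, stats::median)
  sweep(v, 1, med, "-")
}

# PC1-based ER surrogate labels: scores on the first principal component,
# sign-oriented to correlate positively with the available IHC ER labels
# (fallback: positive loading of the highest-variance gene).
pca_er_surrogate <- function(v, er) {
  pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  score <- pc$x[, 1]
  known <- er %in% c("pos", "neg")
  flip <- FALSE
  if (any(known) && stats::sd(score[known]) > 0 &&
      length(unique(er[known])) > 1L) {
    r <- stats::cor(score[known], as.numeric(er[known] == "pos"))
    if (is.finite(r) && r < 0) flip <- TRUE
  } else {
    top <- which.max(apply(v, 1, stats::var))
    if (pc$rotation[top, 1] < 0) flip <- TRUE
  }
  if (flip) score <- -score
  ifelse(score > 0, "pos", "neg")
}

# Grouped subgroup-quantile centering: per gene g and group s, subtract
# quantile(x_g over samples in s, p = quantile_prob[g, s]).
center_by_quantiles <- function(v, groups, quantiles) {
  out <- v
  for (s in unique(groups)) {
    cols <- which(groups == s)
    qt <- quantiles[quantiles$subgroup == s, ]
    if (nrow(qt) == 0L) {
      stop("quantile table has no entries for subgroup ", s)
    }
    p <- qt$quantile_prob[match(rownames(v), qt$gene_id)]
    if (any(is.na(p))) {
      stop("quantile table lacks subgroup ", s, " entries for gene(s): ",
           paste(utils::head(rownames(v)[is.na(p)], 10), collapse = ", "))
    }
    qv <- vapply(seq_len(nrow(v)), function(i) {
      stats::quantile(v[i, cols], probs = p[i], names = FALSE, type = 7)
    }, 0)
    out[, cols] <- sweep(v[, cols, drop = FALSE], 1, qv, "-")
  }
  out
}

# Subgroup label per sample for ssBC centering. version 1: ER side (with
# "TN" for declared triple-negatives); version 2: ER/HER2 combination.
sample_subgroups <- function(clinical, version) {
  if (version == 1L) {
    out <- ifelse(clinical$tn, "TN",
                  ifelse(clinical$er == "pos", "ER+",
                         ifelse(clinical$er == "neg", "ER-", NA_character_)))
  } else {
    out <- erher2_subgroup(clinical)
  }
  out
}

#' Apply a centering strategy to a log2 expression matrix
#'
#' Strategy semantics:
#' * `median` — subtract each gene's cohort median.
#' * `robust_scale` — per gene, `(x - q05) / (q95 - q05) - 0.5`: a
#'   location/scale rescaling robust to outliers.
#' * `cihc` — draw (deterministically, seeded) a subcohort whose ER+
#'   fraction matches `target_er_prop` using the IHC ER labels, then
#'   subtract per-gene medians computed on that subcohort from all
#'   samples.
#' * `cihc_iterative` — iterate cIHC centering and classification,
#'   re-drawing the subcohort from ER-surrogate labels (luminal call =
#'   ER+) until the call vector stabilizes or `max_iter` is reached; the
#'   iteration count is recorded in the `"iterations"` attribute.
#' * `pca_guided` — replace IHC ER labels by thresholding oriented
#'   first-principal-component scores, then proceed as cIHC.
#' * `ssbc_quantile` — per gene, subtract the cohort (or subgroup) sample
#'   quantile at the gene's tabulated probability.
#'
#' @param expr Log2-scale `ExpressionMatrix` (run [prepare_matrix()] with
#'   `family = "NC"` first).
#' @param spec A `CenteringSpec`.
#' @param clinical `ClinicalTable` matched by sample ID; required for the
#'   IHC-guided and subgroup strategies.
#' @param model `CentroidModel`, required by `cihc_iterative` (it
#'   classifies between iterations).
#' @param seed Integer seed controlling the subcohort draws.
#' @return Centered `ExpressionMatrix` (scale remains `"log2"`).
#' @export
apply_centering <- function(expr, spec, clinical = NULL, model = NULL,
                            seed = 1L) {
  if (expr$scale != "log2") stop("centering expects a log2-scale matrix")
  v <- expr$values
  need_clin <- spec$strategy %in% c("cihc", "cihc_iterative", "ssbc_quantile")
  er <- NULL
  if (!is.null(clinical)) {
    idx <- match(colnames(v), clinical$sample_id)
    if (need_clin && any(is.na(idx))) {
      stop("clinical table missing sample(s): ",
           paste(utils::head(colnames(v)[is.na(idx)], 5), collapse = ", "))
    }
    clinical <- clinical[idx, , drop = FALSE]
    er <- clinical$er
  } else if (need_clin && is.null(spec$subgroup)) {
    stop("centering strategy ", spec$strategy, " needs a clinical table")
  }

  out_v <- switch(spec$strategy,
    median = sweep(v, 1, apply(v, 1, stats::median), "-"),
    robust_scale = {
      q05 <- apply(v, 1, stats::quantile, probs = 0.05, names = FALSE)
      q95 <- apply(v, 1, stats::quantile, probs = 0.95, names = FALSE)
      span <- q95 - q05
      if (any(span <= 0)) {
        stop("degenerate 5-95% span for gene(s): ",
             paste(utils::head(rownames(v)[span <= 0], 5), collapse = ", "))
      }
      sweep(sweep(v, 1, q05, "-"), 1, span, "/") - 0.5
    },
    cihc = center_by_medians(v, draw_ihc_subcohort(er, spec$target_er_prop,
                                                   seed)),
    cihc_iterative = {
      if (is.null(model)) stop("cihc_iterative needs a centroid model")
      labels <- er
      prev <- NULL
      iters <- 0L
      centered <- v
      for (i in seq_len(spec$max_iter)) {
        iters <- i
        sub <- draw_ihc_subcohort(labels, spec$target_er_prop, seed + i - 1L)
        centered <- center_by_medians(v, sub)
        tmp <- expr
        tmp$values <- centered
        calls <- classify_nc(tmp, model)$label
        if (!is.null(prev) && identical(calls, prev)) break
        prev <- calls
        labels <- ifelse(calls %in% c("LumA", "LumB"), "pos", "neg")
      }
      attr(centered, "iterations") <- iters
      centered
    },
    pca_guided = {
      surrogate <- pca_er_surrogate(v, er %||% rep("unknown", ncol(v)))
      center_by_medians(v, draw_ihc_subcohort(surrogate, spec$target_er_prop,
                                              seed))
    },
    ssbc_quantile = {
      groups <- if (!is.null(spec$subgroup)) {
        rep(spec$subgroup, ncol(v))
      } else {
        g <- sample_subgroups(clinical, spec$version)
        if (any(is.na(g))) {
          stop("cannot assign a centering subgroup (unknown ER/HER2) for: ",
               paste(utils::head(colnames(v)[is.na(g)], 5), collapse = ", "))
        }
        g
      }
      center_by_quantiles(v, groups, spec$quantiles)
    })

  out <- expr
  iters <- attr(out_v, "iterations")
  attr(out_v, "iterations") <- NULL
  out$values <- out_v
  if (!is.null(iters)) attr(out, "iterations") <- iters
  out
}
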