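# Synthetic world: toy classifier models and cohort simulation with
# controlled ER/HER2 composition. Expression for a sample of subtype k is
# its subtype's raw log2 profile plus i.i.d. Gaussian noise; clinical
# biomarkers are drawn from subtype-conditional probabilities. Centroid,
# quantile and rule-set models are derived analytically from the same
# generative model, so every classifier family is exercised on data that
# satisfies (or, by resampling, deliberately violates) its assumptions.

.default_proportions <- c(LumA = 0.45, LumB = 0.20, Her2 = 0.10,
                          Basal = 0.18, Normal = 0.07)
.default_er <- c(LumA = 0.95, LumB = 0.85, Her2 = 0.30, Basal = 0.10,
                 Normal = 0.60)
.default_pr <- c(LumA = 0.90, LumB = 0.75, Her2 = 0.25, Basal = 0.08,
                 Normal = 0.55)
.default_her2 <- c(LumA = 0.10, LumB = 0.10, Her2 = 0.80, Basal = 0.08,
                   Normal = 0.10)

#' Specify a synthetic cohort
#'
#' Defaults describe an unselected breast-cancer cohort: subtype mix
#' LumA 45%, LumB 20%, Her2 10%, Basal 18%, Normal 7%; ER+ rates per
#' subtype 0.95/0.85/0.30/0.10/0.60; HER2+ rates 0.10 except 0.80 for the
#' HER2-enriched subtype; log2-scale Gaussian noise sd 0.3; cohort size
#' 118 and 100 replicates, matching the resampling protocol the selector's
#' cutoffs were derived under.
#'
#' @param n_genes Number of genes (>= 10).
#' @param proportions Named subtype proportions summing to 1.
#' @param er_given_subtype,pr_given_subtype,her2_given_subtype Named
#'   per-subtype biomarker-positive probabilities.
#' @param noise_sd Log2-scale Gaussian within-subtype noise standard
#'   deviation.
#' @param effect_sd Log2-scale standard deviation of per-gene subtype
#'   contrasts (default 0.2): deliberately below `noise_sd` so that
#'   single-gene contrasts are weak and classification relies on the whole
#'   profile, as in real expression data, leaving samples near decision
#'   boundaries where centering bias matters.
#' @param n Cohort size.
#' @param replicates Number of replicates for resampling procedures.
#' @param seed Integer seed.
#' @return A `SimSpec`.
#' @export
sim_spec <- function(n_genes = 60L,
                     proportions = .default_proportions,
                     er_given_subtype = .default_er,
                     pr_given_subtype = .default_pr,
                     her2_given_subtype = .default_her2,
                     noise_sd = 0.3, effect_sd = 0.2, n = 118L,
                     replicates = 100L, seed = 1L) {
  stopifnot(n_genes >= 10L, n >= 1L, replicates >= 1L, effect_sd > 0)
  proportions <- proportions[subtype_labels()]
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  for (p in list(er_given_subtype, pr_given_subtype, her2_given_subtype)) {
    if (any(p < 0 | p > 1)) stop("conditional probabilities must be in [0,1]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_genes = as.integer(n_genes), proportions = proportions,
                 er_given_subtype = er_given_subtype[subtype_labels()],
                 pr_given_subtype = pr_given_subtype[subtype_labels()],
                 her2_given_subtype = her2_given_subtype[subtype_labels()],
                 noise_sd = noise_sd, effect_sd = effect_sd,
                 n = as.integer(n),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "SimSpec")
}

# Median of the 5-component normal mixture per gene (the reference
# population median the centroid model is centered on).
mixture_median <- function(raw, weights, sd) {
  vapply(seq_len(nrow(raw)), function(i) {
    mus <- raw[i, ]
    lo <- min(mus) - 6 * sd
    hi <- max(mus) + 6 * sd
    stats::uniroot(function(x) sum(weights * stats::pnorm(x, mus, sd)) - 0.5,
                   c(lo, hi), tol = 1e-10)$root
  }, 0)
}

# Subtype posterior weights given a clinical subgroup.
subgroup_weights <- function(spec, subgroup) {
  er <- spec$er_given_subtype
  pr <- spec$pr_given_subtype
  h2 <- spec$her2_given_subtype
  pi <- spec$proportions
  w <- switch(subgroup,
    "ER+" = pi * er,
    "ER-" = pi * (1 - er),
    "TN" = pi * (1 - er) * (1 - pr) * (1 - h2),
    "ER+/HER2-" = pi * er * (1 - h2),
    "ER+/HER2+" = pi * er * h2,
    "ER-/HER2+" = pi * (1 - er) * h2,
    "ER-/HER2-" = pi * (1 - er) * (1 - h2))
  w / sum(w)
}

#' Generate internally consistent toy classifier models
#'
#' Raw per-subtype log2 expression profiles are drawn from a factor model
#' that emulates the correlation structure of real intrinsic subtypes —
#' a luminal continuum (LumB loads 0.45 on the LumA factor), Normal-like
#' overlapping LumA (loading 0.35), HER2-enriched sharing a mild LumB
#' component (0.30), and Basal-like anti-correlated with luminal (-0.30) —
#' scaled to `effect_sd` per gene, and redrawn until all signed pairwise
#' correlations of the centered centroids are < 0.5. Every model is then
#' derived analytically from the generative world:
#' * the centroid model is the raw profiles centered on the reference
#'   population median (the mixture median under `spec$proportions`);
#' * the quantile table stores, per gene and clinical subgroup, the
#'   probability mass of the subgroup's mixture below the reference
#'   median, so subgroup-quantile centering recovers reference-median
#'   centering inside a subgroup cohort;
#' * the rule set takes informative gene pairs with exact
#'   class-conditional firing probabilities
#'   `P(x_a < x_b | k) = pnorm((raw_bk - raw_ak) / (sqrt(2) * noise_sd))`,
#'   clipped to \[0.01, 0.99\].
#'
#' @param spec A `SimSpec` (its `n_genes`, `noise_sd`, proportions and
#'   conditionals define the world).
#' @param n_rules Number of gene-pair rules.
#' @param seed Seed (default `spec$seed`).
#' @return List with `centroid` (`CentroidModel`), `quantiles`
#'   (`QuantileTable`), `ruleset` (`RuleSet`), `lengths` (`GeneLengths`)
#'   and `ref_median` (numeric vector used by [simulate_cohort()]).
#' @export
make_toy_models <- function(spec = sim_spec(), n_rules = 50L,
                            seed = spec$seed) {
  if (spec$n_genes < 10L) stop("need at least 10 genes")
  if (spec$noise_sd <= 0) stop("model derivation needs noise_sd > 0")
  withr::with_seed(seed, {
    genes <- sprintf("%d", 10000L + seq_len(spec$n_genes))
    raw <- NULL
    for (try in 1:50) {
      z <- matrix(stats::rnorm(spec$n_genes * 5), spec$n_genes, 5)
      cand <- cbind(
        LumA   = z[, 1],
        LumB   = 0.45 * z[, 1] + sqrt(1 - 0.45^2) * z[, 2],
        Her2   = 0.30 * z[, 2] + sqrt(1 - 0.30^2) * z[, 3],
        Basal  = -0.30 * z[, 1] + sqrt(1 - 0.30^2) * z[, 4],
        Normal = 0.35 * z[, 1] + sqrt(1 - 0.35^2) * z[, 5]) * spec$effect_sd
      rownames(cand) <- genes
      m <- mixture_median(cand, spec$proportions, spec$noise_sd)
      cent <- cand - m
      cors <- stats::cor(cent)
      # Separation invariant on similarity: signed correlation < 0.5
      # (anti-correlated centroids are maximally separated).
      if (max(cors[upper.tri(cors)]) < 0.5) {
        raw <- cand
        ref_median <- m
        centroids <- cent
        break
      }
    }
    if (is.null(raw)) {
      stop("could not draw centroids with pairwise correlation < 0.5 at ",
           spec$n_genes, " genes")
    }

    subgroups <- c("ER+", "ER-", "TN", "ER+/HER2-", "ER+/HER2+",
                   "ER-/HER2+", "ER-/HER2-")
    qt <- do.call(rbind, lapply(subgroups, function(s) {
      w <- subgroup_weights(spec, s)
      p <- vapply(seq_len(spec$n_genes), function(i) {
        sum(w * stats::pnorm(ref_median[i], raw[i, ], spec$noise_sd))
      }, 0)
      data.frame(gene_id = genes, subgroup = s,
                 quantile_prob = pmin(pmax(p, 0.02), 0.98),
                 stringsAsFactors = FALSE)
    }))

    # Informative gene pairs: firing probability varies across subtypes.
    cand_a <- sample(genes, 30L * n_rules, replace = TRUE)
    cand_b <- sample(genes, 30L * n_rules, replace = TRUE)
    ok <- cand_a != cand_b
    cand_a <- cand_a[ok]
    cand_b <- cand_b[ok]
    ia <- match(cand_a, genes)
    ib <- match(cand_b, genes)
    probs <- matrix(0, length(ia), 5, dimnames = list(NULL, subtype_labels()))
    for (k in 1:5) {
      probs[, k] <- stats::pnorm((raw[ib, k] - raw[ia, k]) /
                                   (sqrt(2) * spec$noise_sd))
    }
    info <- apply(probs, 1, stats::sd) > 0.15
    if (sum(info) < n_rules) {
      stop("too few informative gene pairs; increase n_genes")
    }
    pick <- which(info)[seq_len(n_rules)]
    ruleset <- suppressWarnings(rule_set(
      cand_a[pick], cand_b[pick],
      pmin(pmax(probs[pick, , drop = FALSE], 0.01), 0.99)))

    lengths <- gene_lengths(genes, sample(200:20000, spec$n_genes,
                                          replace = TRUE))
    list(centroid = centroid_model(centroids),
         quantiles = quantile_table(qt$gene_id, qt$subgroup,
                                    qt$quantile_prob),
         ruleset = ruleset,
         lengths = lengths,
         ref_median = stats::setNames(ref_median, genes))
  })
}

#' Simulate a cohort from the toy generative model
#'
#' Each sample draws a subtype from the spec's proportions; log2
#' expression is the subtype's raw profile plus N(0, noise_sd^2) noise per
#' gene; ER/PR/HER2 statuses are Bernoulli draws from the subtype
#' conditionals. The matrix is tagged as log2 normalized intensities
#' (`platform = "microarray"`), the route on which NC methods ingest data
#' unchanged and SSP methods back-transform.
#'
#' @param spec A `SimSpec`.
#' @param models Output of [make_toy_models()] (its `ref_median` restores
#'   the raw profiles).
#' @param n Cohort size (default `spec$n`).
#' @param seed Seed (default `spec$seed`).
#' @param declare_tn If `TRUE`, triple-negative samples (ER-/PR-/HER2-)
#'   get an explicit TN declaration.
#' @return List with `expr` (`ExpressionMatrix`), `clinical`
#'   (`ClinicalTable`) and `truth` (character vector of true subtypes).
#' @export
simulate_cohort <- function(spec, models, n = spec$n, seed = spec$seed,
                            declare_tn = FALSE) {
  raw <- models$centroid$centroids + models$ref_median
  genes <- rownames(raw)
  withr::with_seed(seed, {
    subtype <- sample(subtype_labels(), n, replace = TRUE,
                      prob = spec$proportions)
    v <- raw[, subtype, drop = FALSE] +
      matrix(stats::rnorm(length(genes) * n, 0, spec$noise_sd),
             length(genes), n)
    ids <- sprintf("s%04d", seq_len(n))
    dimnames(v) <- list(genes, ids)
    er <- ifelse(stats::runif(n) < spec$er_given_subtype[subtype],
                 "pos", "neg")
    pr <- ifelse(stats::runif(n) < spec$pr_given_subtype[subtype],
                 "pos", "neg")
    her2 <- ifelse(stats::runif(n) < spec$her2_given_subtype[subtype],
                   "pos", "neg")
    tn <- declare_tn & er == "neg" & pr == "neg" & her2 == "neg"
    list(expr = expression_matrix(v, platform = "microarray"),
         clinical = clinical_table(ids, er, pr, her2, tn),
         truth = stats::setNames(subtype, ids))
  })
}

#' Convert a simulated log2 cohort to a raw-counts cohort
#'
#' Library-size model: linear abundance `2^x` is scaled so each sample's
#' counts sum to a log-normal library size (meanlog `log(5e5)`, sdlog
#' 0.2), then rounded. Exercises the raw-counts normalization routes.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param seed Seed for the library-size draws.
#' @return The cohort with `expr` replaced by a `rnaseq_counts` matrix.
#' @export
as_counts_cohort <- function(cohort, seed = 1L) {
  lin <- 2^cohort$expr$values
  withr::with_seed(seed, {
    lib <- stats::rlnorm(ncol(lin), log(5e5), 0.2)
  })
  counts <- round(sweep(sweep(lin, 2, colSums(lin), "/"), 2, lib, "*"))
  out <- cohort
  out$expr <- expression_matrix(counts, platform = "rnaseq_counts")
  out
}

# Subset a cohort to the given sample indices.
subset_cohort <- function(cohort, idx) {
  ids <- colnames(cohort$expr$values)[idx]
  list(expr = subset_expression(cohort$expr, samples = ids),
       clinical = structure(
         cohort$clinical[match(ids, cohort$clinical$sample_id), ,
                         drop = FALSE],
         class = class(cohort$clinical)),
       truth = cohort$truth[ids])
}

#' Resample a subcohort with a controlled composition
#'
#' Draws `n` samples without replacement from a larger simulated cohort:
#' either at a target ER+ fraction (`er_fraction`) or from a clinical
#' subgroup pool (`subgroup` one of `"ER+"`, `"ER-"`, `"TN"`).
#'
#' @param cohort A simulated mega-cohort.
#' @param n Subcohort size.
#' @param er_fraction Target ER+ fraction in \[0, 1\].
#' @param subgroup Alternative to `er_fraction`: a pure-subgroup draw.
#' @param seed Seed.
#' @return A cohort list (`expr`, `clinical`, `truth`).
#' @export
resample_cohort <- function(cohort, n = 118L, er_fraction = NULL,
                            subgroup = NULL, seed = 1L) {
  clin <- cohort$clinical
  withr::with_seed(seed, {
    if (!is.null(subgroup)) {
      pool <- switch(subgroup,
        "ER+" = which(clin$er == "pos"),
        "ER-" = which(clin$er == "neg"),
        "TN" = which(clin$tn),
        stop("unknown subgroup: ", subgroup))
      if (length(pool) < n) {
        stop(sprintf("pool too small: %d %s samples for n=%d",
                     length(pool), subgroup, n))
      }
      idx <- sample(pool, n)
    } else {
      n_pos <- round(er_fraction * n)
      pos <- which(clin$er == "pos")
      neg <- which(clin$er == "neg")
      if (length(pos) < n_pos || length(neg) < n - n_pos) {
        stop("mega-cohort too small to resample at ER+ fraction ",
             er_fraction)
      }
      idx <- c(sample(pos, n_pos), sample(neg, n - n_pos))
    }
    subset_cohort(cohort, sort(idx))
  })
}
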