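# Desk-scale re-implementations of the two simulation procedures behind
# the selector: (1) deriving ER-deviation cutoffs from a kappa-drop
# criterion over resampled subcohorts, and (2) benchmarking the
# AUTO-enabled method set against the methods it excludes.

# Kappa of a method's calls against true labels on one subcohort; NA when
# the method cannot run on that composition.
.method_kappa <- function(method, sub, models, seed, registry) {
  calls <- tryCatch(
    run_method(method, sub$expr, clinical = sub$clinical, models = models,
               seed = seed, registry = registry),
    error = function(e) NULL)
  if (is.null(calls)) return(NA_real_)
  as.numeric(cohens_kappa(calls$label, unname(sub$truth)))
}

#' Derive ER-deviation cutoffs by resampling
#'
#' For each ER+ fraction f in the grid, draws `R` subcohorts of size `n`
#' at composition f from the mega-cohort, runs the designated method, and
#' computes Cohen's kappa against the true labels. A fraction is flagged
#' as deviated when its mean kappa sits at least `drop` below the mean at
#' the reference fraction (54/118 by default) AND a one-sided two-sample
#' t-test of kappa(f) < kappa(reference) gives P < `alpha`. The inner
#' boundaries of the contiguous flagged regions on each side of the
#' reference are reported.
#'
#' @param mega A large simulated cohort (see [simulate_cohort()]).
#' @param models Toy models from [make_toy_models()].
#' @param method Registry method to evaluate (default the median-centered
#'   NC method).
#' @param er_fracs Grid of ER+ fractions; must contain `reference`.
#' @param R Replicates per fraction (default 100).
#' @param n Subcohort size (default 118).
#' @param drop Minimum mean kappa drop (default 0.05, i.e. 5 points).
#' @param alpha t-test significance level (default 0.01).
#' @param reference Reference ER+ fraction (default 54/118).
#' @param seed Seed.
#' @param registry Method registry.
#' @return A `cutoff_report`: `table` (fraction, mean/sd kappa, p-value,
#'   flagged), `low_inner`/`high_inner` region boundaries, and the
#'   protocol parameters.
#' @export
derive_cutoffs <- function(mega, models, method = "parker.original",
                           er_fracs = sort(unique(c(seq(0.1, 0.9, 0.1),
                                                    54 / 118))),
                           R = 100L, n = 118L, drop = 0.05, alpha = 0.01,
                           reference = 54 / 118, seed = 1L,
                           registry = default_registry()) {
  ref_idx <- which(abs(er_fracs - reference) < 1e-9)
  if (length(ref_idx) != 1L) {
    stop("er_fracs grid must contain the reference fraction ",
         signif(reference, 4))
  }
  kappas <- matrix(NA_real_, R, length(er_fracs))
  for (fi in seq_along(er_fracs)) {
    for (r in seq_len(R)) {
      s <- seed + fi * 100000L + r
      sub <- resample_cohort(mega, n = n, er_fraction = er_fracs[fi],
                             seed = s)
      kappas[r, fi] <- .method_kappa(method, sub, models, seed = s,
                                     registry = registry)
    }
  }
  ref_k <- kappas[, ref_idx]
  mean_k <- colMeans(kappas, na.rm = TRUE)
  flagged <- logical(length(er_fracs))
  pvals <- rep(NA_real_, length(er_fracs))
  for (fi in seq_along(er_fracs)) {
    if (fi == ref_idx) next  # never flag the self-comparison
    pvals[fi] <- tryCatch(
      stats::t.test(kappas[, fi], ref_k, alternative = "less")$p.value,
      error = function(e) NA_real_)
    flagged[fi] <- !is.na(pvals[fi]) &&
      mean_k[fi] <= mean_k[ref_idx] - drop && pvals[fi] < alpha
  }
  low <- er_fracs < er_fracs[ref_idx]
  high <- er_fracs > er_fracs[ref_idx]
  low_inner <- if (any(flagged & low)) max(er_fracs[flagged & low]) else NA
  high_inner <- if (any(flagged & high)) min(er_fracs[flagged & high]) else NA
  structure(
    list(table = data.frame(er_fraction = er_fracs, mean_kappa = mean_k,
                            sd_kappa = apply(kappas, 2, stats::sd,
                                             na.rm = TRUE),
                            p_value = pvals, flagged = flagged),
         low_inner = low_inner, high_inner = high_inner,
         method = method,
         params = list(R = R, n = n, drop = drop, alpha = alpha,
                       reference = reference, seed = seed)),
    class = "cutoff_report")
}

.scenarios <- c("S10", "S90", "ER+", "ER-", "TN")

# Cohort type + resampling recipe per benchmark scenario.
.scenario_recipe <- function(scenario) {
  scenario <- gsub("−", "-", scenario)
  scenario <- switch(scenario,
    "pure ER+" = "ER+", "pure ER-" = "ER-", "pure TN" = "TN", scenario)
  if (!scenario %in% .scenarios) {
    stop("unknown scenario: ", scenario, " (expected one of ",
         paste(.scenarios, collapse = ", "), ")")
  }
  switch(scenario,
    S10 = list(cohort_type = "unselected", er_fraction = 0.10),
    S90 = list(cohort_type = "unselected", er_fraction = 0.90),
    "ER+" = list(cohort_type = "ER+", subgroup = "ER+"),
    "ER-" = list(cohort_type = "ER-", subgroup = "ER-"),
    "TN" = list(cohort_type = "TN", subgroup = "TN"))
}

#' Benchmark AUTO-enabled methods against the methods AUTO excludes
#'
#' For each replicate, resamples a subcohort of the requested composition,
#' runs the selector, executes both the enabled and the excluded method
#' sets, and scores every method's calls against the true labels. Methods
#' that cannot run on the composition (e.g. IHC-balanced centering on a
#' pure-ER+ cohort) contribute NA and are excluded from set means.
#'
#' @param scenario One of `"S10"`, `"S90"`, `"ER+"`, `"ER-"`, `"TN"`
#'   (aliases `"pure ER+"` etc. accepted): two skewed ER+ mixes at 10% and
#'   90%, and three pure subtype-specific cohorts.
#' @param mega A large simulated cohort; for the TN scenario it must carry
#'   TN declarations (`declare_tn = TRUE` in [simulate_cohort()]).
#' @param models Toy models.
#' @param R Replicates (default 25).
#' @param n Subcohort size (default 118).
#' @param seed Seed.
#' @param registry Method registry.
#' @return A `benchmark_report`: per-set mean +/- sd accuracy and kappa,
#'   per-replicate deltas (percentage points), and the scenario recipe.
#' @export
auto_vs_excluded <- function(scenario, mega, models, R = 25L, n = 118L,
                             seed = 1L, registry = default_registry()) {
  recipe <- .scenario_recipe(scenario)
  acc <- list(auto = numeric(0), excluded = numeric(0))
  kap <- list(auto = numeric(0), excluded = numeric(0))
  delta_acc <- numeric(0)
  for (r in seq_len(R)) {
    s <- seed + r
    sub <- if (is.null(recipe$subgroup)) {
      resample_cohort(mega, n = n, er_fraction = recipe$er_fraction,
                      seed = s)
    } else {
      resample_cohort(mega, n = n, subgroup = recipe$subgroup, seed = s)
    }
    decision <- select_methods(cohort_diagnostics(sub$clinical),
                               cohort_type = recipe$cohort_type,
                               registry = registry)
    score_set <- function(methods) {
      a <- k <- rep(NA_real_, length(methods))
      for (i in seq_along(methods)) {
        m <- methods[i]
        subgroup <- if (m == "ssBC" && !is.na(decision$ssbc_subgroup)) {
          decision$ssbc_subgroup
        } else NULL
        calls <- tryCatch(
          run_method(m, sub$expr, clinical = sub$clinical, models = models,
                     subgroup = subgroup, seed = s, registry = registry,
                     cohort_declared = recipe$cohort_type != "unselected"),
          error = function(e) NULL)
        if (is.null(calls)) next
        a[i] <- as.numeric(accuracy(calls$label, unname(sub$truth)))
        k[i] <- tryCatch(
          as.numeric(cohens_kappa(calls$label, unname(sub$truth))),
          error = function(e) NA_real_)
      }
      list(acc = mean(a, na.rm = TRUE), kappa = mean(k, na.rm = TRUE))
    }
    auto_score <- score_set(decision$enabled)
    excl_methods <- decision$disabled$method
    excl_score <- if (length(excl_methods)) score_set(excl_methods) else
      list(acc = NA_real_, kappa = NA_real_)
    acc$auto <- c(acc$auto, auto_score$acc)
    acc$excluded <- c(acc$excluded, excl_score$acc)
    kap$auto <- c(kap$auto, auto_score$kappa)
    kap$excluded <- c(kap$excluded, excl_score$kappa)
    delta_acc <- c(delta_acc, auto_score$acc - excl_score$acc)
  }
  summarize <- function(x) c(mean = mean(x, na.rm = TRUE),
                             sd = stats::sd(x, na.rm = TRUE))
  structure(
    list(scenario = scenario,
         recipe = recipe,
         accuracy = list(auto = summarize(acc$auto),
                         excluded = summarize(acc$excluded)),
         kappa = list(auto = summarize(kap$auto),
                      excluded = summarize(kap$excluded)),
         delta_accuracy_pp = delta_acc,
         mean_delta_accuracy_pp =
           if (all(is.na(delta_acc))) NA_real_
           else mean(delta_acc, na.rm = TRUE),
         params = list(R = R, n = n, seed = seed)),
    class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("Scenario %s (R=%d, n=%d)\n", x$scenario, x$params$R,
              x$params$n))
  cat(sprintf("  AUTO     accuracy %.2f +/- %.2f %%, kappa %.3f\n",
              x$accuracy$auto["mean"], x$accuracy$auto["sd"],
              x$kappa$auto["mean"]))
  cat(sprintf("  Excluded accuracy %.2f +/- %.2f %%, kappa %.3f\n",
              x$accuracy$excluded["mean"], x$accuracy$excluded["sd"],
              x$kappa$excluded["mean"]))
  cat(sprintf("  Delta accuracy %+0.2f pp\n", x$mean_delta_accuracy_pp))
  invisible(x)
}
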