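# AUTO mode: quantitative, cohort-composition-aware partition of the
# method registry into enabled and disabled sets, with machine-readable
# reasons and an auditable decision record.

#' Default AUTO-mode thresholds
#'
#' The ER-deviation cutoffs (ER+ <= 39% or >= 69%, derived from a
#' kappa-drop criterion against the ER-balanced reference composition) and
#' the minimum subgroup sizes gating the subgroup-specific NC methods:
#' at least 15 ER+ or 18 ER- (or TN) samples for the ER-side scheme, and at
#' least 8 ER+/HER2-, 8 ER+/HER2+, 9 ER-/HER2+ or 9 ER-/HER2- samples for
#' the ER/HER2 scheme. The reference ER+ percentage is that of the PAM50
#' training cohort (54/118).
#'
#' @return List of thresholds.
#' @export
auto_thresholds <- function() {
  list(er_low_pct = 39,
       er_high_pct = 69,
       reference_er_pct = 100 * 54 / 118,
       min_er_pos = 15L,
       min_er_neg_or_tn = 18L,
       min_ssbc2 = c("ER+/HER2-" = 8L, "ER+/HER2+" = 8L,
                     "ER-/HER2+" = 9L, "ER-/HER2-" = 9L))
}

#' Cohort composition diagnostics
#'
#' The ER+ percentage is computed over samples with known ER status
#' (unknowns are excluded from the denominator). ER/HER2 subgroup counts
#' are over samples with both statuses known; the TN count is over
#' explicit declarations.
#'
#' @param clinical A `ClinicalTable`.
#' @return A `cohort_diagnostics` list: `n_samples`, `n_er_pos`,
#'   `n_er_neg`, `n_er_unknown`, `er_pos_pct`, `subgroup_counts`, `n_tn`.
#' @export
cohort_diagnostics <- function(clinical) {
  n_pos <- sum(clinical$er == "pos")
  n_neg <- sum(clinical$er == "neg")
  n_unk <- sum(clinical$er == "unknown")
  n_tn <- sum(clinical$tn)
  if (n_pos + n_neg == 0L && n_tn == 0L) {
    stop("no sample has a known ER status and no TN declaration is present")
  }
  sg <- erher2_subgroup(clinical)
  counts <- vapply(names(auto_thresholds()$min_ssbc2),
                   function(s) sum(!is.na(sg) & sg == s), 0L)
  structure(
    list(n_samples = nrow(clinical),
         n_er_pos = n_pos, n_er_neg = n_neg, n_er_unknown = n_unk,
         er_pos_pct = if (n_pos + n_neg > 0) 100 * n_pos / (n_pos + n_neg)
                      else NA_real_,
         subgroup_counts = as.list(counts),
         n_tn = n_tn),
    class = "cohort_diagnostics")
}

.cohort_types <- c("unselected", "ER+", "ER-", "ER+/HER2-", "HER2+",
                   "ER-/HER2-", "TN")

# ssBC.v2 subgroups evaluated for each cohort type.
.ssbc2_groups <- list(
  "ER+"       = c("ER+/HER2-", "ER+/HER2+"),
  "ER-"       = c("ER-/HER2+", "ER-/HER2-"),
  "ER+/HER2-" = "ER+/HER2-",
  "HER2+"     = c("ER+/HER2+", "ER-/HER2+"),
  "ER-/HER2-" = "ER-/HER2-",
  "TN"        = "ER-/HER2-")

#' Partition the method registry by cohort composition (AUTO mode)
#'
#' Decision flow:
#' * SSP methods are always enabled, whatever the composition.
#' * `unselected` cohorts route on the ER+ percentage: strictly inside
#'   (39, 69) the cohort is ER-balanced and the conventional NC methods
#'   run; at or beyond either cutoff the ER-deviated centering methods
#'   (IHC-guided and robust rescaling) replace them.
#' * Subtype-specific cohort types enable only the subgroup-quantile NC
#'   methods, each gated by its minimum subgroup size; every other NC
#'   method is disabled as assuming a broader subtype distribution.
#' * `TN` is handled as an ER-negative-type cohort with TN quantiles and
#'   requires every sample to carry an explicit TN declaration.
#'
#' @param diagnostics Output of [cohort_diagnostics()].
#' @param cohort_type One of `"unselected"`, `"ER+"`, `"ER-"`,
#'   `"ER+/HER2-"`, `"HER2+"`, `"ER-/HER2-"`, `"TN"`.
#' @param registry Method registry (default [default_registry()]).
#' @param thresholds AUTO thresholds (default [auto_thresholds()]).
#' @return An `AutoDecision`: diagnostics, branch, thresholds, `enabled`
#'   (character vector), `disabled` (data frame of method/reason),
#'   `ssbc_subgroup` and `ssbc2_subgroups` detail.
#' @export
select_methods <- function(diagnostics, cohort_type = "unselected",
                           registry = default_registry(),
                           thresholds = auto_thresholds()) {
  cohort_type <- gsub("−", "-", cohort_type)
  if (!cohort_type %in% .cohort_types) {
    stop("unknown cohort_type: ", cohort_type,
         " (expected one of ", paste(.cohort_types, collapse = ", "), ")")
  }
  if (cohort_type == "TN" && diagnostics$n_tn < diagnostics$n_samples) {
    stop("the TN branch requires every sample to have an explicit ",
         "IHC-defined TN declaration (ER-/PR-/HER2-)")
  }

  enabled <- character(0)
  disabled <- list()
  add_disabled <- function(name, reason) {
    disabled[[name]] <<- reason
  }
  tags <- vapply(registry, function(d) d$branch_tag, "")
  conventional <- names(registry)[tags == "conventional"]
  deviated <- names(registry)[tags == "deviated"]
  subtype_m <- names(registry)[tags == "subtype"]
  ssp <- names(registry)[vapply(registry, function(d) d$family, "") == "SSP"]
  enabled <- ssp  # SSP methods are always eligible

  ssbc_subgroup <- NA_character_
  ssbc2_pass <- character(0)

  if (cohort_type == "unselected") {
    pct <- diagnostics$er_pos_pct
    if (is.na(pct)) stop("unselected cohort needs known ER statuses")
    if (pct <= thresholds$er_low_pct || pct >= thresholds$er_high_pct) {
      branch <- "deviated"
      enabled <- c(enabled, deviated)
      for (m in conventional) add_disabled(m, "er_balance_assumption_violated")
    } else {
      branch <- "balanced"
      enabled <- c(enabled, conventional)
      for (m in deviated) add_disabled(m, "requires_er_deviated_cohort")
    }
    for (m in subtype_m) add_disabled(m, "requires_subtype_specific_cohort")
  } else {
    branch <- if (cohort_type == "TN") "tn" else "subtype_specific"
    for (m in c(conventional, deviated)) {
      add_disabled(m, "assumes_broader_subtype_distribution")
    }
    # ssBC (ER-side scheme): gate on the matching ER-side count.
    if ("ssBC" %in% subtype_m) {
      gate <- switch(cohort_type,
        "ER+" = , "ER+/HER2-" = list(sub = if (cohort_type == "ER+") "ER+"
                                           else "ER+",
                                     n = diagnostics$n_er_pos,
                                     min = thresholds$min_er_pos),
        "ER-" = , "ER-/HER2-" = list(sub = "ER-",
                                     n = diagnostics$n_er_neg,
                                     min = thresholds$min_er_neg_or_tn),
        "TN" = list(sub = "TN", n = diagnostics$n_tn,
                    min = thresholds$min_er_neg_or_tn),
        "HER2+" = NULL)
      if (is.null(gate)) {
        add_disabled("ssBC", "no_matching_subgroup")
      } else if (gate$n >= gate$min) {
        enabled <- c(enabled, "ssBC")
        ssbc_subgroup <- gate$sub
      } else {
        add_disabled("ssBC", "subgroup_below_minimum")
      }
    }
    # ssBC.v2 (ER/HER2 scheme): each relevant subgroup against its own
    # gate, independent of the ER-side gate above.
    if ("ssBC.v2" %in% subtype_m) {
      groups <- .ssbc2_groups[[cohort_type]]
      pass <- groups[vapply(groups, function(s) {
        diagnostics$subgroup_counts[[s]] >= thresholds$min_ssbc2[[s]]
      }, TRUE)]
      if (length(pass)) {
        enabled <- c(enabled, "ssBC.v2")
        ssbc2_pass <- pass
      } else {
        add_disabled("ssBC.v2", "subgroup_below_minimum")
      }
    }
  }

  decision <- structure(
    list(diagnostics = diagnostics,
         cohort_type = cohort_type,
         branch = branch,
         thresholds = thresholds,
         enabled = enabled,
         disabled = data.frame(method = names(disabled),
                               reason = unlist(disabled, use.names = FALSE),
                               stringsAsFactors = FALSE),
         ssbc_subgroup = ssbc_subgroup,
         ssbc2_subgroups = ssbc2_pass),
    class = "AutoDecision")
  stopifnot(setequal(c(decision$enabled, decision$disabled$method),
                     names(registry)),
            !anyDuplicated(c(decision$enabled, decision$disabled$method)))
  bs_log("info", "AUTO branch=%s enabled=[%s]", branch,
         paste(enabled, collapse = ", "))
  decision
}

#' @export
print.AutoDecision <- function(x, ...) {
  cat(sprintf("AutoDecision: cohort_type=%s branch=%s (ER+ %.1f%%)\n",
              x$cohort_type, x$branch, x$diagnostics$er_pos_pct))
  cat("  enabled: ", paste(x$enabled, collapse = ", "), "\n")
  if (nrow(x$disabled)) {
    for (i in seq_len(nrow(x$disabled))) {
      cat(sprintf("  disabled: %s (%s)\n", x$disabled$method[i],
                  x$disabled$reason[i]))
    }
  }
  invisible(x)
}

#' Write an AUTO decision to a JSON audit file
#'
#' @param decision An `AutoDecision`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_auto_decision <- function(decision, path) {
  payload <- list(
    cohort_type = decision$cohort_type,
    branch = decision$branch,
    diagnostics = unclass(decision$diagnostics),
    thresholds = lapply(decision$thresholds, function(x) {
      if (is.null(names(x))) unname(x) else as.list(x)
    }),
    enabled = decision$enabled,
    disabled = decision$disabled,
    ssbc_subgroup = decision$ssbc_subgroup,
    ssbc2_subgroups = decision$ssbc2_subgroups)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Re-read an AUTO decision from its JSON audit file
#'
#' The parsed record carries enough information (diagnostics, cohort type,
#' thresholds) to replay [select_methods()] and recover the identical
#' enabled/disabled partition.
#'
#' @param path Path to a JSON file written by [write_auto_decision()].
#' @return An `AutoDecision`.
#' @export
read_auto_decision <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  thr <- p$thresholds
  thr$min_ssbc2 <- unlist(thr$min_ssbc2)
  diag <- p$diagnostics
  diag$subgroup_counts <- as.list(unlist(diag$subgroup_counts))
  structure(
    list(diagnostics = structure(diag, class = "cohort_diagnostics"),
         cohort_type = p$cohort_type,
         branch = p$branch,
         thresholds = thr,
         enabled = as.character(p$enabled),
         disabled = if (length(p$disabled)) {
           as.data.frame(p$disabled, stringsAsFactors = FALSE)
         } else {
           data.frame(method = character(0), reason = character(0))
         },
         ssbc_subgroup = p$ssbc_subgroup,
         ssbc2_subgroups = as.character(p$ssbc2_subgroups)),
    class = "AutoDecision")
}
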