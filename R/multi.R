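# Multi-method execution: run every enabled method through its own
# normalization route and collect the calls into a samples x methods
# matrix. A single method's failure degrades to an NA column, never an
# aborted run.

# Execute one registry method end to end on a raw input matrix.
# `cohort_declared` marks a subtype-specific cohort context: the
# subgroup-quantile methods are only runnable inside one (matching the
# original tools, which require an explicit subgroup declaration).
run_method <- function(name, expr, clinical = NULL, models = list(),
                       lengths = NULL, subgroup = NULL, seed = 1L,
                       registry = default_registry(), offset = 1,
                       cohort_declared = FALSE) {
  desc <- registry[[name]]
  if (is.null(desc)) stop("unknown method: ", name)
  if (!is.null(desc$centering) && desc$centering == "ssbc_quantile" &&
      is.null(subgroup) && !isTRUE(cohort_declared)) {
    stop("method ", name, " requires a declared cohort subgroup ",
         "(subtype-specific cohort type or explicit subgroup)")
  }
  if (desc$family == "SSP") {
    if (is.null(models$ruleset)) stop("method ", name, " needs a rule set")
    prep <- prepare_matrix(expr, lengths, family = "SSP")
    calls <- classify_ssp(prep, models$ruleset)
  } else {
    if (is.null(models$centroid)) {
      stop("method ", name, " needs a centroid model")
    }
    prep <- prepare_matrix(expr, lengths, family = "NC", offset = offset)
    model <- models$centroid
    if (!is.null(desc$correlation)) model$correlation_kind <- desc$correlation
    spec <- centering_spec(desc$centering,
                           quantiles = models$quantiles,
                           subgroup = subgroup,
                           version = if (name == "ssBC.v2") 2L else 1L)
    centered <- apply_centering(prep, spec, clinical = clinical,
                                model = model, seed = seed)
    calls <- classify_nc(centered, model)
  }
  calls$method <- name
  attr(calls, "prep") <- list(scale = prep$scale, units = prep$units)
  calls
}

#' Run multiple subtyping methods on one input matrix
#'
#' Each method is routed through the normalization its family requires
#' (see [prepare_matrix()]), centered per its descriptor, and classified.
#' A method that errors contributes an all-NA column with a logged
#' warning; the run itself completes.
#'
#' @param expr Raw `ExpressionMatrix` (any supported platform).
#' @param clinical `ClinicalTable` (required by IHC-guided and subgroup
#'   methods).
#' @param methods An `AutoDecision` (its enabled set is run, and subgroup
#'   context is taken from it) or an explicit character vector of registry
#'   method names.
#' @param models Named list of model objects: `centroid`, `quantiles`,
#'   `ruleset`.
#' @param lengths `GeneLengths` for the raw-counts SSP route.
#' @param seed Seed for the stochastic centering strategies.
#' @param registry Method registry.
#' @return A `CallMatrix`: samples x methods character matrix of labels,
#'   with per-method calls in the `"calls"` attribute and each method's
#'   normalization route in the `"prep"` attribute.
#' @export
run_multi <- function(expr, clinical = NULL, methods, models = list(),
                      lengths = NULL, seed = 1L,
                      registry = default_registry()) {
  decision <- NULL
  declared <- FALSE
  if (inherits(methods, "AutoDecision")) {
    decision <- methods
    declared <- decision$branch %in% c("subtype_specific", "tn")
    methods <- decision$enabled
  }
  if (length(methods) == 0L) stop("no methods enabled")
  samples <- colnames(expr$values)
  out <- matrix(NA_character_, length(samples), length(methods),
                dimnames = list(samples, methods))
  all_calls <- list()
  prep_info <- list()
  for (m in methods) {
    subgroup <- NULL
    if (!is.null(decision) && m == "ssBC" &&
        !is.na(decision$ssbc_subgroup)) {
      subgroup <- decision$ssbc_subgroup
    }
    res <- tryCatch(
      run_method(m, expr, clinical = clinical, models = models,
                 lengths = lengths, subgroup = subgroup, seed = seed,
                 registry = registry, cohort_declared = declared),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("method ", m, " failed: ", conditionMessage(res),
              call. = FALSE)
      bs_log("warn", "method %s failed: %s", m, conditionMessage(res))
      next
    }
    out[res$sample_id, m] <- res$label
    all_calls[[m]] <- res
    prep_info[[m]] <- attr(res, "prep")
  }
  structure(out, class = c("CallMatrix", class(out)),
            calls = all_calls, prep = prep_info)
}

#' Write a call matrix to TSV
#'
#' @param x A `CallMatrix` (samples x methods labels).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_call_matrix <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
  invisible(path)
}

#' Read a call matrix from TSV
#'
#' @param path Path to a TSV with a `sample_id` column and one label
#'   column per method.
#' @return A `CallMatrix`.
#' @export
read_call_matrix <- function(path) {
  df <- read_tsv_strict(path)
  m <- as.matrix(df[, setdiff(colnames(df), "sample_id"), drop = FALSE])
  rownames(m) <- df$sample_id
  structure(m, class = c("CallMatrix", class(m)))
}
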