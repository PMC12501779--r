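# The method registry: descriptors for the ten supported subtyping
# methods. The catalogue lives in a versioned TSV (inst/extdata/registry.tsv)
# so branch assignments can be corrected without a code change.

#' Construct a method descriptor
#'
#' @param name Method name.
#' @param family `"NC"` (nearest-centroid) or `"SSP"` (single-sample
#'   predictor).
#' @param centering Centering strategy for NC methods (see
#'   [centering_spec()]); must be `NULL` for SSP methods.
#' @param correlation Correlation kind used by the NC engine for this
#'   method (`"spearman"` or `"pearson"`); `NULL` for SSP.
#' @param branch_tag Cohort-composition assumption tag: `"conventional"`
#'   (ER-balanced cohorts), `"deviated"` (ER-deviated cohorts),
#'   `"subtype"` (subtype-specific cohorts) or `"ssp"` (always eligible).
#' @return A `MethodDescriptor`.
#' @export
method_descriptor <- function(name, family = c("NC", "SSP"),
                              centering = NULL, correlation = NULL,
                              branch_tag = "conventional") {
  family <- match.arg(family)
  if (family == "SSP" && !is.null(centering)) {
    stop("SSP methods carry no centering strategy")
  }
  if (family == "NC" && is.null(centering)) {
    stop("NC methods need a centering strategy")
  }
  structure(list(name = name, family = family, centering = centering,
                 correlation = correlation, branch_tag = branch_tag),
            class = "MethodDescriptor")
}

#' The default ten-method registry
#'
#' Reads the versioned registry file shipped with the package: eight
#' nearest-centroid variants distinguished by centering strategy and
#' correlation kind, plus two single-sample predictors.
#'
#' @return Named list of `MethodDescriptor` objects.
#' @export
default_registry <- function() {
  path <- system.file("extdata", "registry.tsv", package = "brcaIS",
                      mustWork = TRUE)
  df <- read_tsv_strict(path)
  out <- lapply(seq_len(nrow(df)), function(i) {
    ssp <- df$family[i] == "SSP"
    method_descriptor(
      name = df$name[i],
      family = df$family[i],
      centering = if (ssp) NULL else df$centering[i],
      correlation = if (ssp) NULL else df$correlation[i],
      branch_tag = df$branch_tag[i])
  })
  stats::setNames(out, df$name)
}
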