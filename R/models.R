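# Classifier model containers and their TSV dialects:
#   centroid : gene_id + one column per subtype; "# key: value" header lines
#              may carry correlation_kind and min_gene_fraction.
#   quantile : gene_id, subgroup, quantile_prob.
#   ruleset  : gene_a, gene_b + one probability column per subtype;
#              optional "# prior: LumA=..,LumB=.." and "# epsilon: .." lines.

#' Construct a nearest-centroid model
#'
#' @param centroids Numeric matrix, genes in rows (rownames = gene IDs),
#'   subtypes in columns. Column names must normalize to the five canonical
#'   labels (see [subtype_labels()]); column order defines the tie-break
#'   order.
#' @param correlation_kind `"spearman"` (default) or `"pearson"`.
#' @param min_gene_fraction Minimum fraction of model genes that must be
#'   present in the input (default 0.8).
#' @return A `CentroidModel`.
#' @export
centroid_model <- function(centroids, correlation_kind = "spearman",
                           min_gene_fraction = 0.8) {
  if (!is.matrix(centroids)) centroids <- as.matrix(centroids)
  storage.mode(centroids) <- "double"
  if (is.null(rownames(centroids))) stop("centroids need gene rownames")
  if (anyDuplicated(rownames(centroids))) {
    stop("duplicate genes in centroid model")
  }
  colnames(centroids) <- normalize_subtype(colnames(centroids))
  if (anyDuplicated(colnames(centroids))) {
    stop("duplicate subtype columns in centroid model")
  }
  assert_finite(centroids, "centroid values")
  if (!correlation_kind %in% c("spearman", "pearson")) {
    stop("correlation_kind must be spearman or pearson")
  }
  if (min_gene_fraction <= 0 || min_gene_fraction > 1) {
    stop("min_gene_fraction must be in (0, 1]")
  }
  structure(list(centroids = centroids,
                 subtypes = colnames(centroids),
                 correlation_kind = correlation_kind,
                 min_gene_fraction = min_gene_fraction),
            class = "CentroidModel")
}

#' Construct a subgroup quantile table
#'
#' Gene-specific quantile probabilities used for subgroup-specific
#' centering: in a clinically selected subgroup cohort, subtracting the
#' cohort quantile at `quantile_prob[gene, subgroup]` stands in for the
#' reference-population median of that gene.
#'
#' @param gene_id,subgroup,quantile_prob Parallel vectors; subgroups from
#'   the canonical set `ER+`, `ER-`, `TN`, `ER+/HER2-`, `ER+/HER2+`,
#'   `ER-/HER2+`, `ER-/HER2-`; probabilities strictly in (0, 1).
#' @return A `QuantileTable` data frame.
#' @export
quantile_table <- function(gene_id, subgroup, quantile_prob) {
  gene_id <- as.character(gene_id)
  subgroup <- normalize_subgroup(subgroup)
  quantile_prob <- as.numeric(quantile_prob)
  if (any(!is.finite(quantile_prob)) ||
      any(quantile_prob <= 0 | quantile_prob >= 1)) {
    stop("quantile_prob must lie strictly between 0 and 1")
  }
  key <- paste(gene_id, subgroup)
  if (anyDuplicated(key)) {
    stop("duplicate (gene, subgroup) pairs: ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "))
  }
  structure(data.frame(gene_id = gene_id, subgroup = subgroup,
                       quantile_prob = quantile_prob,
                       stringsAsFactors = FALSE),
            class = c("QuantileTable", "data.frame"))
}

#' Construct a gene-pair rule set for the single-sample predictor engine
#'
#' Each rule is a gene pair (a, b); a rule fires for a sample when the
#' linear expression of `gene_a` is strictly below that of `gene_b`.
#' Class-conditional firing probabilities are clipped into
#' `[epsilon, 1 - epsilon]` (values outside `[0, 1]` are rejected).
#'
#' @param gene_a,gene_b Character vectors defining the rules; `gene_a` must
#'   differ from `gene_b` within each rule.
#' @param probs Numeric matrix, rules x subtypes, of P(rule fires | subtype).
#' @param priors Per-subtype prior probabilities; default uniform.
#' @param epsilon Probability floor (default 1e-6).
#' @return A `RuleSet`.
#' @export
rule_set <- function(gene_a, gene_b, probs, priors = NULL, epsilon = 1e-6) {
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  if (any(gene_a == gene_b)) stop("gene_a must differ from gene_b")
  if (!is.matrix(probs)) probs <- as.matrix(probs)
  storage.mode(probs) <- "double"
  if (nrow(probs) != length(gene_a)) stop("probs rows must match rules")
  colnames(probs) <- normalize_subtype(colnames(probs))
  assert_finite(probs, "rule probabilities")
  if (any(probs < 0 | probs > 1)) {
    stop("rule probability outside [0, 1]")
  }
  if (any(probs < epsilon | probs > 1 - epsilon)) {
    warning("rule probabilities clipped to [epsilon, 1 - epsilon]")
    probs <- pmin(pmax(probs, epsilon), 1 - epsilon)
  }
  if (is.null(priors)) {
    priors <- stats::setNames(rep(1 / ncol(probs), ncol(probs)),
                              colnames(probs))
  } else {
    names(priors) <- normalize_subtype(names(priors))
    priors <- priors[colnames(probs)]
    if (any(!is.finite(priors)) || any(priors <= 0)) {
      stop("priors must be positive for every subtype")
    }
    priors <- priors / sum(priors)
  }
  structure(list(gene_a = gene_a, gene_b = gene_b, probs = probs,
                 priors = priors, epsilon = epsilon),
            class = "RuleSet")
}

#' Read a classifier model file
#'
#' @param path Path to a TSV file in the dialect for `kind`.
#' @param kind `"centroid"`, `"quantile"` or `"ruleset"`.
#' @return A `CentroidModel`, `QuantileTable` or `RuleSet`.
#' @export
read_model <- function(path, kind = c("centroid", "quantile", "ruleset")) {
  kind <- match.arg(kind)
  meta <- read_header_meta(path)
  df <- read_tsv_strict(path)
  switch(kind,
    centroid = {
      m <- as.matrix(df[, -1, drop = FALSE])
      rownames(m) <- as.character(df[[1]])
      centroid_model(
        m,
        correlation_kind = meta$correlation_kind %||% "spearman",
        min_gene_fraction = as.numeric(meta$min_gene_fraction %||% "0.8"))
    },
    quantile = {
      if (!all(c("gene_id", "subgroup", "quantile_prob") %in% colnames(df))) {
        stop("quantile TSV needs columns gene_id, subgroup, quantile_prob")
      }
      quantile_table(df$gene_id, df$subgroup, df$quantile_prob)
    },
    ruleset = {
      if (!all(c("gene_a", "gene_b") %in% colnames(df))) {
        stop("ruleset TSV needs columns gene_a, gene_b")
      }
      prob_cols <- setdiff(colnames(df), c("gene_a", "gene_b"))
      priors <- NULL
      if (!is.null(meta$prior)) {
        kv <- strsplit(strsplit(meta$prior, ",")[[1]], "=")
        priors <- stats::setNames(
          vapply(kv, function(p) as.numeric(p[2]), 0),
          vapply(kv, function(p) trimws(p[1]), ""))
      }
      rule_set(df$gene_a, df$gene_b,
               as.matrix(df[, prob_cols, drop = FALSE]),
               priors = priors,
               epsilon = as.numeric(meta$epsilon %||% "1e-6"))
    })
}

#' Write a classifier model file
#'
#' @param model A `CentroidModel`, `QuantileTable` or `RuleSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "CentroidModel")) {
    con <- file(path, "w", encoding = "UTF-8")
    writeLines(c(sprintf("# correlation_kind: %s", model$correlation_kind),
                 sprintf("# min_gene_fraction: %.17g", model$min_gene_fraction)),
               con)
    df <- data.frame(gene_id = rownames(model$centroids), model$centroids,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  } else if (inherits(model, "QuantileTable")) {
    write_tsv_strict(as.data.frame(model), path)
  } else if (inherits(model, "RuleSet")) {
    con <- file(path, "w", encoding = "UTF-8")
    writeLines(c(sprintf("# epsilon: %.17g", model$epsilon),
                 sprintf("# prior: %s",
                         paste(sprintf("%s=%.17g", names(model$priors),
                                       model$priors), collapse = ","))),
               con)
    df <- data.frame(gene_a = model$gene_a, gene_b = model$gene_b,
                     model$probs, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  } else {
    stop("unsupported model class")
  }
  invisible(path)
}
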