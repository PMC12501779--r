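# Single-sample predictor engine: within-sample gene-pair order rules
# scored by a naive-Bayes model. Each sample is classified independently of
# every other sample, which makes SSP calls immune to cohort composition.

#' Evaluate gene-pair rules on one sample
#'
#' A rule (a, b) fires (outcome 1) when the sample's linear expression of
#' gene a is strictly below that of gene b; exact equality counts as not
#' fired (outcome 0). Rules referencing genes absent from the sample are
#' skipped and counted.
#'
#' @param sample Named numeric vector of linear-scale expression values.
#' @param rules A `RuleSet`.
#' @return List with `outcome` (integer vector, NA for skipped rules) and
#'   `skipped` (count of skipped rules).
#' @export
evaluate_rules <- function(sample, rules) {
  a <- sample[rules$gene_a]
  b <- sample[rules$gene_b]
  outcome <- as.integer(a < b)
  skipped <- is.na(a) | is.na(b)
  outcome[skipped] <- NA_integer_
  list(outcome = outcome, skipped = sum(skipped))
}

#' Classify samples with the single-sample predictor engine
#'
#' Per sample, the log-posterior for subtype k is
#' `log prior_k + sum over evaluated rules of
#' [outcome * log P_rk + (1 - outcome) * log(1 - P_rk)]`;
#' skipped rules are excluded from the likelihood. Scores are
#' softmax-normalized posteriors summing to 1; the label is the argmax with
#' ties broken by the rule set's subtype column order. A sample whose rules
#' are all skipped gets an NA label and flag.
#'
#' @param expr Linear-scale `ExpressionMatrix` (run [prepare_matrix()] with
#'   `family = "SSP"` first).
#' @param rules A `RuleSet`.
#' @return A `SubtypeCalls` data frame.
#' @export
classify_ssp <- function(expr, rules) {
  if (expr$scale != "linear") stop("SSP engine expects linear-scale input")
  if (length(rules$gene_a) == 0L) stop("empty rule set")
  v <- expr$values
  subtypes <- colnames(rules$probs)
  logp <- log(rules$probs)
  log1mp <- log1p(-rules$probs)
  logprior <- log(rules$priors)

  n <- ncol(v)
  scores <- matrix(NA_real_, n, length(subtypes),
                   dimnames = list(colnames(v), subtypes))
  label <- rep(NA_character_, n)
  tie <- logical(n)
  skipped <- integer(n)
  for (j in seq_len(n)) {
    ev <- evaluate_rules(v[, j], rules)
    skipped[j] <- ev$skipped
    use <- !is.na(ev$outcome)
    if (!any(use)) next  # all rules skipped: NA call, flagged via skipped
    o <- ev$outcome[use]
    ll <- logprior +
      colSums(o * logp[use, , drop = FALSE] +
                (1 - o) * log1mp[use, , drop = FALSE])
    post <- exp(ll - max(ll))
    post <- post / sum(post)
    scores[j, ] <- post
    best <- which(post == max(post))
    label[j] <- subtypes[best[1]]
    tie[j] <- length(best) > 1L
  }
  make_calls(colnames(v), label, scores, method = "ssp",
             tie = tie, skipped_rules = skipped)
}
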