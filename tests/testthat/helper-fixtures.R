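# Shared fixtures, built in code. The toy world is cached per test run.

toy_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- sim_spec(seed = 42L)
      cache <<- list(spec = spec, models = make_toy_models(spec))
    }
    cache
  }
})

# Clinical table with given ER/HER2 composition (PR negative throughout
# unless TN is involved, where all three markers are negative).
make_clinical <- function(n_er_pos = 0, n_er_neg = 0, n_er_unknown = 0,
                          her2_pos = "neg", her2_neg = "neg", tn = FALSE) {
  n <- n_er_pos + n_er_neg + n_er_unknown
  er <- c(rep("pos", n_er_pos), rep("neg", n_er_neg),
          rep("unknown", n_er_unknown))
  her2 <- c(rep(her2_pos, n_er_pos), rep(her2_neg, n_er_neg),
            rep("unknown", n_er_unknown))
  pr <- ifelse(er == "pos", "pos", "neg")
  if (isTRUE(tn)) {
    pr <- rep("neg", n)
    her2 <- rep("neg", n)
    er <- rep("neg", n)
  }
  clinical_table(sprintf("c%03d", seq_len(n)), er, pr, her2,
                 tn = rep(isTRUE(tn), n))
}

rand_labels <- function(n, k = 5, seed = NULL) {
  draw <- function() sample(subtype_labels()[seq_len(k)], n, replace = TRUE)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

rand_expression <- function(n_genes, n_samples, platform = "microarray",
                            seed = 1L) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n_samples))))
    expression_matrix(v, platform = platform)
  })
}

rand_counts <- function(n_genes, n_samples, lambda = 50, seed = 1L) {
  withr::with_seed(seed, {
    v <- matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("s%03d", seq_len(n_samples))))
    expression_matrix(v, platform = "rnaseq_counts")
  })
}

# --- independent oracles (deliberately naive, loop-based) ---------------

# Type-7 quantile by hand.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo == n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

oracle_pearson <- function(a, b) {
  ma <- sum(a) / length(a)
  mb <- sum(b) / length(b)
  num <- 0; da <- 0; db <- 0
  for (i in seq_along(a)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    da <- da + (a[i] - ma)^2
    db <- db + (b[i] - mb)^2
  }
  num / sqrt(da * db)
}

oracle_spearman <- function(a, b) oracle_pearson(rank(a), rank(b))

# Step-by-step upper-quartile log2-CPM.
oracle_uqcpm <- function(counts, offset = 1) {
  n <- ncol(counts)
  q <- numeric(n); L <- numeric(n)
  for (j in seq_len(n)) {
    x <- counts[, j]
    q[j] <- oracle_quantile(x[x > 0], 0.75)
    L[j] <- sum(x)
  }
  r <- q / L
  g <- exp(mean(log(r)))
  out <- counts * 0
  for (j in seq_len(n)) {
    E <- L[j] * (r[j] / g)
    for (i in seq_len(nrow(counts))) {
      out[i, j] <- log2(counts[i, j] * 1e6 / E + offset)
    }
  }
  out
}

# Naive-Bayes log-posterior summed term by term.
oracle_ssp_posterior <- function(x, rules) {
  subtypes <- colnames(rules$probs)
  ll <- log(rules$priors)
  for (r in seq_along(rules$gene_a)) {
    a <- x[rules$gene_a[r]]
    b <- x[rules$gene_b[r]]
    if (is.na(a) || is.na(b)) next
    o <- as.integer(a < b)
    for (k in seq_along(subtypes)) {
      p <- rules$probs[r, k]
      ll[k] <- ll[k] + o * log(p) + (1 - o) * log(1 - p)
    }
  }
  post <- exp(ll - max(ll))
  post / sum(post)
}

# Cohen's kappa from an explicit contingency table.
oracle_kappa <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  labs <- sort(unique(c(a, b)))
  tab <- matrix(0, length(labs), length(labs),
                dimnames = list(labs, labs))
  for (i in seq_along(a)) tab[a[i], b[i]] <- tab[a[i], b[i]] + 1
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}
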