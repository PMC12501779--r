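# Readers, writers, validation and round-trips for every on-disk format.

test_that("read_expression parses counts and propagates platform tags", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2",
               "101\t5\t0",
               "102\t3\t7",
               "103\t0\t2"), path)
  em <- read_expression(path, platform = "rnaseq_counts")
  expect_identical(dim(em), c(3L, 2L))
  expect_identical(em$scale, "linear")
  expect_identical(em$units, "counts")
  expect_equal(em$values["102", "s2"], 7)

  fp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "101\t1.5", "102\t-0.25"), fp)
  em2 <- read_expression(fp, platform = "rnaseq_log2fpkm")
  expect_identical(em2$scale, "log2")
  expect_identical(em2$units, "fpkm")
})

test_that("read_expression validation errors name the offending cell", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "101\t5\tNA", "102\t3\t7"), path)
  expect_error(read_expression(path, "rnaseq_counts"), "101.*s2")

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "101\t-3"), neg)
  expect_error(read_expression(neg, "rnaseq_counts"), "negative count")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts1", "101\t1\t2"), dup)
  expect_error(read_expression(dup, "rnaseq_counts"), "duplicate sample")

  dupg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1", "101\t1", "101\t2"), dupg)
  expect_error(read_expression(dupg, "rnaseq_counts"), "duplicate gene")
})

test_that("clinical synonyms normalize and TN consistency is enforced", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ter\tpr\ther2\ttn",
               "s1\tpositive\tnegative\tNegative\tfalse",
               "s2\t0\t0\t0\ttrue",
               "s4\t+\t1\todd\t0"), path)
  ct <- read_clinical(path)
  expect_identical(ct$er, c("pos", "neg", "pos"))
  expect_identical(ct$pr, c("neg", "neg", "pos"))
  expect_identical(ct$her2[3], "unknown")
  expect_identical(ct$tn, c(FALSE, TRUE, FALSE))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ter\tpr\ther2\ttn",
               "s3\t1\t0\t0\ttrue"), bad)
  expect_error(read_clinical(bad), "TN")

  extra <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ter\tpr\ther2\tgrade",
               "s1\t1\t0\t0\tIII"), extra)
  expect_warning(read_clinical(extra), "grade")
})

test_that("model loading validates and normalizes", {
  # long subtype names normalized; unknown rejected
  m <- matrix(rnorm(50), 10, 5,
              dimnames = list(sprintf("g%d", 1:10),
                              c("Luminal A", "Luminal B", "HER2-enriched",
                                "Basal-like", "Normal-like")))
  cm <- centroid_model(m)
  expect_identical(cm$subtypes, subtype_labels())
  colnames(m)[1] <- "Claudin-low"
  expect_error(centroid_model(m), "unknown subtype")

  expect_error(quantile_table("g1", "ER+", 1.5), "strictly between")
  expect_error(quantile_table(c("g1", "g1"), c("ER+", "ER+"), c(0.4, 0.5)),
               "duplicate")
  # unicode minus accepted
  qt <- quantile_table("g1", "ER−", 0.4)
  expect_identical(qt$subgroup, "ER-")

  # boundary probabilities clip with a warning; out-of-range rejected
  p <- matrix(c(1.0, rep(0.5, 9)), 2, 5,
              dimnames = list(NULL, subtype_labels()))
  expect_warning(rs <- rule_set(c("a", "b"), c("b", "c"), p), "clipped")
  expect_equal(max(rs$probs), 1 - 1e-6)
  p[1, 1] <- 1.2
  expect_error(rule_set(c("a", "b"), c("b", "c"), p), "outside")
  expect_error(rule_set("a", "a", p[1, , drop = FALSE]), "differ")
})

test_that("every model type round-trips through disk field-for-field", {
  w <- toy_world()
  models <- w$models
  dir <- withr::local_tempdir()

  cp <- file.path(dir, "centroids.tsv")
  write_model(models$centroid, cp)
  cm <- read_model(cp, "centroid")
  expect_identical(cm$subtypes, models$centroid$subtypes)
  expect_identical(cm$correlation_kind, models$centroid$correlation_kind)
  expect_equal(cm$centroids, models$centroid$centroids, tolerance = 1e-12)

  qp <- file.path(dir, "quantiles.tsv")
  write_model(models$quantiles, qp)
  qt <- read_model(qp, "quantile")
  expect_identical(qt$gene_id, models$quantiles$gene_id)
  expect_identical(qt$subgroup, models$quantiles$subgroup)
  expect_equal(qt$quantile_prob, models$quantiles$quantile_prob,
               tolerance = 1e-12)

  rp <- file.path(dir, "rules.tsv")
  write_model(models$ruleset, rp)
  rs <- read_model(rp, "ruleset")
  expect_identical(rs$gene_a, models$ruleset$gene_a)
  expect_identical(rs$gene_b, models$ruleset$gene_b)
  expect_equal(rs$probs, models$ruleset$probs, tolerance = 1e-12)
  expect_equal(rs$priors, models$ruleset$priors, tolerance = 1e-12)
  expect_equal(rs$epsilon, models$ruleset$epsilon)

  ep <- file.path(dir, "expr.tsv")
  co <- simulate_cohort(w$spec, models, n = 8, seed = 3)
  write_expression(co$expr, ep)
  em <- read_expression(ep, platform = "microarray")
  expect_equal(em$values, co$expr$values, tolerance = 1e-12)

  clp <- file.path(dir, "clinical.tsv")
  write_clinical(co$clinical, clp)
  cl <- read_clinical(clp)
  expect_identical(as.data.frame(cl), as.data.frame(co$clinical))

  # calls round trip
  calls <- classify_nc(apply_centering(co$expr, centering_spec("median")),
                       models$centroid)
  kp <- file.path(dir, "calls.tsv")
  write_calls(calls, kp)
  k2 <- read_calls(kp)
  expect_identical(k2$label, calls$label)
  expect_equal(as.matrix(k2[, subtype_labels()]),
               as.matrix(calls[, subtype_labels()]), tolerance = 1e-12)
})

test_that("AutoDecision audit log replays to the identical partition", {
  clin <- make_clinical(n_er_pos = 20, n_er_neg = 80)
  d <- select_methods(cohort_diagnostics(clin), "unselected")
  path <- withr::local_tempfile(fileext = ".json")
  write_auto_decision(d, path)
  d2 <- read_auto_decision(path)
  expect_identical(d2$branch, d$branch)
  expect_identical(d2$enabled, d$enabled)
  expect_identical(d2$disabled$method, d$disabled$method)
  expect_identical(d2$disabled$reason, d$disabled$reason)
  # replay the selection from the re-parsed diagnostics + thresholds
  replay <- select_methods(d2$diagnostics, d2$cohort_type,
                           thresholds = d2$thresholds)
  expect_setequal(replay$enabled, d$enabled)
  expect_setequal(replay$disabled$method, d$disabled$method)
  expect_identical(replay$branch, d$branch)
})
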