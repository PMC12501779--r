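# Gene mapping and the normalization routes.

test_that("map_to_entrez relabels 1:1 mappings and drops unannotated probes", {
  em <- rand_expression(3, 4, seed = 1)
  ann <- data.frame(probe_id = c("g001", "g002", "g003"),
                    entrez_id = c("11", "22", "33"))
  res <- map_to_entrez(em, ann)
  expect_identical(rownames(res$expr$values), c("11", "22", "33"))
  expect_identical(res$report$dropped_unmapped, character(0))
  expect_identical(nrow(res$report$duplicates_collapsed), 0L)

  ann2 <- ann[1:2, ]
  res2 <- map_to_entrez(em, ann2)
  expect_identical(res2$report$dropped_unmapped, "g003")
  expect_identical(res2$report$n_mapped_genes, 2L)

  none <- data.frame(probe_id = "x", entrez_id = "9")
  expect_error(map_to_entrez(em, none), "no input probe")
})

test_that("duplicate probes collapse to the max-IQR probe", {
  # 4-sample fixture; IQRs computed by brute force below
  v <- rbind(p1 = c(0, 2, 4, 6),    # spread out
             p2 = c(3, 3.2, 3.4, 3.6),  # tight
             p3 = c(1, 1, 1, 1))
  colnames(v) <- sprintf("s%d", 1:4)
  em <- expression_matrix(v, platform = "microarray")
  ann <- data.frame(probe_id = c("p1", "p2", "p3"),
                    entrez_id = c("77", "77", "88"))
  iqr1 <- oracle_quantile(v[1, ], 0.75) - oracle_quantile(v[1, ], 0.25)
  iqr2 <- oracle_quantile(v[2, ], 0.75) - oracle_quantile(v[2, ], 0.25)
  expect_gt(iqr1, iqr2)
  res <- map_to_entrez(em, ann, required_genes = c("77", "88", "99"))
  expect_identical(res$report$duplicates_collapsed$kept, "p1")
  expect_identical(res$report$duplicates_collapsed$discarded, "p2")
  expect_identical(res$report$missing_model_genes, "99")
  expect_equal(res$expr$values["77", ], v["p1", ])
})

test_that("mapping report conserves probe counts on random annotations", {
  for (s in 1:20) {
    em <- rand_expression(30, 5, seed = s)
    withr::with_seed(s, {
      ann <- data.frame(
        probe_id = sample(rownames(em$values), 25),
        entrez_id = as.character(sample(1:12, 25, replace = TRUE)))
    })
    res <- map_to_entrez(em, ann)
    rep <- res$report
    expect_identical(
      rep$n_input_probes,
      rep$n_mapped_genes + length(rep$dropped_unmapped) +
        rep$n_duplicates_discarded)
  }
})

test_that("upper-quartile log2-CPM matches its analytic single-sample value", {
  v <- matrix(c(10, 10, 10, 10), 4, 1,
              dimnames = list(sprintf("g%d", 1:4), "s1"))
  em <- expression_matrix(v, platform = "rnaseq_counts")
  out <- upper_quartile_log2cpm(em)
  # single sample: factor 1, effective library 40
  expect_equal(unname(out$values[, 1]), rep(log2(10 * 1e6 / 40 + 1), 4))
  expect_identical(out$scale, "log2")
  expect_identical(out$units, "cpm")
})

test_that("identical columns normalize identically and all-zero samples error", {
  v <- cbind(s1 = c(5, 0, 12, 3), s2 = c(5, 0, 12, 3), s3 = c(9, 1, 0, 4))
  rownames(v) <- sprintf("g%d", 1:4)
  out <- upper_quartile_log2cpm(expression_matrix(v, "rnaseq_counts"))
  expect_equal(out$values[, "s1"], out$values[, "s2"])

  vz <- cbind(s1 = c(1, 2), s2 = c(0, 0))
  rownames(vz) <- c("g1", "g2")
  expect_error(upper_quartile_log2cpm(expression_matrix(vz, "rnaseq_counts")),
               "all-zero sample.*s2")
})

test_that("upper-quartile log2-CPM matches the step-by-step oracle", {
  for (s in 1:100) {
    em <- rand_counts(6, 3, seed = s)
    em$values <- em$values + 1  # keep strictly positive
    out <- upper_quartile_log2cpm(em)
    expect_equal(out$values, oracle_uqcpm(em$values), tolerance = 1e-12)
  }
})

test_that("with offset 0, per-column count rescaling leaves output unchanged", {
  em <- rand_counts(8, 4, seed = 9)
  em$values <- em$values + 1
  base <- upper_quartile_log2cpm(em, offset = 0)
  scaled <- em
  scaled$values[, 2] <- scaled$values[, 2] * 7
  out <- upper_quartile_log2cpm(scaled, offset = 0)
  expect_equal(out$values[, 2], base$values[, 2], tolerance = 1e-9)
})

test_that("linear FPKM matches its analytic value and is library-scale invariant", {
  v <- matrix(10, 1, 1, dimnames = list("g1", "s1"))
  # library size forced to 1e6 via a filler gene
  v2 <- rbind(v, g2 = 1e6 - 10)
  em <- expression_matrix(v2, "rnaseq_counts")
  gl <- gene_lengths(c("g1", "g2"), c(1000, 500))
  out <- linear_fpkm(em, gl)
  expect_equal(out$values["g1", "s1"], 10)

  em5 <- rand_counts(5, 3, seed = 2)
  em5$values <- em5$values + 1
  gl5 <- gene_lengths(rownames(em5$values), c(500, 1500, 800, 2000, 1200))
  base <- linear_fpkm(em5, gl5)
  doubled <- em5
  doubled$values[, 1] <- doubled$values[, 1] * 2
  expect_equal(linear_fpkm(doubled, gl5)$values[, 1], base$values[, 1])

  # brute-force check
  L <- colSums(em5$values)
  for (i in 1:5) for (j in 1:3) {
    expect_equal(base$values[i, j],
                 unname(em5$values[i, j] * 1e9 / (L[j] * gl5$length[i])),
                 tolerance = 1e-12)
  }
  expect_error(linear_fpkm(em5, gene_lengths("g001", 100)), "missing gene length")
})

test_that("prepare_matrix dispatches exactly per platform and family", {
  cnt <- rand_counts(6, 3, seed = 4)
  cnt$values <- cnt$values + 1
  gl <- gene_lengths(rownames(cnt$values), rep(1000, 6))

  nc <- prepare_matrix(cnt, gl, family = "NC")
  expect_equal(nc$values, upper_quartile_log2cpm(cnt)$values)
  ssp <- prepare_matrix(cnt, gl, family = "SSP")
  expect_equal(ssp$values, linear_fpkm(cnt, gl)$values)
  expect_error(prepare_matrix(cnt, NULL, family = "SSP"), "lengths")

  lf <- rand_expression(6, 3, platform = "rnaseq_log2fpkm", seed = 5)
  expect_identical(prepare_matrix(lf, family = "NC"), lf)
  back <- prepare_matrix(lf, family = "SSP")
  expect_equal(back$values, 2^lf$values)
  expect_identical(back$scale, "linear")

  ma <- rand_expression(6, 3, platform = "microarray", seed = 6)
  expect_identical(prepare_matrix(ma, family = "NC"), ma)
  expect_equal(prepare_matrix(ma, family = "SSP")$values, 2^ma$values)

  # idempotence of the NC route on normalized platforms
  expect_identical(prepare_matrix(prepare_matrix(ma, family = "NC"),
                                  family = "NC"), ma)
})
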