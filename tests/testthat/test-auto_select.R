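# Cohort diagnostics and the AUTO selection algorithm.

test_that("ER+ percentage uses the known-status denominator", {
  d <- cohort_diagnostics(make_clinical(n_er_pos = 54, n_er_neg = 64))
  expect_equal(round(d$er_pos_pct, 1), 45.8)

  d0 <- cohort_diagnostics(make_clinical(n_er_pos = 0, n_er_neg = 20))
  expect_equal(d0$er_pos_pct, 0)

  dmix <- cohort_diagnostics(
    make_clinical(n_er_pos = 10, n_er_neg = 5, n_er_unknown = 5))
  expect_equal(round(dmix$er_pos_pct, 1), 66.7)
  expect_identical(dmix$n_er_unknown, 5L)

  expect_error(cohort_diagnostics(make_clinical(n_er_unknown = 4)),
               "no sample")
})

test_that("ER-deviation boundaries route exactly as printed", {
  branch_at <- function(pct) {
    clin <- make_clinical(n_er_pos = pct, n_er_neg = 100 - pct)
    select_methods(cohort_diagnostics(clin), "unselected")$branch
  }
  expect_identical(branch_at(39), "deviated")
  expect_identical(branch_at(40), "balanced")
  expect_identical(branch_at(68), "balanced")
  expect_identical(branch_at(69), "deviated")
  expect_identical(branch_at(10), "deviated")
  expect_identical(branch_at(90), "deviated")

  dev <- select_methods(cohort_diagnostics(
    make_clinical(n_er_pos = 10, n_er_neg = 90)), "unselected")
  expect_setequal(setdiff(dev$enabled, c("AIMS", "sspbc")),
                  c("cIHC", "cIHC.itr", "genefu.robust"))
  bal <- select_methods(cohort_diagnostics(
    make_clinical(n_er_pos = 50, n_er_neg = 50)), "unselected")
  expect_setequal(setdiff(bal$enabled, c("AIMS", "sspbc")),
                  c("parker.original", "genefu.scale", "PCAPAM50"))
  expect_identical(
    bal$disabled$reason[bal$disabled$method == "cIHC"],
    "requires_er_deviated_cohort")
})

test_that("subgroup size gates switch at 15/18 and 8/9", {
  ssbc_on <- function(n, type, her2 = "neg") {
    clin <- if (type == "ER+") {
      make_clinical(n_er_pos = n, her2_pos = her2)
    } else {
      make_clinical(n_er_neg = n, her2_neg = her2)
    }
    d <- select_methods(cohort_diagnostics(clin), type)
    "ssBC" %in% d$enabled
  }
  expect_false(ssbc_on(14, "ER+"))
  expect_true(ssbc_on(15, "ER+"))
  expect_false(ssbc_on(17, "ER-"))
  expect_true(ssbc_on(18, "ER-"))

  ssbc2_on <- function(n, type) {
    clin <- switch(type,
      "ER+/HER2-" = make_clinical(n_er_pos = n, her2_pos = "neg"),
      "ER-/HER2-" = make_clinical(n_er_neg = n, her2_neg = "neg"))
    d <- select_methods(cohort_diagnostics(clin), type)
    "ssBC.v2" %in% d$enabled
  }
  expect_false(ssbc2_on(7, "ER+/HER2-"))
  expect_true(ssbc2_on(8, "ER+/HER2-"))
  expect_false(ssbc2_on(8, "ER-/HER2-"))
  expect_true(ssbc2_on(9, "ER-/HER2-"))

  # the two gate families are independent: 8 ER+/HER2- samples enable
  # ssBC.v2 while ssBC (needing 15 ER+) stays disabled
  d8 <- select_methods(cohort_diagnostics(
    make_clinical(n_er_pos = 8, her2_pos = "neg")), "ER+/HER2-")
  expect_true("ssBC.v2" %in% d8$enabled)
  expect_false("ssBC" %in% d8$enabled)
  # SSP methods stay on below every gate
  d14 <- select_methods(cohort_diagnostics(
    make_clinical(n_er_pos = 14)), "ER+")
  expect_true(all(c("AIMS", "sspbc") %in% d14$enabled))
})

test_that("HER2+ cohorts evaluate both HER2+ subgroups independently", {
  # 10 ER+/HER2+ and 2 ER-/HER2+: gate 8 passes for ER+/HER2+ only
  clin <- clinical_table(sprintf("h%02d", 1:12),
                         er = c(rep("pos", 10), rep("neg", 2)),
                         pr = rep("neg", 12),
                         her2 = rep("pos", 12))
  d <- select_methods(cohort_diagnostics(clin), "HER2+")
  expect_true("ssBC.v2" %in% d$enabled)
  expect_identical(d$ssbc2_subgroups, "ER+/HER2+")
  expect_false("ssBC" %in% d$enabled)
})

test_that("TN branch requires explicit declarations and gates at 18", {
  tn18 <- make_clinical(n_er_neg = 18, tn = TRUE)
  d <- select_methods(cohort_diagnostics(tn18), "TN")
  expect_identical(d$branch, "tn")
  expect_true("ssBC" %in% d$enabled)
  expect_identical(d$ssbc_subgroup, "TN")

  tn17 <- make_clinical(n_er_neg = 17, tn = TRUE)
  expect_false("ssBC" %in% select_methods(cohort_diagnostics(tn17),
                                          "TN")$enabled)

  undeclared <- make_clinical(n_er_neg = 20)
  expect_error(select_methods(cohort_diagnostics(undeclared), "TN"),
               "TN declaration")
  expect_error(select_methods(cohort_diagnostics(tn18), "basal-only"),
               "unknown cohort_type")
})

test_that("partition, SSP-always-on and gate monotonicity hold everywhere", {
  registry <- default_registry()
  cohorts <- list()
  for (n in c(1, 7, 8, 9, 14, 15, 17, 18, 25)) {
    cohorts <- c(cohorts,
                 list(list(clin = make_clinical(n_er_pos = n), types =
                             c("ER+", "ER+/HER2-")),
                      list(list = NULL,
                           clin = make_clinical(n_er_neg = n),
                           types = c("ER-", "ER-/HER2-")),
                      list(clin = make_clinical(n_er_pos = n,
                                                n_er_neg = n + 3),
                           types = "unselected"),
                      list(clin = make_clinical(n_er_neg = n, tn = TRUE),
                           types = "TN")))
  }
  for (case in cohorts) {
    d0 <- cohort_diagnostics(case$clin)
    for (ty in case$types) {
      dec <- select_methods(d0, ty)
      both <- c(dec$enabled, dec$disabled$method)
      expect_setequal(both, names(registry))
      expect_identical(anyDuplicated(both), 0L)
      expect_true(all(c("AIMS", "sspbc") %in% dec$enabled))
    }
  }

  # enabling never flips off as a subgroup count increases
  prev_on <- FALSE
  for (n in 1:30) {
    dec <- select_methods(cohort_diagnostics(
      make_clinical(n_er_pos = n)), "ER+")
    on <- "ssBC" %in% dec$enabled
    expect_false(prev_on && !on)
    prev_on <- on
  }
})
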