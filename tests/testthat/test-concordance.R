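co <- specimen_cohort()
res <- classify_variability(co)
labs <- cohort_ihc_labels(co)

test_that("per-group and overall concordance reproduce the reported percentages", {
  expect_equal(concordance(res, labs, "nci", "MSI-H:BRAF-mutant")$pct_concordant, 93)
  expect_equal(concordance(res, labs, "nci", "MSI-H:BRAF-wild-type")$pct_concordant, 85)
  expect_equal(concordance(res, labs, "nci", "MSS")$pct_concordant, 79)
  expect_equal(concordance(res, labs, "nci")$pct_concordant, 86)
  expect_equal(concordance(res, labs, "score", "MSI-H:BRAF-mutant")$pct_concordant, 94)
  expect_equal(concordance(res, labs, "score", "MSI-H:BRAF-wild-type")$pct_concordant, 87)
  expect_equal(concordance(res, labs, "score", "MSS")$pct_concordant, 77)
  expect_equal(concordance(res, labs, "score")$pct_concordant, 87)

  # evaluated/concordant fractions behind the headline numbers
  r <- concordance(res, labs, "nci", "MSI-H:BRAF-mutant")
  expect_equal(c(r$n_concordant, r$n_evaluated), c(14, 15))
  r <- concordance(res, labs, "score")
  expect_equal(c(r$n_concordant, r$n_evaluated), c(40, 46))
})

test_that("exclusion bookkeeping conserves sample counts", {
  ct <- concordance_table(res, labs)
  expect_true(all(ct$n_excluded_msil + ct$n_evaluated == ct$n_total))
  expect_true(all(ct$n_concordant <= ct$n_evaluated))
  expect_equal(ct$n_total[ct$group == "all"], c(56, 56))
})

test_that("tier counts cover all 56 specimens and the 3-5 score tier holds 10", {
  tc <- tier_counts(res)
  expect_equal(sum(tc$n[tc$method == "score"]), 56)
  expect_equal(sum(tc$n[tc$method == "nci"]), 56)
  expect_equal(tc$n[tc$method == "score" & tc$status == "MSI-L"], 10)
  expect_equal(tier_counts(res[0, ])$n, rep(0L, 6))
})

test_that("unmatched sample ids are reported by name", {
  expect_error(concordance(res, labs[-1, ], "nci"), labs$sample_id[1], fixed = TRUE)
})

test_that("all calls MSI-L leaves the percentage undefined, not crashing", {
  one <- classify_variability(data.frame(sample_id = "a", `BAT-25` = 4,
                                         `BAT-26` = 0, D5S346 = 0, D2S123 = 0,
                                         D17S250 = 0, check.names = FALSE))
  lab <- tibble::tibble(sample_id = "a", ihc_status = "MSS", subgroup = NA_character_)
  r <- concordance(one, lab, "nci")
  expect_equal(r$n_evaluated, 0)
  expect_true(is.na(r$pct_concordant))
})

test_that("Kruskal-Wallis on MSI scores matches a first-principles rank computation", {
  gs <- group_score_test(res, labs)
  df <- merge(res, labs, by = "sample_id")
  expect_equal(gs$statistic, oracle_kruskal_h(df$msi_score, df$subgroup),
               tolerance = 1e-10)
  expect_equal(gs$df, 2)
  expect_lt(gs$p.value, 0.05)
  expect_equal(sum(gs$groups$n), 56)

  # null case: three identical distributions
  res0 <- classify_variability(data.frame(
    sample_id = as.character(1:9),
    `BAT-25` = rep(c(0, 10, 20), 3), `BAT-26` = 0, D5S346 = 0, D2S123 = 0,
    D17S250 = 0, check.names = FALSE))
  lab0 <- tibble::tibble(sample_id = as.character(1:9),
                         ihc_status = "MSS",
                         subgroup = rep(c("a", "b", "c"), each = 3))
  gs0 <- group_score_test(res0, lab0)
  expect_lt(gs0$statistic, 1e-8)
  expect_gt(gs0$p.value, 0.99)

  # complete separation of two groups
  res1 <- classify_variability(data.frame(
    sample_id = as.character(1:6),
    `BAT-25` = c(1, 2, 3, 101, 102, 103) / 2, `BAT-26` = c(1, 2, 3, 101, 102, 103) / 2,
    D5S346 = 0, D2S123 = 0, D17S250 = 0, check.names = FALSE))
  lab1 <- tibble::tibble(sample_id = as.character(1:6), ihc_status = "MSS",
                         subgroup = rep(c("lo", "hi"), each = 3))
  expect_lt(group_score_test(res1, lab1)$p.value, 0.05)

  expect_error(group_score_test(res1, dplyr::mutate(lab1, subgroup = "one")),
               ">= 2 subgroups")
})

test_that("group_score_test is invariant to within-group sample order", {
  perm <- sample(seq_len(nrow(labs)))
  gs1 <- group_score_test(res, labs)
  gs2 <- group_score_test(res[perm, ], labs)
  expect_equal(gs1$statistic, gs2$statistic)
})

test_that("two-group mean comparison runs on the cohort subgroups", {
  tt <- group_mean_test(res, labs, "MSI-H:BRAF-mutant", "MSS")
  expect_s3_class(tt, "htest")
  expect_lt(tt$p.value, 0.05)
  expect_error(group_mean_test(res, labs, "MSI-H:BRAF-mutant", "nope"), ">= 2 samples")
})
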