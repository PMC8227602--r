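panel <- msi_panel()

test_that("noise filter keeps peaks at or above the threshold, against the pre-filter total", {
  tr <- peak_trace(c(100, 101, 102), c(98, 1, 1))
  expect_equal(filter_noise(tr, 0.02)$size_bp, 100)

  tr2 <- peak_trace(c(100, 102), c(50, 50))
  expect_equal(nrow(filter_noise(tr2, 0.02)), 2)

  # boundary is >=: a peak at exactly 2% of total survives
  tr3 <- peak_trace(c(100, 105), c(98, 2))
  expect_equal(filter_noise(tr3, 0.02)$size_bp, c(100, 105))

  # noise_fraction 0 is the identity
  expect_equal(filter_noise(tr, 0), tr, ignore_attr = TRUE)

  z <- filter_noise(peak_trace(c(100), c(0)), 0.02)
  expect_equal(nrow(z), 0)
  expect_equal(attr(z, "qc"), "zero_signal")
})

test_that("novelty requires both the distance and the extended-range rule", {
  normal <- peak_trace(c(120, 121, 122), c(100, 100, 100))

  # identical traces: every distance 0, nothing novel
  calls <- label_novel(normal, normal, panel)
  expect_false(any(calls$is_novel))

  # 2 bp away and inside range - 10: novel, with its signal share
  tum <- peak_trace(c(118, 120), c(30, 70))
  calls <- label_novel(tum, normal, panel)
  expect_true(calls$is_novel[calls$size_bp == 118])
  expect_equal(calls$signal_proportion[calls$size_bp == 118], 0.30)

  # > 10 bp beyond the normal range: never novel, whatever its signal
  tum2 <- peak_trace(c(135, 120), c(60, 40))
  calls2 <- label_novel(tum2, normal, panel)
  expect_false(calls2$is_novel[calls2$size_bp == 135])
  expect_false(calls2$within_extended_range[calls2$size_bp == 135])
})

test_that("empty normal after preprocessing flags the marker missing", {
  tum <- peak_trace(120, 100)
  calls <- label_novel(tum, peak_trace(), panel)
  expect_true(attr(calls, "missing"))
  res <- allelic_variability(tum, peak_trace(120, 0), panel, "BAT-25")
  expect_true(res$missing)
  expect_match(res$qc, "empty_normal")
})

test_that("novel-peak labels match an exhaustive brute-force oracle", {
  withr::local_seed(424242)
  for (rep in 1:300) {
    tum <- random_trace()
    nor <- random_trace()
    calls <- label_novel(tum, nor, panel)
    oracle <- oracle_novel(tum, nor, panel)
    expect_equal(calls$size_bp, oracle$size_bp)
    expect_equal(calls$is_novel, oracle$is_novel, info = paste("rep", rep))
  }
})

test_that("allelic variability sums novel-peak signal proportions", {
  normal <- peak_trace(c(120, 121), c(500, 500))

  # tumour identical to normal: exactly 0, stable
  res <- allelic_variability(normal, normal, panel, "BAT-25")
  expect_identical(res$variability_pct, 0)
  expect_false(res$unstable)

  # one novel peak with 36% of tumour signal
  tum <- peak_trace(c(114, 120, 121), c(36, 32, 32))
  res <- allelic_variability(tum, normal, panel, "BAT-25")
  expect_equal(res$variability_pct, 36)
  expect_true(res$unstable)

  # two novel peaks at 7% and 13% sum to 20%
  tum2 <- peak_trace(c(114, 116, 120, 121), c(7, 13, 40, 40))
  calls <- attr(allelic_variability(tum2, normal, panel, "BAT-25"), "novel_calls")
  expect_equal(sort(calls$signal_proportion[calls$is_novel]), c(0.07, 0.13))
  expect_equal(allelic_variability(tum2, normal, panel, "BAT-25")$variability_pct, 20)
})

test_that("variability is scale-free, bounded, and signal proportions sum to 1", {
  withr::local_seed(99)
  for (rep in 1:50) {
    tum <- random_trace()
    nor <- random_trace()
    res <- allelic_variability(tum, nor, panel, "m")
    expect_gte(res$variability_pct, 0)
    expect_lte(res$variability_pct, 100)

    # scaling all tumour signals leaves the result unchanged
    tum_scaled <- peak_trace(tum$size_bp, tum$rfu * 7.3)
    res2 <- allelic_variability(tum_scaled, nor, panel, "m")
    expect_equal(res2$variability_pct, res$variability_pct)

    # pre-filter proportions over ALL tumour peaks sum to 1
    p0 <- msi_panel(noise_fraction = 0)
    calls <- label_novel(tum, nor, p0)
    expect_equal(sum(calls$signal_proportion), 1, tolerance = 1e-9)
  }
})

test_that("a sub-threshold tumour peak is filtered and cannot become novel", {
  normal <- peak_trace(120, 1000)
  tum <- peak_trace(c(110, 120), c(5, 995)) # 0.5% of signal, 10 bp away
  calls <- label_novel(tum, normal, panel)
  expect_false(110 %in% calls$size_bp)
  expect_equal(allelic_variability(tum, normal, panel, "m")$variability_pct, 0)
})

test_that("denominator mode switches between pre- and post-filter totals", {
  normal <- peak_trace(120, 1000)
  # 100 novel + 890 at normal position + 10 filtered as noise
  tum <- peak_trace(c(114, 120, 130), c(100, 890, 10))
  pre <- allelic_variability(tum, normal, msi_panel(), "m")$variability_pct
  post <- allelic_variability(tum, normal,
                              msi_panel(denominator_mode = "post"), "m")$variability_pct
  expect_equal(pre, 10)
  expect_equal(post, 100 * 100 / 990)
})
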