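test_that("standard errors recovered from confidence intervals match t theory", {
  # large-n limit approaches the normal 2/1.96
  expect_equal(as.numeric(se_from_ci(10, 8, 12, n = 1e6)), 2 / 1.96,
               tolerance = 1e-4)
  # small-n t oracle: 2 / qt(0.975, 9)
  expect_equal(as.numeric(se_from_ci(10, 8, 12, n = 10)), 2 / qt(0.975, 9))
  expect_equal(as.numeric(se_from_ci(10, 8, 12, n = 10)), 0.8841119,
               tolerance = 1e-6)
  # degenerate interval
  expect_equal(as.numeric(se_from_ci(5, 5, 5, n = 8)), 0)
  expect_error(se_from_ci(10, 12, 8, n = 10), "inverted")
  # round trip: CI built from a known SE recovers it
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:50, 1); se <- runif(1, 0.1, 3); m <- rnorm(1)
    half <- qt(0.975, n - 1) * se
    expect_equal(as.numeric(se_from_ci(m, m - half, m + half, n)), se)
  }
})

test_that("summary-based tests agree exactly with raw-data t tests", {
  set.seed(99)
  for (i in 1:10) {
    x1 <- rnorm(sample(5:40, 1), mean = 10, sd = runif(1, 1, 4))
    x2 <- rnorm(sample(5:40, 1), mean = 10 + rnorm(1), sd = runif(1, 1, 4))
    g1 <- group_summary("a", length(x1), mean(x1), sd = sd(x1))
    g2 <- group_summary("b", length(x2), mean(x2), sd = sd(x2))

    welch <- welch_test_from_summaries(g1, g2)
    ref_w <- t.test(x1, x2)
    expect_equal(welch$statistic, unname(ref_w$statistic))
    expect_equal(welch$df, unname(ref_w$parameter))
    expect_equal(welch$p_value, ref_w$p.value)

    pooled <- welch_test_from_summaries(g1, g2, method = "pooled")
    ref_p <- t.test(x1, x2, var.equal = TRUE)
    expect_equal(pooled$statistic, unname(ref_p$statistic))
    expect_equal(pooled$p_value, ref_p$p.value)
  }
})

test_that("summary tests handle identical groups, symmetry and large separation", {
  g <- group_summary("g", 20, 10, sd = 2)
  same <- welch_test_from_summaries(g, g)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  g1 <- group_summary("a", 25, 10, sd = 2)
  g2 <- group_summary("b", 30, 12, sd = 3)
  ab <- welch_test_from_summaries(g1, g2)
  ba <- welch_test_from_summaries(g2, g1)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$df, ba$df)

  # means 10 SE apart: overwhelming evidence
  se <- 2 / sqrt(25)
  far <- welch_test_from_summaries(
    group_summary("a", 25, 10, sd = 2),
    group_summary("b", 25, 10 + 10 * se * sqrt(2), sd = 2))
  expect_lt(far$p_value, 1e-6)

  # summaries built from a CI work identically to SD input
  x <- rnorm(15, 10, 2)
  half <- qt(0.975, 14) * sd(x) / sqrt(15)
  via_ci <- group_summary("c", 15, mean(x), ci_low = mean(x) - half,
                          ci_high = mean(x) + half)
  via_sd <- group_summary("c", 15, mean(x), sd = sd(x))
  expect_equal(via_ci$se, via_sd$se)
})

test_that("NOAEL/LOAEL classification follows the lowest-significant-dose rule", {
  res <- classify_noael_loael(data.frame(dose = c(68, 345, 733),
                                         significant = c(FALSE, FALSE, TRUE)))
  expect_equal(res$noael, 345)
  expect_equal(res$loael, 733)
  expect_false(res$non_monotone)

  none <- classify_noael_loael(data.frame(dose = c(10, 20, 30),
                                          significant = FALSE))
  expect_equal(none$noael, 30)
  expect_true(is.na(none$loael))

  all_sig <- classify_noael_loael(data.frame(dose = c(10, 20, 30),
                                             significant = TRUE))
  expect_true(is.na(all_sig$noael))
  expect_equal(all_sig$loael, 10)

  nm <- classify_noael_loael(data.frame(dose = c(10, 20, 30),
                                        significant = c(TRUE, FALSE, TRUE)))
  expect_equal(nm$loael, 10)
  expect_true(nm$non_monotone)

  expect_error(classify_noael_loael(data.frame(dose = c(30, 10),
                                               significant = c(TRUE, FALSE))),
               "ascending")
})

test_that("NOAEL sits strictly below the LOAEL whenever both exist", {
  set.seed(13)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    doses <- sort(runif(k, 1, 1000))
    sig <- runif(k) < 0.5
    res <- classify_noael_loael(data.frame(dose = doses, significant = sig))
    if (!is.na(res$noael) && !is.na(res$loael)) {
      expect_lt(res$noael, res$loael)
    }
  }
})

test_that("classification works end to end from generated quartile summaries", {
  qs <- generate_quartile_summaries(quartile_summary_params(seed = 2024))
  cmp <- compare_quartiles(qs)
  expect_length(cmp, 4)
  # summary-based p equals the raw-data Welch p for each quartile
  for (nm in names(qs$quartiles)) {
    ref <- t.test(qs$raw$control, qs$raw[[nm]])
    got <- cmp[[which(vapply(cmp, `[[`, character(1), "group") == nm)]]
    expect_equal(got$p_value, ref$p.value)
  }
  res <- classify_noael_loael(cmp)
  expect_true(is.na(res$loael) || res$loael %in% c(68, 172, 345, 733))
})
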