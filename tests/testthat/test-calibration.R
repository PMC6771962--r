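test_that("an exact line is recovered with zero residual error", {
  x <- c(10, 20, 40, 80)
  y <- exp(0.5 + 0.8 * log(x))
  fit <- fit_loglog(x, y)
  expect_equal(fit$slope, 0.8)
  expect_equal(fit$intercept, 0.5)
  expect_equal(fit$residual_se, 0, tolerance = 1e-10)
})

test_that("coefficients match the normal-equation oracle on random data", {
  set.seed(55)
  for (i in 1:10) {
    d <- tiny_cohort(seed = 200 + i, n = sample(5:30, 1),
                     noise = runif(1, 0.1, 1))
    fit <- fit_loglog(d)
    ora <- ols_oracle(log(d$maternal_serum), log(d$tsh))
    expect_equal(fit$slope, ora$slope)
    expect_equal(fit$intercept, ora$intercept)
    expect_equal(fit$residual_se, ora$sigma)
  }
})

test_that("non-positive values are rejected with the offending row", {
  d <- tiny_cohort()
  d$maternal_serum[3] <- -1
  expect_error(fit_loglog(d), "3")
  d2 <- tiny_cohort()
  d2$tsh[5] <- 0
  expect_error(fit_loglog(d2), "5")
  expect_error(fit_loglog(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_error(fit_loglog(c(1, 2), c(1, 2)), "at least 3")
})

test_that("inverse prediction inverts forward prediction exactly", {
  fit <- fit_loglog(tiny_cohort())
  for (th in c(2, 5, 10)) {
    pred <- inverse_predict(fit, th)
    expect_equal(predict_outcome(fit, pred$point), th)
  }
  # threshold at the fitted mean response returns the predictor mean
  th_bar <- exp(fit$ybar_log)
  expect_equal(log(inverse_predict(fit, th_bar)$point), fit$xbar_log)
})

test_that("a zero-noise fit yields a zero-width interval at the point", {
  x <- c(10, 20, 40, 80, 160)
  y <- exp(-0.4 + 0.37 * log(x))
  fit <- fit_loglog(x, y)
  for (mth in c("approx_se", "fieller")) {
    pred <- inverse_predict(fit, 5, method = mth)
    expect_equal(pred$ci_low, pred$point)
    expect_equal(pred$ci_high, pred$point)
  }
})

test_that("interval endpoints in ppt are invariant to the internal log base", {
  # independent oracle in base 10: fit and invert entirely in log10, then
  # back-transform; all ppt-scale results must agree with the natural-log path
  d <- tiny_cohort(seed = 77, n = 30, noise = 0.4)
  fit <- fit_loglog(d)
  l10x <- log10(d$maternal_serum); l10y <- log10(d$tsh)
  o <- ols_oracle(l10x, l10y)
  th <- 5
  x0_10 <- (log10(th) - o$intercept) / o$slope
  expect_equal(10^x0_10, inverse_predict(fit, th)$point)
  n <- length(l10x)
  sxx10 <- sum((l10x - mean(l10x))^2)
  se10 <- (o$sigma / abs(o$slope)) *
    sqrt(1 / n + (log10(th) - mean(l10y))^2 / (o$slope^2 * sxx10))
  tq <- qt(0.975, n - 2)
  pred <- inverse_predict(fit, th, method = "approx_se")
  expect_equal(10^(x0_10 - tq * se10), pred$ci_low)
  expect_equal(10^(x0_10 + tq * se10), pred$ci_high)
})

test_that("the replicate term widens the interval and matches its formula", {
  fit <- fit_loglog(tiny_cohort(seed = 31, n = 40, noise = 0.5))
  inf_mode <- inverse_predict(fit, 5, m = Inf)
  one_mode <- inverse_predict(fit, 5, m = 1)
  expect_gt(one_mode$ci_high / one_mode$ci_low,
            inf_mode$ci_high / inf_mode$ci_low)
  # closed-form check of the Massart SE in both modes
  for (m in c(1, 4, Inf)) {
    pr <- inverse_predict(fit, 5, m = m)
    se <- (fit$residual_se / abs(fit$slope)) *
      sqrt((if (is.infinite(m)) 0 else 1 / m) + 1 / fit$n +
             (log(5) - fit$ybar_log)^2 / (fit$slope^2 * fit$sxx_log))
    expect_equal(pr$se_log, se)
  }
})

test_that("approx and Fieller intervals agree when the slope is strong", {
  # strong-slope fixture: slope t-statistic far above 10
  set.seed(8)
  x <- exp(rnorm(200, 3, 1.2))
  y <- exp(0.2 + 0.9 * log(x) + rnorm(200, 0, 0.25))
  fit <- fit_loglog(x, y)
  tstat <- fit$slope / (fit$residual_se / sqrt(fit$sxx_log))
  expect_gt(tstat, 10)
  a <- inverse_predict(fit, 5, method = "approx_se")
  f <- inverse_predict(fit, 5, method = "fieller")
  wa <- log(a$ci_high) - log(a$ci_low)
  wf <- log(f$ci_high) - log(f$ci_low)
  expect_lt(abs(wa - wf) / wf, 0.01)
})

test_that("a slope CI spanning zero gives a signalled unbounded Fieller interval", {
  set.seed(12)
  x <- exp(rnorm(12, 3, 0.8))
  y <- exp(1 + 0.02 * log(x) + rnorm(12, 0, 1.5))  # essentially flat
  fit <- fit_loglog(x, y)
  expect_warning(pred <- inverse_predict(fit, 5, method = "fieller"),
                 "unbounded")
  expect_true(pred$unbounded_above)
  expect_true(pred$unbounded_below)
})

test_that("upper limits beyond the cap are flagged for '>' presentation", {
  set.seed(3)
  x <- exp(rnorm(15, 2.5, 0.9))
  y <- exp(-0.4 + 0.37 * log(x) + rnorm(15, 0, 1.2))
  fit <- fit_loglog(x, y)
  pred <- inverse_predict(fit, 10, cap = 100)
  expect_true(pred$unbounded_above)
  pred2 <- inverse_predict(fit, 10, cap = Inf)
  expect_false(is.finite(pred2$cap) && pred2$ci_high > pred2$cap)
})

test_that("interval width shrinks with n and grows with residual noise", {
  width_at <- function(n, noise, seed) {
    set.seed(seed)
    x <- exp(rnorm(n, 3, 1))
    y <- exp(-0.4 + 0.37 * log(x) + rnorm(n, 0, noise))
    pr <- inverse_predict(fit_loglog(x, y), 5)
    log(pr$ci_high) - log(pr$ci_low)
  }
  # averaged over replicate seeds to beat sampling noise
  w_small_n <- mean(vapply(1:30, function(s) width_at(25, 0.5, s), 1))
  w_big_n <- mean(vapply(1:30, function(s) width_at(400, 0.5, s), 1))
  expect_lt(w_big_n, w_small_n)
  w_quiet <- mean(vapply(1:30, function(s) width_at(50, 0.3, 100 + s), 1))
  w_noisy <- mean(vapply(1:30, function(s) width_at(50, 0.9, 100 + s), 1))
  expect_lt(w_quiet, w_noisy)
})

test_that("threshold PODs carry the screening/clinical classification defaults", {
  coh <- generate_tsh_cohort(tsh_cohort_params(seed = 6, noise_log_sd = 0))
  fit <- fit_loglog(coh)
  pod5 <- pod_from_threshold(fit, 5)
  pod10 <- pod_from_threshold(fit, 10)
  # zero noise: the generator's curve crosses 5 uU/mL at exactly 235 ppt
  expect_equal(pod5$dose$value, 235, tolerance = 1e-6)
  expect_equal(pod10$dose$value, 1513.56, tolerance = 1e-4)
  expect_identical(pod5$classification, "LOAEL")
  expect_identical(pod10$classification, "NOAEL")
  expect_gt(pod10$dose$value, pod5$dose$value)  # monotone in the threshold
  # override and unknown-threshold behaviour
  expect_identical(pod_from_threshold(fit, 5,
                                      classification = "NOAEL")$classification,
                   "NOAEL")
  expect_error(pod_from_threshold(fit, 7), "classification")
})
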