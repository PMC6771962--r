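test_that("the p95 prior convention puts the nominal at the 95th percentile", {
  spec <- uf_prior(10)
  expect_equal(exp(spec$log_mean), sqrt(10))
  expect_equal(spec$log_sd, log(10 / sqrt(10)) / qnorm(0.95))
  expect_equal(spec$log_sd, 0.699936, tolerance = 1e-6)
  # defining property: quantile(0.95) == nominal, for any nominal
  for (nom in c(2, 3, 10, 100)) {
    sp <- uf_prior(nom)
    expect_equal(qlnorm(0.95, sp$log_mean, sp$log_sd), nom)
  }
  # degenerate nominal 1: median 1, floor spread
  sp1 <- uf_prior(1)
  expect_equal(exp(sp1$log_mean), 1)
  expect_equal(sp1$log_sd, 1e-6)
  expect_error(uf_prior(0.5), ">= 1")
  # alternative conventions
  mn <- uf_prior(10, "median_nominal", log_sd = 0.3)
  expect_equal(exp(mn$log_mean), 10)
  expect_equal(mn$log_sd, 0.3)
  expect_error(uf_prior(10, "median_nominal"), "log_sd")
  ex <- uf_prior(10, "explicit", log_mean = 1, log_sd = 0.2)
  expect_equal(ex$log_mean, 1)
})

test_that("point POD with point UFs collapses to the deterministic RfD", {
  pod <- pod_distribution("point", 20, kind = "intake",
                          metric = "TCDD", classification = "LOAEL")
  d <- induced_rfd(pod, list(uf_spec("UF_L", 10), uf_spec("UF_H", 3)),
                   n_samples = 1e4, seed = 1)
  expect_equal(d$point, 20 / 30)
  expect_true(all(d$samples == d$samples[1]))
  expect_equal(lower_bound(d, 0.025), 20 / 30)
  expect_equal(percentile_of(d, 0.5), 0)
  expect_equal(percentile_of(d, 1), 100)
})

test_that("the seed is a hard requirement and small draws are rejected", {
  pod <- pod_distribution("point", 20, kind = "intake",
                          metric = "TCDD", classification = "LOAEL")
  expect_error(induced_rfd(pod, list(uf_spec("UF_H", 3)), n_samples = 1e4),
               "seed")
  expect_error(induced_rfd(pod, list(uf_spec("UF_H", 3)), n_samples = 100,
                           seed = 1), "1e4")
})

test_that("Monte Carlo quantiles track the closed lognormal form", {
  pod <- pod_distribution(
    "lognormal",
    spec = lognormal_spec(log(200), 0.5),
    kind = "serum", metric = "TCDD", threshold = 5,
    classification = "LOAEL")
  ufs <- list(uf_spec("UF_L", 10, uf_prior(10)), uf_spec("UF_H", 3, uf_prior(3)))
  d <- induced_rfd(pod, ufs, n_samples = 1e5, seed = 9, anchor = epa_anchor())
  cf <- d$closed_form
  # closed form assembles by lognormal product algebra
  expect_equal(cf$log_mean,
               log(200 * 20 / 235) - 0.5 * log(10) - 0.5 * log(3))
  expect_equal(cf$log_sd,
               sqrt(0.5^2 + uf_prior(10)$log_sd^2 + uf_prior(3)$log_sd^2))
  for (p in c(0.025, 0.5, 0.975)) {
    expect_equal(quantile(d$samples, p)[[1]],
                 qlnorm(p, cf$log_mean, cf$log_sd), tolerance = 0.02)
  }
  # Kolmogorov-Smirnov agreement between draws and the analytic lognormal
  ks <- suppressWarnings(ks.test(d$samples, plnorm, cf$log_mean, cf$log_sd))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("sequential UFs equal a single product-distribution UF", {
  pod <- pod_distribution("lognormal", spec = lognormal_spec(log(50), 0.4),
                          kind = "intake", metric = "TCDD",
                          classification = "LOAEL")
  seq_ufs <- list(uf_spec("UF_L", 10, uf_prior(10)),
                  uf_spec("UF_H", 3, uf_prior(3)))
  prod_spec <- lognormal_spec(uf_prior(10)$log_mean + uf_prior(3)$log_mean,
                              sqrt(uf_prior(10)$log_sd^2 + uf_prior(3)$log_sd^2))
  prod_uf <- list(uf_spec("UF_LH", 30, prod_spec))
  d_seq <- induced_rfd(pod, seq_ufs, n_samples = 1e4, seed = 4)
  d_prod <- induced_rfd(pod, prod_uf, n_samples = 1e4, seed = 4)
  expect_equal(d_seq$closed_form$log_mean, d_prod$closed_form$log_mean)
  expect_equal(d_seq$closed_form$log_sd, d_prod$closed_form$log_sd)
})

test_that("lower_bound and percentile_of are mutually consistent and monotone", {
  pod <- pod_distribution("lognormal", spec = lognormal_spec(log(100), 0.8),
                          kind = "intake", metric = "TCDD",
                          classification = "NOAEL")
  d <- induced_rfd(pod, list(uf_spec("UF_H", 3, uf_prior(3))),
                   n_samples = 1e4, seed = 2)
  expect_equal(percentile_of(d, lower_bound(d, 0.025)), 2.5)
  expect_equal(percentile_of(d, lower_bound(d, 0.5)), 50)
  expect_equal(lower_bound(d, 0.5),
               qlnorm(0.5, d$closed_form$log_mean, d$closed_form$log_sd))
  # closed-form analytic quantile identity
  cf <- d$closed_form
  expect_equal(lower_bound(d, 0.025),
               exp(cf$log_mean + qnorm(0.025) * cf$log_sd))
  # three log-SDs below the median sits at Phi(-3) = 0.135%
  expect_equal(percentile_of(d, exp(cf$log_mean - 3 * cf$log_sd)),
               100 * pnorm(-3))
  # monotone in p
  ps <- c(0.01, 0.025, 0.1, 0.5, 0.9)
  expect_true(all(diff(vapply(ps, function(p) lower_bound(d, p), 1)) > 0))
  expect_error(lower_bound(d, 1.2), "p")
  # analytic tails resolve far below Monte Carlo resolution
  tiny <- percentile_of(d, lower_bound(d, 1e-12))
  expect_equal(tiny, 1e-10, tolerance = 1e-6)
})

test_that("without a closed form, sub-resolution tails are censored not invented", {
  pod <- pod_distribution("lognormal", spec = lognormal_spec(log(100), 0.5),
                          kind = "intake", metric = "TCDD",
                          classification = "NOAEL")
  d <- induced_rfd(pod, list(uf_spec("UF_H", 3, uf_prior(3))),
                   n_samples = 1e4, seed = 3)
  d$closed_form <- NULL  # force the empirical path
  expect_warning(p <- percentile_of(d, min(d$samples) / 100),
                 "Monte Carlo resolution")
  expect_equal(as.numeric(p), 100 / length(d$samples))
  expect_true(isTRUE(attr(p, "censored")))
})

test_that("the scenario grid has exactly eight reproducible scenarios", {
  coh <- generate_tsh_cohort(tsh_cohort_params(seed = 10))
  fit_tcdd <- fit_loglog(coh)
  fit_teq <- fit_loglog(as_teq_cohort(coh))
  g1 <- scenario_grid(fit_tcdd, fit_teq, epa_anchor(), n_samples = 1e4,
                      seed = 20)
  expect_equal(nrow(g1$summary), 8)
  expect_equal(length(g1$distributions), 8)
  expect_false(anyDuplicated(g1$summary$scenario) > 0)
  expect_setequal(
    g1$summary$scenario,
    as.vector(outer(c("TCDD", "TEQ"),
                    as.vector(outer(c(5, 10), c("NOAEL", "LOAEL"),
                                    function(t, cl) paste0("t", t, "_", cl))),
                    paste, sep = "_")))
  # identical seed => bit-identical summary
  g2 <- scenario_grid(fit_tcdd, fit_teq, epa_anchor(), n_samples = 1e4,
                      seed = 20)
  expect_identical(g1$summary, g2$summary)
  # a metric/fit mix-up is caught
  expect_error(scenario_grid(fit_teq, fit_teq, epa_anchor(), n_samples = 1e4,
                             seed = 1), "tagged")
})

test_that("grid lower bounds obey the NOAEL/LOAEL and TEQ/TCDD orderings", {
  for (s in c(101, 202, 303)) {
    coh <- generate_tsh_cohort(tsh_cohort_params(seed = s))
    g <- scenario_grid(fit_loglog(coh), fit_loglog(as_teq_cohort(coh)),
                       epa_anchor(), n_samples = 1e4, seed = s)
    sm <- g$summary
    key <- function(metric, thr, cls)
      sm[sm$metric == metric & sm$threshold == thr &
           sm$classification == cls, ]
    for (metric in c("TCDD", "TEQ")) {
      for (thr in c(5, 10)) {
        expect_gt(key(metric, thr, "NOAEL")$p2.5,
                  key(metric, thr, "LOAEL")$p2.5)
      }
    }
    for (thr in c(5, 10)) {
      for (cls in c("NOAEL", "LOAEL")) {
        expect_gte(key("TEQ", thr, cls)$p2.5, key("TCDD", thr, cls)$p2.5)
      }
    }
  }
})
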