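# Shared fixtures and independent oracles for the test suite.

# Table-style serum->intake anchor: 235 ppt maternal serum <-> 0.020 ng/kg/day.
epa_anchor <- function() {
  serum_intake_anchor(serum_conc(235, "TCDD"),
                      intake_rate(0.020, "ng/kg/day"))
}

# Independent ordinary-least-squares oracle: normal equations, no lm().
ols_oracle <- function(x, y) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  resid <- y - a - b * x
  list(intercept = a, slope = b, sigma = sqrt(sum(resid^2) / (n - 2)))
}

# Small deterministic exposure/outcome cohort with known noise, for
# regression-style checks that do not need the generator.
tiny_cohort <- function(seed = 101, n = 25, noise = 0.3) {
  set.seed(seed)
  x <- exp(rnorm(n, 3, 1))
  y <- exp(-0.4 + 0.37 * log(x) + rnorm(n, 0, noise))
  data.frame(maternal_serum = x, tsh = y)
}
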