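reduced_chain <- function(seed = 1) chain_spec(6000, 1000, 5, seed = seed)

test_that("chain bookkeeping: saved-sample count and seed determinism", {
  expect_equal((60000 - 10000) %/% 10, 5000)  # default spec saves 5000 draws
  set.seed(71)
  d <- data.frame(y = rnorm(30), x = rnorm(30))
  f1 <- bayes_lm(y ~ x, d, chain = chain_spec(2000, 500, 3, seed = 9))
  f2 <- bayes_lm(y ~ x, d, chain = chain_spec(2000, 500, 3, seed = 9))
  expect_identical(f1$samples, f2$samples)
  expect_identical(f1$sigma2, f2$sigma2)
  expect_equal(nrow(f1$samples), (2000 - 500) %/% 3)
  f3 <- bayes_lm(y ~ x, d, chain = chain_spec(2000, 500, 3, seed = 10))
  expect_false(identical(f1$samples, f3$samples))
  expect_error(chain_spec(1000, 1000), class = "rumenpls_input_error")
})

test_that("posterior means agree with the closed-form OLS estimate", {
  set.seed(13)
  n <- 50
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), g = factor(rep(c("a", "b"), n / 2)))
  d$y <- 1 + 2 * d$x1 - 1.5 * d$x2 + 0.8 * (d$g == "b") + rnorm(n, 0, 0.7)
  fit <- bayes_lm(y ~ x1 + x2 + g, d, chain = reduced_chain(3))
  ols <- coef(lm(y ~ x1 + x2 + g, d))
  for (cn in fit$coef_names) {
    mcse <- mc_error(fit$samples[, cn])
    expect_lt(abs(mean(fit$samples[, cn]) - ols[cn]), 3 * mcse + 1e-8)
  }
})

test_that("rank-deficient designs are caught or repaired", {
  set.seed(14)
  d <- data.frame(y = rnorm(20), a = factor(rep(c("u", "v"), 10)))
  d$b <- d$a                              # perfectly aliased factor
  expect_warning(fit <- bayes_lm(y ~ a + b, d, chain = chain_spec(500, 100, 1)),
                 "aliased")
  expect_false(any(grepl("^b", fit$coef_names)))
  X <- cbind(1, 1:20, 2 * (1:20))
  expect_error(gibbs_sample(rnorm(20), X, chain_spec(500, 100, 1)),
               class = "rumenpls_estimability")
})

test_that("posterior summaries: P0 symmetry, saturation, and Pr <= P0", {
  set.seed(15)
  sym <- fake_fit(rnorm(5000))
  s <- posterior_summary(sym, "b")
  expect_lt(abs(s$p0 - 0.5), 0.03)
  above <- fake_fit(runif(2000, 2, 3))
  s2 <- posterior_summary(above, "b", r = 1.5)
  expect_equal(s2$p0, 1)
  expect_equal(s2$pr, 1)
  for (mu in c(-1, 0, 0.5, 2)) {
    f <- fake_fit(rnorm(3000, mu))
    sm <- posterior_summary(f, "b", r = 0.4)
    expect_lte(sm$pr, sm$p0)
  }
  expect_error(posterior_summary(sym, "b", r = -1), class = "rumenpls_input_error")
})

test_that("HPD interval matches the analytic shortest interval of a known posterior", {
  # conjugate normal-model posterior for a mean is a scaled t; for a
  # symmetric unimodal density the shortest 95% interval is the equal-tail one
  set.seed(16)
  df <- 12; loc <- 3; scl <- 0.8
  x <- loc + scl * rt(200000, df)
  hpd <- rumenpls:::hpd_interval(x, 0.95)
  analytic <- loc + scl * qt(c(0.025, 0.975), df)
  width <- diff(analytic)
  expect_lt(abs(hpd[1] - analytic[1]), 0.02 * width)
  expect_lt(abs(hpd[2] - analytic[2]), 0.02 * width)
  if (requireNamespace("coda", quietly = TRUE)) {
    ci <- coda::HPDinterval(coda::as.mcmc(x), 0.95)
    expect_equal(unname(hpd), unname(c(ci[1, 1], ci[1, 2])), tolerance = 1e-6)
  }
})

test_that("relevance threshold is one-third of the phenotypic SD", {
  y <- c(1, 4, 7)                         # sd = 3
  expect_equal(relevant_threshold(y), 1)
  expect_equal(relevant_threshold(5 * y), 5 * relevant_threshold(y))
  expect_warning(r0 <- relevant_threshold(rep(2, 10)), "constant")
  expect_equal(r0, 0)
})

test_that("Geweke Z: oracle agreement, null calibration, gross non-convergence", {
  set.seed(17)
  x <- as.numeric(arima.sim(list(ar = 0.5), 1000))
  expect_equal(geweke_z(x), geweke_oracle(x), tolerance = 1e-6)
  broken <- c(rep(0, 500), rep(10, 500)) + rnorm(1000, 0, 0.01)
  expect_gt(abs(geweke_z(broken)), 3)
  hits <- 0; runs <- 200
  for (i in 1:runs) {
    set.seed(1000 + i)
    hits <- hits + (abs(geweke_z(rnorm(2000))) < 2)
  }
  expect_gte(hits / runs, 0.90)           # ~95% of iid chains look converged
  expect_lte(hits / runs, 0.995)
  expect_error(geweke_z(rnorm(50)), class = "rumenpls_short_chain")
})

test_that("Monte Carlo error: iid limit, autocorrelation inflation, constant chain", {
  set.seed(18)
  x <- rnorm(5000)
  expect_equal(mc_error(x), sd(x) / sqrt(5000), tolerance = 0.2)
  ar <- as.numeric(arima.sim(list(ar = 0.9), 5000))
  expect_gt(mc_error(ar), sd(ar) / sqrt(5000))
  expect_equal(mc_error(rep(3, 500)), 0)
  # oracle agreement for the spectral estimator
  expect_equal(mc_error(x), sqrt(spectral0_oracle(x) / 5000), tolerance = 1e-6)
})

test_that("posterior concentrates on OLS for large n", {
  set.seed(19)
  n <- 200
  x <- rnorm(n)
  y <- 2 + 0.5 * x + rnorm(n)
  fit <- bayes_lm(y ~ x, data.frame(x = x, y = y), chain = reduced_chain(4))
  ols <- coef(lm(y ~ x))
  expect_lt(abs(mean(fit$samples[, "x"]) - ols["x"]),
            mc_error(fit$samples[, "x"]) + 0.01)
})
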