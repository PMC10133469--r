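test_that("NIPALS model structure: unit weights, orthogonal scores, exact fitted values", {
  set.seed(3)
  X <- matrix(rnorm(20 * 10), 20, 10, dimnames = list(NULL, paste0("V", 1:10)))
  y <- rnorm(20)
  m <- fit_pls(X, y, 4)
  expect_equal(colSums(m$W^2), rep(1, 4), tolerance = 1e-10)
  g <- crossprod(m$T)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # prediction with h components equals X_scaled B + intercept = fitted values
  expect_equal(predict(m, X), drop(sweep(sweep(X, 2, m$x_center), 2, m$x_scale, "/")
                                   %*% m$B) + m$y_center, tolerance = 1e-12)
})

test_that("NIPALS coefficients match the Krylov/SVD PLS1 oracle", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(10:30, 1); p <- sample(4:20, 1)
    h <- sample(1:min(5, p, n - 2), 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    m <- fit_pls(X, y, h)
    expect_equal(m$B, pls1_oracle_coef(X, y, h), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("degenerate and boundary fits behave as specified", {
  # with mutually orthogonal predictors, y proportional to one of them is
  # fitted exactly by a single component
  X <- scale(stats::contr.helmert(16)[, 1:4])
  colnames(X) <- paste0("V", 1:4)
  y <- 3 * X[, 2]
  m <- fit_pls(X, y, 1)
  expect_gt(cor(predict(m, X), y)^2, 1 - 1e-10)
  set.seed(4)
  Xr <- matrix(rnorm(15 * 6), 15, 6)
  # h = 0: prediction is the response mean
  m0 <- fit_pls(Xr, rnorm(15), 0)
  expect_equal(unname(predict(m0, Xr)), rep(m0$y_center, 15))
  expect_error(fit_pls(Xr, rnorm(15), 10), class = "rumenpls_input_error")
  expect_error(fit_pls(Xr, rep(1, 15), 1), class = "rumenpls_constant_y")
  expect_error(fit_pls(Xr, factor(rep("a", 15)), 1), class = "rumenpls_input_error")
})

test_that("prediction contract: reproducibility, duplicates, class labels, column checks", {
  d <- make_separable_classes(n_per = 8, p = 6, shift = 5, seed = 2)
  m <- fit_pls(d$X, d$y, 1)
  expect_equal(predict(m, d$X[c(1, 1), ])[1], predict(m, d$X[c(1, 1), ])[2])
  expect_identical(predict(m, d$X, type = "class"), as.character(d$y))
  bad <- d$X[, -1]
  expect_error(predict(m, bad), class = "rumenpls_column_mismatch")
})

test_that("Q2 series: RSS0 identity, signal selects one component, permuted y fails Q2", {
  set.seed(21)
  # rank-one signal: X reflects a single latent factor that drives y
  t_lat <- rnorm(24)
  X <- outer(t_lat, runif(8, 0.5, 2)) + matrix(rnorm(24 * 8, 0, 0.1), 24, 8)
  y <- t_lat + rnorm(24, 0, 0.1)
  q2 <- q2_sequence(X, y, cv = cv_spec(k = 4, reps = 5, seed = 1), h_max = 3)
  expect_equal(attr(q2, "RSS0"), 23 * var(y), tolerance = 1e-10)
  expect_gt(q2$Q2[1], 0.9)
  expect_equal(select_n_components(q2), 1)
  expect_true(all(diff(q2$RSS) <= 1e-10)) # RSS non-increasing in h
  yp <- sample(y)
  q2p <- q2_sequence(X, yp, cv = cv_spec(k = 4, reps = 5, seed = 1), h_max = 2)
  expect_lt(q2p$Q2[1], 0.5)
})

test_that("component selection rule: floor of one, inclusive stop boundary", {
  expect_equal(select_n_components(c(0.41, 0.12, 0.03)), 2)
  expect_equal(select_n_components(c(0.02, 0.5)), 1)    # floor rule
  expect_equal(select_n_components(c(0.0975)), 1)       # boundary is "stop"
  expect_equal(select_n_components(c(0.4, 0.3, 0.2)), 3)
})

test_that("VIP scores: hand case, single-variable normalisation, sum identity", {
  # one-variable model: normalisation forces VIP = 1
  set.seed(5)
  x1 <- matrix(rnorm(20), 20, 1)
  expect_equal(unname(vip_scores(fit_pls(x1, drop(x1) + rnorm(20, 0, .1), 1))), 1)
  # h = 1 with w = (1/sqrt2, 1/sqrt2, 0): VIP_j = sqrt(3 w_j^2); orthogonal
  # unit-variance predictors with y = a + b give that weight vector exactly
  X <- scale(stats::contr.helmert(12)[, 1:3])
  colnames(X) <- c("a", "b", "c")
  y <- X[, 1] + X[, 2]
  m <- fit_pls(X, y, 1)
  expect_equal(unname(vip_scores(m)), sqrt(3 * m$W[, 1]^2), tolerance = 1e-10)
  expect_equal(unname(vip_scores(m)), c(sqrt(1.5), sqrt(1.5), 0), tolerance = 1e-8)
  expect_equal(unname(round(vip_scores(m), 4))[1:2], c(1.2247, 1.2247))
  # sum of squared VIPs equals p for arbitrary fitted models
  for (h in 1:3) {
    Xr <- matrix(rnorm(25 * 7), 25, 7)
    mr <- fit_pls(Xr, rnorm(25), h)
    expect_equal(sum(vip_scores(mr)^2), 7, tolerance = 1e-8)
  }
})

test_that("jackknife intervals match a brute-force loop and separate signal from noise", {
  d <- make_signal_data(n = 24, p = 6, n_signal = 2, noise_sd = 0.05, seed = 8)
  cv <- cv_spec(k = 4, reps = 5, seed = 2)
  jk <- jackknife_coefficients(d$X, d$y, h = 2, cv = cv)
  # brute-force: replicate the refits explicitly and redo the arithmetic
  coefs <- NULL; rep_id <- c()
  enc_y <- d$y
  for (r in seq_len(cv$reps)) {
    folds <- rumenpls:::cv_folds_for_rep(enc_y, list(mode = "regression"), cv, r, 24)
    for (f in sort(unique(folds))) {
      m <- fit_pls(d$X[folds != f, ], d$y[folds != f], 2)
      coefs <- rbind(coefs, m$B / m$x_scale)
      rep_id <- c(rep_id, r)
    }
  }
  oracle <- jackknife_interval_oracle(coefs, rep_id)
  expect_equal(jk$lower, oracle[, 1], tolerance = 1e-10)
  expect_equal(jk$upper, oracle[, 2], tolerance = 1e-10)
  # strong signal variables exclude zero; mostly-noise variables contain it
  expect_true(all(jk$excludes_zero[1:2]))
  noise_hits <- 0
  for (s in 1:10) {
    dn <- make_signal_data(n = 24, p = 6, n_signal = 2, noise_sd = 0.05, seed = 100 + s)
    jkn <- jackknife_coefficients(dn$X, dn$y, h = 2, cv = cv)
    noise_hits <- noise_hits + sum(!jkn$excludes_zero[3:6])
  }
  expect_gte(noise_hits / 40, 0.8)
})

test_that("fold assignment is deterministic and stratified folds balance classes", {
  y <- factor(rep(c("A", "B"), each = 10))
  f1 <- rumenpls:::make_folds(20, 4, labels = y, stratified = TRUE, seed = 3, replicate = 2)
  f2 <- rumenpls:::make_folds(20, 4, labels = y, stratified = TRUE, seed = 3, replicate = 2)
  f3 <- rumenpls:::make_folds(20, 4, labels = y, stratified = TRUE, seed = 3, replicate = 3)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  for (f in 1:4) expect_equal(sum(y[f1 == f] == "A"), sum(y[f1 == f] == "B"))
})

test_that("cross-validation: separable classes are classified perfectly, noiseless regression predicts", {
  d <- make_separable_classes(n_per = 10, p = 8, shift = 8, seed = 3)
  cv <- cv_spec(k = 4, reps = 20, seed = 7)
  res <- cross_validate(d$X, d$y, 1, cv)
  expect_equal(res$criterion, 0)
  set.seed(9)
  # noiseless rank-two response: two components predict almost perfectly
  lat <- matrix(rnorm(24 * 2), 24, 2)
  X <- lat %*% matrix(runif(12, -1, 1), 2, 6) + matrix(rnorm(24 * 6, 0, 0.02), 24, 6)
  y <- drop(lat %*% c(2, -1))
  rg <- cross_validate(X, y, 2, cv_spec(k = 3, reps = 20, seed = 7))
  expect_gt(rg$criterion, 0.99)
  expect_true(all(rg$per_replicate >= 0 & rg$per_replicate <= 1))
})

test_that("iterative selection recovers embedded signal variables", {
  hits <- 0
  for (s in 1:5) {
    d <- make_signal_data(n = 26, p = 30, n_signal = 5, noise_sd = 0.2,
                          seed = 200 + s)
    sel <- iterative_variable_selection(d$X, d$y,
                                        cv = cv_spec(k = 3, reps = 5, seed = 2),
                                        h_max = 3)
    full_cv <- cross_validate(d$X, d$y, sel$h, cv_spec(k = 3, reps = 5, seed = 2))
    ok <- all(d$signal %in% sel$variables) &&
      sel$cv_result$criterion >= full_cv$criterion - 1e-10
    hits <- hits + ok
  }
  expect_gte(hits, 4)
})

test_that("iterative selection terminates immediately when nothing fails", {
  set.seed(31)
  X <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(X %*% c(1, 1, 1)) + rnorm(30, 0, 0.05)
  sel <- iterative_variable_selection(X, y, cv = cv_spec(k = 3, reps = 5, seed = 4))
  expect_identical(sort(sel$variables), c("a", "b", "c"))
  expect_equal(max(sel$trace$iteration), 1)
})
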