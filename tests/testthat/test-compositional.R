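test_that("prevalence filter keeps genera at or above the threshold", {
  # per-genus prevalences 1, .75, .5, .5, .25, 0 on a 4-sample table
  x <- cbind(g1 = c(1, 2, 3, 4), g2 = c(0, 1, 1, 1), g3 = c(0, 0, 2, 2),
             g4 = c(5, 5, 0, 0), g5 = c(0, 0, 0, 7), g6 = c(0, 0, 0, 0))
  rownames(x) <- paste0("s", 1:4)
  expect_identical(colnames(prevalence_filter(x, 0.5)),
                   c("g1", "g2", "g3", "g4"))
  # boundary inclusive: present in exactly threshold fraction is kept
  y <- cbind(a = c(3, 0, 0, 0, 0), b = c(1, 1, 1, 1, 1))
  expect_identical(colnames(prevalence_filter(y, 0.2)), c("a", "b"))
  # threshold 0 is the identity, and filtering is idempotent
  expect_identical(prevalence_filter(x, 0), x)
  f1 <- prevalence_filter(x, 0.5)
  expect_identical(prevalence_filter(f1, 0.5), f1)
  expect_error(prevalence_filter(x[, c("g3", "g5")], 0.9), # max prevalence 0.5
               class = "rumenpls_empty_table")
})

test_that("zero replacement follows the documented Bayesian-multiplicative prior", {
  x <- rbind(s1 = c(2, 3, 5), s2 = c(4, 0, 6))
  colnames(x) <- c("g1", "g2", "g3")
  out <- replace_zeros(x)
  # hand computation under the documented prior: t_j from geometric means of
  # non-zero proportions, s_i = sqrt(N_i), replaced = s_i t_j / (N_i + s_i)
  t_raw <- c(sqrt(0.2 * 0.4), 0.3, sqrt(0.5 * 0.6))
  t_j <- t_raw / sum(t_raw)
  s2_strength <- sqrt(10)
  replaced <- s2_strength * t_j[2] / (10 + s2_strength)
  expect_equal(out["s2", "g2"], replaced, tolerance = 1e-12)
  # non-zero ratios preserved exactly; rows close to 1
  expect_equal(out["s2", "g1"] / out["s2", "g3"], 4 / 6, tolerance = 1e-12)
  expect_equal(unname(rowSums(out)), c(1, 1), tolerance = 1e-12)
  expect_gt(min(out), 0)
  # zero-free input reduces to simple closure
  expect_equal(replace_zeros(x[1, , drop = FALSE]),
               x[1, , drop = FALSE] / 10, tolerance = 1e-12)
  expect_error(replace_zeros(rbind(c(0, 0, 0), c(1, 1, 1))),
               class = "rumenpls_all_zero_sample")
})

test_that("zero replacement preserves non-zero sub-compositions on random tables", {
  set.seed(42)
  for (rep in 1:10) {
    x <- matrix(rpois(8 * 12, 3), 8, 12)
    x <- x[, colSums(x) > 0, drop = FALSE]
    x <- x[rowSums(x) > 0, , drop = FALSE]
    out <- replace_zeros(x)
    expect_equal(rowSums(out), rep(1, nrow(out)), tolerance = 1e-12,
                 ignore_attr = TRUE)
    for (i in seq_len(nrow(x))) {
      nz <- which(x[i, ] > 0)
      if (length(nz) >= 2) {
        expect_equal(out[i, nz] / sum(out[i, nz]),
                     x[i, nz] / sum(x[i, nz]), tolerance = 1e-12)
      }
    }
  }
})

test_that("clr transform matches hand values, zero row sums, scale invariance", {
  expect_equal(unname(clr_transform(rbind(rep(0.25, 4)))[1, ]), rep(0, 4))
  v <- clr_transform(rbind(c(0.5, 0.25, 0.25)))[1, ]
  expect_equal(unname(v), c(log(2) * 2 / 3, -log(2) / 3, -log(2) / 3),
               tolerance = 1e-10)
  expect_equal(unname(round(v, 4)), c(0.4621, -0.2310, -0.2310))
  expect_equal(clr_transform(rbind(c(2, 1, 1))), clr_transform(rbind(c(4, 2, 2))),
               tolerance = 1e-12)
  set.seed(7)
  m <- matrix(rexp(30) + 0.01, 5, 6)
  expect_equal(max(abs(rowSums(clr_transform(m)))), 0, tolerance = 1e-10)
  # per-sample rescaling of counts leaves clr unchanged
  scl <- diag(c(1, 10, 100, 2, 5))
  expect_equal(clr_transform(scl %*% m), clr_transform(m), tolerance = 1e-10)
  expect_error(clr_transform(rbind(c(0.5, 0, 0.5))), class = "rumenpls_nonpositive")
})

test_that("archaea:bacteria log-ratio", {
  tax <- data.frame(genus = c("ma", "mb", "bc", "bd", "ue"),
                    domain = c("Archaea", "Archaea", "Bacteria", "Bacteria",
                               "unclassified"))
  x <- rbind(s1 = c(5, 5, 4, 6, 99), s2 = c(4, 6, 500, 500, 1))
  colnames(x) <- tax$genus
  ab <- archaea_bacteria_logratio(x, tax)
  expect_equal(unname(ab["s1"]), 0)                       # equal totals
  expect_equal(unname(ab["s2"]), log(0.01), tolerance = 1e-12)
  expect_equal(unname(round(ab["s2"], 4)), -4.6052)
  # ratio invariance under per-sample scaling; unclassified genera ignored
  expect_equal(archaea_bacteria_logratio(x * 2, tax), ab)
  x2 <- x; x2["s1", c("ma", "mb")] <- 0
  expect_error(archaea_bacteria_logratio(x2, tax), class = "rumenpls_zero_domain")
})

test_that("prevalence scan selects a sensible threshold and handles trivial grids", {
  ds <- generate_dataset(sim_config(seed = 11))
  labels <- ds$phenotypes$diet
  cv <- cv_spec(k = 4, reps = 5, seed = 3)
  # singleton grid {0}: that threshold is selected and retains everything
  sc0 <- scan_prevalence(ds$counts, labels, grid = 0, cv = cv)
  expect_equal(attr(sc0, "selected"), 0)
  expect_equal(sc0$n_retained[1], ncol(ds$counts))
  sc <- scan_prevalence(ds$counts, labels, grid = c(0, 0.2, 0.5), cv = cv)
  expect_true(all(diff(sc$n_retained) <= 0))  # retained count non-increasing
  expect_true(attr(sc, "selected") %in% sc$threshold)
  sel_row <- which(sc$threshold == attr(sc, "selected"))
  expect_equal(sc$misclassification[sel_row],
               min(sc$misclassification, na.rm = TRUE))
})

test_that("prevalence scan under permuted labels shows no spurious discrimination", {
  ds <- generate_dataset(sim_config(seed = 12))
  set.seed(99)
  perm <- sample(ds$phenotypes$diet)
  sc <- scan_prevalence(ds$counts, perm, grid = c(0.2, 0.5),
                        cv = cv_spec(k = 4, reps = 10, seed = 5))
  # binomial SE of a 26-sample misclassification around 50% is ~9.8 points;
  # no threshold should sit more than 3 SE below 50%
  expect_true(all(sc$misclassification > 50 - 3 * 9.8, na.rm = TRUE))
})
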