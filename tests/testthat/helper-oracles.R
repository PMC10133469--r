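# Independent oracles and small data builders used across the test files.

# Krylov-space closed form for PLS1 (Helland): with S = X'X and s = X'y on
# the centered/scaled data, the h-component coefficient vector is
# B_h = K (K' S K)^-1 K' s with K = [s, S s, ..., S^{h-1} s], orthonormalised
# through svd() for numerical stability. No deflation: a code path fully
# independent of the NIPALS implementation.
pls1_oracle_coef <- function(X, y, h) {
  xc <- colMeans(X)
  xs <- apply(X, 2, stats::sd)
  xs[xs == 0] <- 1
  Xs <- sweep(sweep(X, 2, xc), 2, xs, "/")
  yc <- y - mean(y)
  S <- crossprod(Xs)
  s <- crossprod(Xs, yc)
  K <- matrix(NA_real_, ncol(X), h)
  v <- s
  for (a in seq_len(h)) {
    K[, a] <- v
    v <- S %*% v
  }
  K <- svd(K)$u
  drop(K %*% solve(crossprod(K, S %*% K), crossprod(K, s)))
}

# Plain-loop reimplementation of the jackknife interval arithmetic, given
# the matrix of per-refit coefficients and their replicate ids.
jackknife_interval_oracle <- function(coefs, rep_id) {
  m <- nrow(coefs)
  p <- ncol(coefs)
  out <- matrix(NA_real_, p, 2)
  for (j in seq_len(p)) {
    vs <- c()
    for (r in unique(rep_id)) {
      b <- coefs[rep_id == r, j]
      k <- length(b)
      vs <- c(vs, (k - 1) / k * sum((b - mean(b))^2))
    }
    se <- sqrt(mean(vs))
    bbar <- mean(coefs[, j])
    tcrit <- qt(0.975, m - 1)
    out[j, ] <- c(bbar - tcrit * se, bbar + tcrit * se)
  }
  out
}

# Loop-based Bartlett lag-window spectral density at frequency zero with the
# truncation lag at 4% of the series length; companion oracle for geweke_z
# and mc_error.
spectral0_oracle <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(0)
  L <- max(1, floor(0.04 * n))
  xm <- mean(x)
  g <- numeric(L + 1)
  for (l in 0:L) {
    acc <- 0
    for (t in 1:(n - l)) acc <- acc + (x[t] - xm) * (x[t + l] - xm)
    g[l + 1] <- acc / n
  }
  s0 <- g[1]
  for (l in 1:L) s0 <- s0 + 2 * (1 - l / (L + 1)) * g[l + 1]
  max(s0, 0)
}

geweke_oracle <- function(x) {
  n <- length(x)
  a <- x[seq_len(floor(0.1 * n))]
  b <- x[(n - floor(0.5 * n) + 1):n]
  (mean(a) - mean(b)) /
    sqrt(spectral0_oracle(a) / length(a) + spectral0_oracle(b) / length(b))
}

# Regression instance where the first n_signal variables are noisy replicas
# of a latent factor that drives y (the regime PLS is built for: a block of
# correlated informative predictors among independent noise).
make_signal_data <- function(n, p, n_signal = 5, noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  t_lat <- rnorm(n)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", seq_len(p))))
  X[, seq_len(n_signal)] <- t_lat + matrix(rnorm(n * n_signal, 0, 0.3), n, n_signal)
  y <- 2 * t_lat + rnorm(n, 0, noise_sd)
  list(X = X, y = y, signal = paste0("V", seq_len(n_signal)))
}

# Balanced two-class data, robustly linearly separable: every variable
# carries the class shift (alternating direction), so autoscaling cannot let
# chance noise correlations outvote the signal in small training folds.
make_separable_classes <- function(n_per = 10, p = 8, shift = 4, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p,
              dimnames = list(NULL, paste0("V", seq_len(p))))
  dir <- rep_len(c(1, -1), p)
  X[seq_len(n_per), ] <- X[seq_len(n_per), ] +
    matrix(shift * dir, n_per, p, byrow = TRUE)
  y <- factor(rep(c("A", "B"), each = n_per))
  list(X = X, y = y)
}

# Minimal bayes_lm-like object wrapping externally supplied samples, for
# testing posterior summaries in isolation.
fake_fit <- function(samples, sigma2 = rep(1, nrow(samples))) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1,
                                               dimnames = list(NULL, "b"))
  structure(list(samples = samples, sigma2 = sigma2,
                 coef_names = colnames(samples)),
            class = "bayes_lm")
}
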