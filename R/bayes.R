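# Bayesian linear model with bounded flat priors via single-site Gibbs
# sampling, plus posterior summaries (HPD95, P0, Pr, effect size) and
# chain diagnostics (Geweke Z, Monte Carlo standard error).

#' MCMC chain specification
#'
#' Defaults follow the analysis protocol: 60,000 iterations, 10,000 burn-in,
#' saving 1 of every 10 samples (5,000 saved draws).
#'
#' @param iterations total Gibbs iterations.
#' @param burn_in discarded initial iterations (< iterations).
#' @param thin keep every `thin`-th post-burn-in sample (>= 1).
#' @param seed integer RNG seed.
#' @param bounds half-width of the flat prior box for location parameters.
#' @return object of class `chain_spec`.
#' @export
chain_spec <- function(iterations = 60000, burn_in = 10000, thin = 10,
                       seed = 1, bounds = 1e6) {
  if (burn_in >= iterations)
    stop_named("rumenpls_input_error", "burn_in must be < iterations")
  if (thin < 1) stop_named("rumenpls_input_error", "thin must be >= 1")
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), bounds = bounds),
            class = "chain_spec")
}

# Build a full-rank design matrix with reference (treatment) coding, dropping
# aliased columns with a warning naming them.
build_design <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning(sprintf("dropping aliased column(s): %s", paste(drop, collapse = ", ")))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  list(y = y, X = X)
}

#' Bayesian linear model via Gibbs sampling
#'
#' Fits `formula` on `data` with bounded flat priors on all location
#' parameters and a flat prior on the residual variance within
#' `(0, bounds]`. Location parameters are updated single-site from their full
#' conditional normal truncated to the prior box; the residual variance from
#' its full conditional scaled inverse chi-square. Factors use reference
#' coding (first level zero), so a `dietTMR` coefficient with `GRASS` as first
#' level is the TMR - GRASS difference. Aliased columns are dropped with a
#' warning rather than failing.
#'
#' @param formula model formula (response ~ fixed effects + covariates).
#' @param data data frame with complete cases for all model variables.
#' @param chain a [chain_spec()].
#' @return object of class `bayes_lm`: list with `samples` (saved draws x
#'   coefficients), `sigma2` (saved residual-variance draws), `coef_names`,
#'   `y`, `X`, `chain`.
#' @export
bayes_lm <- function(formula, data, chain = chain_spec()) {
  d <- build_design(formula, data)
  gibbs_sample(d$y, d$X, chain)
}

#' Gibbs sampler for a linear model on an explicit design matrix
#'
#' @param y numeric response vector.
#' @param X full-rank design matrix (samples x parameters).
#' @param chain a [chain_spec()].
#' @return a `bayes_lm` object; see [bayes_lm()].
#' @export
gibbs_sample <- function(y, X, chain = chain_spec()) {
  X <- assert_matrix_like(X, "X")
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_named("rumenpls_input_error", "length(y) != nrow(X)")
  if (anyNA(y) || anyNA(X)) stop_named("rumenpls_input_error", "complete cases required")
  if (n <= p)
    stop_named("rumenpls_estimability",
               "n = %d samples cannot identify %d location parameters", n, p)
  if (qr(X)$rank < p)
    stop_named("rumenpls_estimability", "design matrix is rank deficient")
  b <- chain$bounds
  n_save <- (chain$iterations - chain$burn_in) %/% chain$thin
  samples <- matrix(NA_real_, n_save, p)
  sigma2_save <- numeric(n_save)
  # when the model has an intercept, covariate columns are centered during
  # sampling (vastly better single-site mixing); saved draws are mapped back
  # to the original parameterisation, which leaves all slopes untouched
  const <- apply(X, 2, function(col) all(col == col[1]))
  has_const <- any(const)
  cmeans <- colMeans(X)
  cmeans[const | !has_const] <- 0
  ic <- if (has_const) which(const)[1] else NA_integer_
  Xw <- sweep(X, 2, cmeans)
  xtx <- colSums(Xw^2)
  with_seed(chain$seed, {
    beta <- qr.solve(Xw, y)
    beta <- pmin(pmax(beta, -b), b)
    r <- y - drop(Xw %*% beta)
    sigma2 <- max(sum(r^2) / max(n - p, 1), 1e-12)
    idx <- 0
    for (it in seq_len(chain$iterations)) {
      for (j in seq_len(p)) {
        xj <- Xw[, j]
        r <- r + xj * beta[j]
        mj <- sum(xj * r) / xtx[j]
        sdj <- sqrt(sigma2 / xtx[j])
        bj <- mj + sdj * stats::rnorm(1)
        if (abs(bj) > b) { # truncation to the prior box, rarely active
          plo <- stats::pnorm(-b, mj, sdj); phi <- stats::pnorm(b, mj, sdj)
          bj <- stats::qnorm(plo + stats::runif(1) * (phi - plo), mj, sdj)
          bj <- pmin(pmax(bj, -b), b)
        }
        beta[j] <- bj
        r <- r - xj * bj
      }
      ssr <- sum(r^2)
      sigma2 <- ssr / stats::rchisq(1, df = max(n - 2, 1))
      sigma2 <- min(max(sigma2, 1e-300), b)
      if (it > chain$burn_in && (it - chain$burn_in) %% chain$thin == 0) {
        idx <- idx + 1
        bo <- beta
        if (has_const)
          bo[ic] <- beta[ic] - sum(cmeans * beta) / Xw[1, ic]
        samples[idx, ] <- bo
        sigma2_save[idx] <- sigma2
      }
    }
  })
  colnames(samples) <- colnames(X)
  structure(list(samples = samples, sigma2 = sigma2_save,
                 coef_names = colnames(X), y = y, X = X, chain = chain),
            class = "bayes_lm")
}

#' Relevance threshold from the phenotypic standard deviation
#'
#' `r = sd(y) / 3`, one-third of the raw response's sample standard
#' deviation; the minimum difference considered biologically relevant.
#'
#' @param y numeric response vector, `n >= 2`.
#' @return non-negative scalar; 0 with a warning for a constant response.
#' @export
relevant_threshold <- function(y) {
  if (length(y) < 2) stop_named("rumenpls_input_error", "need n >= 2")
  s <- stats::sd(y)
  if (s == 0) {
    warning("constant response; relevance threshold is 0")
    return(0)
  }
  s / 3
}

# Shortest interval containing prob mass of the sampled posterior.
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1, ceiling(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

#' Summarise a posterior contrast
#'
#' Computes the posterior mean and median, the shortest (highest posterior
#' density) 95% interval, `P0` (the probability the contrast exceeds 0 in the
#' direction of its posterior mean), `Pr` (the analogous probability of
#' exceeding the relevance threshold `r`), the effect size (posterior median
#' of contrast / residual SD), and chain diagnostics.
#'
#' @param fit a [bayes_lm()] object.
#' @param contrast a coefficient name, or a numeric vector of length
#'   `ncol(samples)` defining a linear combination of coefficients.
#' @param r non-negative relevance threshold (default 0 makes `Pr = P0`).
#' @param label optional row label.
#' @return one-row data frame: `term`, `mean`, `median`, `hpd_low`,
#'   `hpd_high`, `p0`, `pr`, `r`, `effect_size`, `geweke_z`, `mc_se`.
#' @export
posterior_summary <- function(fit, contrast, r = 0, label = NULL) {
  if (!inherits(fit, "bayes_lm")) stop_named("rumenpls_input_error", "fit must be a bayes_lm")
  if (r < 0) stop_named("rumenpls_input_error", "r must be >= 0")
  if (is.character(contrast)) {
    if (!contrast %in% fit$coef_names)
      stop_named("rumenpls_input_error", "unknown coefficient '%s'", contrast)
    s <- fit$samples[, contrast]
    label <- label %||% contrast
  } else {
    if (length(contrast) != ncol(fit$samples))
      stop_named("rumenpls_input_error", "contrast vector length mismatch")
    s <- drop(fit$samples %*% contrast)
    label <- label %||% "contrast"
  }
  if (length(s) == 0) stop_named("rumenpls_input_error", "empty chain")
  m <- mean(s)
  pos <- m >= 0
  p0 <- if (pos) mean(s > 0) else mean(s < 0)
  pr <- if (pos) mean(s > r) else mean(s < -r)
  hpd <- hpd_interval(s, 0.95)
  es <- stats::median(s / sqrt(fit$sigma2))
  data.frame(term = label, mean = m, median = stats::median(s),
             hpd_low = hpd[1], hpd_high = hpd[2], p0 = p0, pr = pr, r = r,
             effect_size = es,
             geweke_z = geweke_z(s), mc_se = mc_error(s),
             row.names = NULL)
}

# Bartlett lag-window estimate of the spectral density at frequency zero,
# with the truncation lag at 4% of the series length. Returns the long-run
# variance; the variance of the mean is spectral0(x)/length(x).
spectral0 <- function(x) {
  n <- length(x)
  v <- stats::var(x)
  if (v == 0) return(0)
  L <- max(1, floor(0.04 * n))
  ac <- stats::acf(x, lag.max = L, type = "covariance", plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  s0 <- ac[1] + 2 * sum((1 - seq_len(L) / (L + 1)) * ac[-1])
  max(s0, 0)
}

#' Geweke convergence Z score
#'
#' Compares the means of the first 10% and last 50% of the chain,
#' standardised by spectral-density estimates of each window's variance of
#' the mean (Bartlett lag window truncated at 4% of the window length).
#' `|Z| < 2` is consistent with convergence.
#'
#' @param x numeric chain of saved samples (>= 100).
#' @return scalar Z statistic.
#' @export
geweke_z <- function(x) {
  n <- length(x)
  if (n < 100) stop_named("rumenpls_short_chain", "need >= 100 samples, got %d", n)
  a <- x[seq_len(floor(0.1 * n))]
  b <- x[(n - floor(0.5 * n) + 1):n]
  va <- spectral0(a) / length(a)
  vb <- spectral0(b) / length(b)
  if (va + vb == 0) return(0)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

#' Monte Carlo standard error of a chain mean
#'
#' Time-series standard error from the spectral density at frequency zero
#' (Bartlett lag window truncated at 4% of the chain length); accounts for
#' autocorrelation, reducing to `sd/sqrt(n)` for an independent chain.
#'
#' @param x numeric chain of saved samples (>= 100).
#' @return non-negative scalar standard error.
#' @export
mc_error <- function(x) {
  n <- length(x)
  if (n < 100) stop_named("rumenpls_short_chain", "need >= 100 samples, got %d", n)
  sqrt(spectral0(x) / n)
}
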