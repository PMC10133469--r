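# NIPALS PLS1 regression and two-class discriminant PLS (DA-PLS), with
# Q2-based dimension selection, VIP scores, jackknife coefficient intervals,
# repeated cross-validation and permutation validation.

#' Cross-validation specification
#'
#' @param k number of folds (>= 2).
#' @param reps number of replicates (>= 1).
#' @param stratified stratify folds by class in discriminant mode.
#' @param seed integer seed governing fold assignment and permutations.
#' @param permute one of `"none"`, `"test_labels"` (shuffle only test-set
#'   responses before scoring, the validation-stage permutation) or
#'   `"full_labels"` (shuffle responses before splitting).
#' @return object of class `cv_spec`.
#' @export
cv_spec <- function(k = 4, reps = 20, stratified = TRUE, seed = 1,
                    permute = c("none", "test_labels", "full_labels")) {
  permute <- match.arg(permute)
  if (k < 2) stop_named("rumenpls_input_error", "k must be >= 2")
  if (reps < 1) stop_named("rumenpls_input_error", "reps must be >= 1")
  structure(list(k = as.integer(k), reps = as.integer(reps),
                 stratified = isTRUE(stratified), seed = as.integer(seed),
                 permute = permute),
            class = "cv_spec")
}

# Deterministic fold assignment: depends only on (seed, replicate, n, labels).
# Stratified assignment shuffles indices within each class and deals folds
# cyclically; ties in stratification are broken by sample order.
make_folds <- function(n, k, labels = NULL, stratified = FALSE, seed = 1,
                       replicate = 1) {
  if (k > n) stop_named("rumenpls_input_error", "more folds than samples")
  folds <- integer(n)
  with_seed(derive_seed(seed, replicate, n, k), {
    if (stratified && !is.null(labels)) {
      for (lv in unique(as.character(labels))) {
        idx <- which(as.character(labels) == lv)
        idx <- idx[sample.int(length(idx))]
        folds[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      folds[sample.int(n)] <- rep_len(seq_len(k), n)
    }
  })
  folds
}

encode_response <- function(y) {
  if (is.numeric(y)) {
    return(list(y = as.numeric(y), mode = "regression", levels = NULL))
  }
  y <- as.factor(y)
  lv <- levels(droplevels(y))
  if (length(lv) != 2)
    stop_named("rumenpls_input_error",
               "discriminant mode requires exactly 2 classes, got %d", length(lv))
  list(y = ifelse(as.character(y) == lv[2], 1, -1), mode = "discriminant",
       levels = lv)
}

#' Fit a PLS1 / two-class DA-PLS model by NIPALS
#'
#' Predictors are centered and scaled to unit variance (constant columns are
#' scaled by 1); the response is centered. For a factor response the model is
#' a two-class discriminant PLS: PLS1 on a -1/+1 dummy with class assignment
#' by prediction sign. NIPALS with X-deflation; weight vectors have unit norm
#' and successive score vectors are orthogonal.
#'
#' @param X numeric predictor matrix, samples x variables, no missing values.
#' @param y numeric response, or a two-level factor for discriminant mode.
#' @param h number of latent components, `0 <= h <= min(n - 1, p)`.
#' @return object of class `pls_model` with weights `W`, x-loadings `P`,
#'   y-loadings `q`, scores `T`, coefficients `B` (on the centered/scaled
#'   scale), centering/scaling vectors and the mode flag.
#' @export
fit_pls <- function(X, y, h) {
  X <- assert_matrix_like(X, "X")
  if (anyNA(X)) stop_named("rumenpls_input_error", "X contains missing values")
  enc <- encode_response(y)
  yv <- enc$y
  n <- nrow(X); p <- ncol(X)
  if (length(yv) != n) stop_named("rumenpls_input_error", "length(y) != nrow(X)")
  if (stats::var(yv) == 0)
    stop_named("rumenpls_constant_y",
               if (enc$mode == "discriminant") "single-class labels" else "constant response")
  if (h > min(n - 1, p))
    stop_named("rumenpls_input_error", "h = %d exceeds min(n - 1, p) = %d",
               h, min(n - 1, p))
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[x_scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  y_center <- mean(yv)
  Xd <- Xs
  yd <- yv - y_center
  W <- P <- matrix(0, p, h)
  Tm <- matrix(0, n, h)
  qv <- tt <- numeric(h)
  for (a in seq_len(h)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop_named("rumenpls_degenerate",
                 "residual X carries no covariance with y at component %d", a)
    w <- w / nw
    t <- Xd %*% w
    tt[a] <- sum(t^2)
    pl <- crossprod(Xd, t) / tt[a]
    qv[a] <- sum(yd * t) / tt[a]
    Xd <- Xd - tcrossprod(t, pl)
    yd <- yd - t * qv[a]
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t
  }
  # coefficients per cumulative number of components: B_h = W_h (P_h' W_h)^-1 q_h
  Bcum <- matrix(0, p, max(h, 1))
  if (h > 0) {
    for (a in seq_len(h)) {
      Wa <- W[, seq_len(a), drop = FALSE]
      Pa <- P[, seq_len(a), drop = FALSE]
      Bcum[, a] <- Wa %*% solve(crossprod(Pa, Wa), qv[seq_len(a)])
    }
  }
  structure(list(
    n_components = h, W = W, P = P, q = qv, T = Tm, tt = tt,
    B = if (h > 0) Bcum[, h] else rep(0, p), B_cum = Bcum,
    x_center = x_center, x_scale = x_scale, y_center = y_center,
    mode = enc$mode, levels = enc$levels,
    var_names = colnames(X)
  ), class = "pls_model")
}

#' Predict from a fitted PLS model
#'
#' Applies the stored centering/scaling, then the linear predictor with the
#' model's `h` components. In discriminant mode `type = "class"` returns hard
#' labels by prediction sign.
#'
#' @param object a [fit_pls()] model.
#' @param newdata matrix with the training column set (checked by name when
#'   names are present).
#' @param type `"response"` for the numeric predictor, `"class"` for labels.
#' @param ... unused.
#' @return numeric vector, or character labels for `type = "class"`.
#' @export
predict.pls_model <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  newdata <- assert_matrix_like(newdata, "newdata")
  if (!is.null(object$var_names) && !is.null(colnames(newdata))) {
    if (!identical(colnames(newdata), object$var_names)) {
      missing <- setdiff(object$var_names, colnames(newdata))
      extra <- setdiff(colnames(newdata), object$var_names)
      if (length(missing) || length(extra))
        stop_named("rumenpls_column_mismatch",
                   "column mismatch; missing: [%s]; extra: [%s]",
                   paste(missing, collapse = ", "), paste(extra, collapse = ", "))
      newdata <- newdata[, object$var_names, drop = FALSE]
    }
  }
  if (ncol(newdata) != length(object$x_center))
    stop_named("rumenpls_column_mismatch", "wrong number of columns")
  Xs <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
  yhat <- drop(Xs %*% object$B) + object$y_center
  if (type == "class") {
    if (object$mode != "discriminant")
      stop_named("rumenpls_input_error", "class prediction requires discriminant mode")
    return(object$levels[(yhat > 0) + 1L])
  }
  yhat
}

# Predictions for every cumulative component count 1..h (n x h matrix);
# used so CV loops fit once per fold.
predict_components <- function(object, newdata) {
  newdata <- assert_matrix_like(newdata, "newdata")
  Xs <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, "/")
  Xs %*% object$B_cum + object$y_center
}

#' RSS/PRESS/Q2 sequence over latent dimensions
#'
#' `RSS_h` is the residual sum of squares of the full-data fit with `h`
#' components (`RSS_0 = sum((y - mean(y))^2)`). `PRESS_h` sums squared
#' test-fold residuals within each replicate and averages across replicates.
#' `Q2_h = 1 - PRESS_h / RSS_{h-1}`. Folds are seeded and stratified by class
#' in discriminant mode; a fold whose training set is single-class is
#' resampled (up to 100 retries).
#'
#' @param X predictor matrix.
#' @param y response (numeric, or two-level factor for discriminant mode).
#' @param cv a [cv_spec()].
#' @param h_max maximum number of components to evaluate (>= 1).
#' @return object of class `q2_series`: data frame with `h`, `RSS`, `PRESS`,
#'   `Q2`; `RSS0` and the cv spec as attributes.
#' @export
q2_sequence <- function(X, y, cv = cv_spec(), h_max = 3) {
  X <- assert_matrix_like(X, "X")
  if (h_max < 1) stop_named("rumenpls_input_error", "h_max must be >= 1")
  h_max <- max(1, min(h_max, nrow(X) - 2, ncol(X))) # leave room in training folds
  enc <- encode_response(y)
  yv <- enc$y
  n <- nrow(X)
  rss0 <- sum((yv - mean(yv))^2)
  full <- fit_pls(X, y, h_max)
  pred_full <- predict_components(full, X)
  rss <- colSums((yv - pred_full)^2)
  press_rep <- matrix(0, cv$reps, h_max)
  for (r in seq_len(cv$reps)) {
    folds <- cv_folds_for_rep(yv, enc, cv, r, n)
    for (f in sort(unique(folds))) {
      test <- folds == f
      m <- fit_pls(X[!test, , drop = FALSE],
                   if (enc$mode == "discriminant") factor(enc$levels[(yv[!test] > 0) + 1L], levels = enc$levels) else yv[!test],
                   h_max)
      ph <- predict_components(m, X[test, , drop = FALSE])
      press_rep[r, ] <- press_rep[r, ] + colSums((yv[test] - ph)^2)
    }
  }
  press <- colMeans(press_rep)
  q2 <- 1 - press / c(rss0, rss[-h_max])
  structure(data.frame(h = seq_len(h_max), RSS = rss, PRESS = press, Q2 = q2),
            RSS0 = rss0, cv = cv, class = c("q2_series", "data.frame"))
}

# Fold assignment with a single-class-training guard in discriminant mode.
cv_folds_for_rep <- function(yv, enc, cv, replicate, n) {
  labels <- if (enc$mode == "discriminant") enc$levels[(yv > 0) + 1L] else NULL
  for (try in 0:100) {
    folds <- make_folds(n, cv$k, labels = labels,
                        stratified = cv$stratified && !is.null(labels),
                        seed = derive_seed(cv$seed, try), replicate = replicate)
    if (is.null(labels)) return(folds)
    ok <- all(vapply(sort(unique(folds)), function(f)
      length(unique(labels[folds != f])) == 2, logical(1)))
    if (ok) return(folds)
  }
  stop_named("rumenpls_fold_error", "could not build folds with both classes in every training set")
}

#' Number of components from a Q2 series
#'
#' Returns the largest `h*` such that `Q2_h > threshold` for every
#' `h <= h*`; a dimension is not added once `Q2_h <= threshold`. At least one
#' component is always retained.
#'
#' @param q2 a [q2_sequence()] result (or a bare numeric Q2 vector).
#' @param threshold stopping threshold (default 0.0975).
#' @return integer number of components, >= 1.
#' @export
select_n_components <- function(q2, threshold = 0.0975) {
  v <- if (inherits(q2, "data.frame")) q2$Q2 else as.numeric(q2)
  if (length(v) == 0) stop_named("rumenpls_input_error", "empty Q2 series")
  below <- which(v <= threshold)
  if (length(below) == 0) return(length(v))
  max(1L, below[1] - 1L)
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_h SSY_h w_jh^2 / sum_h SSY_h)` with
#' `SSY_h = q_h^2 * t_h' t_h` (weights already have unit norm). The scores
#' satisfy `sum_j VIP_j^2 = p`.
#'
#' @param model a fitted [fit_pls()] model with `h >= 1`.
#' @return named numeric vector of VIP scores.
#' @export
vip_scores <- function(model) {
  if (!inherits(model, "pls_model") || model$n_components < 1)
    stop_named("rumenpls_input_error", "need a fitted model with >= 1 component")
  ssy <- model$q^2 * model$tt
  p <- nrow(model$W)
  vip <- sqrt(p * drop(model$W^2 %*% ssy) / sum(ssy))
  names(vip) <- model$var_names
  vip
}

#' Jackknife intervals for PLS regression coefficients
#'
#' Refits the `h`-component model on every leave-fold-out training set across
#' all CV replicates (`m = k * reps` refits), collecting coefficients on the
#' raw predictor scale. The jackknife variance is the Tukey delete-fold form
#' `(k - 1)/k * sum_folds (b - mean_b)^2` computed within each replicate and
#' averaged over replicates; intervals are
#' `mean(b) +/- t(0.975, m - 1) * sqrt(var_jack)`.
#'
#' @param X predictor matrix.
#' @param y response.
#' @param h number of components.
#' @param cv a [cv_spec()].
#' @return data frame with `variable`, `coef` (mean over refits), `se`,
#'   `lower`, `upper`, `excludes_zero`.
#' @export
jackknife_coefficients <- function(X, y, h, cv = cv_spec()) {
  X <- assert_matrix_like(X, "X")
  enc <- encode_response(y)
  yv <- enc$y
  n <- nrow(X); p <- ncol(X)
  m <- cv$k * cv$reps
  coefs <- matrix(NA_real_, m, p)
  rep_id <- integer(m)
  row <- 0
  for (r in seq_len(cv$reps)) {
    folds <- cv_folds_for_rep(yv, enc, cv, r, n)
    for (f in sort(unique(folds))) {
      keep <- folds != f
      mod <- fit_pls(X[keep, , drop = FALSE],
                     if (enc$mode == "discriminant") factor(enc$levels[(yv[keep] > 0) + 1L], levels = enc$levels) else yv[keep],
                     h)
      row <- row + 1
      rep_id[row] <- r
      coefs[row, ] <- mod$B / mod$x_scale # raw-predictor scale
    }
  }
  coefs <- coefs[seq_len(row), , drop = FALSE]
  rep_id <- rep_id[seq_len(row)]
  bbar <- colMeans(coefs)
  var_by_rep <- vapply(seq_len(p), function(j) {
    mean(vapply(unique(rep_id), function(r) {
      b <- coefs[rep_id == r, j]
      k <- length(b)
      (k - 1) / k * sum((b - mean(b))^2)
    }, numeric(1)))
  }, numeric(1))
  se <- sqrt(var_by_rep)
  tcrit <- stats::qt(0.975, row - 1)
  lower <- bbar - tcrit * se
  upper <- bbar + tcrit * se
  data.frame(variable = colnames(X) %||% paste0("V", seq_len(p)),
             coef = bbar, se = se, lower = lower, upper = upper,
             excludes_zero = lower > 0 | upper < 0,
             row.names = NULL)
}

#' Repeated cross-validation of a fixed PLS model
#'
#' Refits within each training fold on the fixed variable set and number of
#' components. Discriminant mode reports the misclassification percentage;
#' regression mode reports predictive ability, the squared Pearson
#' correlation between test-fold predictions and observations. Both are
#' averaged over folds then over replicates, with the standard deviation
#' across replicates. `permute = "test_labels"` shuffles only the test-set
#' responses before scoring; `permute = "full_labels"` shuffles the response
#' before splitting.
#'
#' @param X predictor matrix (already restricted to the variable set).
#' @param y response.
#' @param h number of components.
#' @param cv a [cv_spec()].
#' @return object of class `cv_result`: list with `criterion` (mean),
#'   `sd` (across replicates), `per_replicate`, `mode`, `cv`.
#' @export
cross_validate <- function(X, y, h, cv = cv_spec()) {
  X <- assert_matrix_like(X, "X")
  enc <- encode_response(y)
  yv <- enc$y
  n <- nrow(X)
  per_rep <- numeric(cv$reps)
  for (r in seq_len(cv$reps)) {
    yr <- yv
    if (cv$permute == "full_labels")
      yr <- with_seed(derive_seed(cv$seed, 7717, r), sample(yv))
    folds <- cv_folds_for_rep(yr, enc, cv, r, n)
    fold_scores <- numeric(0)
    for (f in sort(unique(folds))) {
      test <- folds == f
      mod <- fit_pls(X[!test, , drop = FALSE],
                     if (enc$mode == "discriminant") factor(enc$levels[(yr[!test] > 0) + 1L], levels = enc$levels) else yr[!test],
                     h)
      pred <- drop(predict_components(mod, X[test, , drop = FALSE])[, max(h, 1)])
      if (h == 0) pred <- rep(mod$y_center, sum(test))
      obs <- yr[test]
      if (cv$permute == "test_labels")
        obs <- with_seed(derive_seed(cv$seed, 7867, r, f), sample(obs))
      if (enc$mode == "discriminant") {
        fold_scores <- c(fold_scores, 100 * mean(sign(pred) != sign(obs)))
      } else {
        sc <- if (stats::sd(pred) == 0 || stats::sd(obs) == 0) 0
              else stats::cor(pred, obs)^2
        fold_scores <- c(fold_scores, sc)
      }
    }
    per_rep[r] <- mean(fold_scores)
  }
  structure(list(criterion = mean(per_rep), sd = stats::sd(per_rep),
                 per_replicate = per_rep, mode = enc$mode, h = h, cv = cv),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  what <- if (x$mode == "discriminant") "misclassification (%)" else "predictive ability (R2)"
  cat(sprintf("%s: %.3f +/- %.3f (%d x %d-fold CV, h = %d)\n",
              what, x$criterion, x$sd, x$cv$reps, x$cv$k, x$h))
  invisible(x)
}

#' Iterative VIP/jackknife variable selection
#'
#' Repeats: (1) choose the number of components by [q2_sequence()] /
#' [select_n_components()]; (2) fit and compute VIP and jackknife intervals;
#' (3) drop every variable failing `VIP > vip_threshold` or whose jackknife
#' interval contains zero; (4) re-evaluate the repeated-CV criterion
#' (misclassification % in discriminant mode, minimised; predictive ability
#' in regression mode, maximised) on the same fold seeds. Stops when the
#' criterion stops strictly improving or no variable fails, and returns the
#' best-criterion iteration's variable set; ties on the criterion go to the
#' most parsimonious iteration.
#'
#' @param X predictor matrix with column names.
#' @param y response.
#' @param cv a [cv_spec()].
#' @param vip_threshold VIP cut-off (default 0.8).
#' @param q2_threshold Q2 stopping threshold (default 0.0975).
#' @param h_max maximum components considered per iteration.
#' @param max_iter iteration cap.
#' @return object of class `selection_result`: list with `variables`
#'   (retained ids), `h`, `vip`, `jackknife`, `cv_result`, `trace`
#'   (per-iteration data frame), `emptied` flag.
#' @export
iterative_variable_selection <- function(X, y, cv = cv_spec(),
                                         vip_threshold = 0.8,
                                         q2_threshold = 0.0975,
                                         h_max = 3, max_iter = 25) {
  X <- assert_matrix_like(X, "X")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (ncol(X) < 2) stop_named("rumenpls_input_error", "need >= 2 variables")
  enc <- encode_response(y)
  minimise <- enc$mode == "discriminant"
  vars <- colnames(X)
  trace <- list()
  iters <- list()
  emptied <- FALSE
  for (it in seq_len(max_iter)) {
    Xi <- X[, vars, drop = FALSE]
    q2 <- q2_sequence(Xi, y, cv = cv, h_max = min(h_max, length(vars)))
    h <- select_n_components(q2, q2_threshold)
    model <- fit_pls(Xi, y, h)
    vip <- vip_scores(model)
    jk <- jackknife_coefficients(Xi, y, h, cv)
    cvr <- cross_validate(Xi, y, h, cv)
    iters[[it]] <- list(variables = vars, h = h, vip = vip, jackknife = jk,
                        cv_result = cvr)
    failing <- vars[vip <= vip_threshold | !jk$excludes_zero]
    trace[[it]] <- data.frame(iteration = it, n_variables = length(vars),
                              h = h, criterion = cvr$criterion,
                              n_removed = length(failing))
    if (it > 1) {
      prev <- iters[[it - 1]]$cv_result$criterion
      improved <- if (minimise) cvr$criterion < prev else cvr$criterion > prev
      if (!improved) break
    }
    if (length(failing) == 0) break
    remaining <- setdiff(vars, failing)
    if (length(remaining) < 2) {
      emptied <- TRUE
      warning("variable selection would empty the set; keeping previous iteration")
      break
    }
    vars <- remaining
  }
  crit <- vapply(iters, function(z) z$cv_result$criterion, numeric(1))
  opt <- if (minimise) min(crit) else max(crit)
  # ties on the criterion go to the most parsimonious iteration
  best <- max(which(crit == opt))
  out <- iters[[best]]
  structure(list(variables = out$variables, h = out$h, vip = out$vip,
                 jackknife = out$jackknife, cv_result = out$cv_result,
                 trace = do.call(rbind, trace), emptied = emptied,
                 mode = enc$mode),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("PLS variable selection (%s mode): %d variables, h = %d\n",
              x$mode, length(x$variables), x$h))
  print(x$cv_result)
  invisible(x)
}
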