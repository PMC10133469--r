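# Compositional preprocessing of genus-level count tables: prevalence
# filtering, Bayesian-multiplicative zero replacement, centered log-ratio
# transform and the archaea:bacteria log-ratio.

#' Filter genera by prevalence
#'
#' Retains the genera observed (count > 0) in at least `min_prevalence` of
#' samples. The boundary is inclusive: a genus present in exactly the
#' threshold fraction of samples is kept, matching the rule of removing
#' genera present in *less than* the threshold.
#'
#' @param counts non-negative integer matrix, samples x genera, with genus
#'   names as column names.
#' @param min_prevalence fraction of samples in `[0, 1]`.
#' @return the filtered count matrix; sample set and column order unchanged.
#' @examples
#' x <- matrix(c(5, 0, 0, 3, 2, 0), nrow = 3,
#'             dimnames = list(paste0("s", 1:3), c("gA", "gB")))
#' prevalence_filter(x, 0.5)
#' @export
prevalence_filter <- function(counts, min_prevalence) {
  counts <- assert_matrix_like(counts, "counts")
  if (any(counts < 0)) stop_named("rumenpls_input_error", "counts must be non-negative")
  if (length(min_prevalence) != 1 || min_prevalence < 0 || min_prevalence > 1)
    stop_named("rumenpls_input_error", "min_prevalence must be a fraction in [0, 1]")
  prev <- colMeans(counts > 0)
  keep <- prev >= min_prevalence
  if (!any(keep))
    stop_named("rumenpls_empty_table",
               "no genus reaches prevalence %.2f; lower the threshold", min_prevalence)
  counts[, keep, drop = FALSE]
}

#' Bayesian-multiplicative replacement of count zeros
#'
#' Geometric Bayesian-multiplicative (GBM) imputation. For sample `i` with
#' total count `N_i`, each zero cell of genus `j` receives the
#' posterior-expected proportion under a Dirichlet prior with strength
#' `s_i = sqrt(N_i)` and location `t_j`, the geometric mean of genus `j`'s
#' non-zero observed proportions across samples (renormalised to sum to 1):
#' `replaced_ij = s_i * t_j / (N_i + s_i)`. Non-zero cells are multiplicatively
#' shrunk by `1 - sum(replaced in row i)` so each row closes to 1, which
#' preserves all pairwise ratios among originally non-zero parts exactly.
#'
#' @param counts non-negative count matrix, samples x genera; every sample
#'   and every genus must have at least one non-zero entry (guaranteed after
#'   [prevalence_filter()]).
#' @return strictly positive matrix of proportions with unit row sums.
#' @export
replace_zeros <- function(counts) {
  counts <- assert_matrix_like(counts, "counts")
  if (any(counts < 0)) stop_named("rumenpls_input_error", "counts must be non-negative")
  n_i <- rowSums(counts)
  if (any(n_i == 0)) {
    bad <- rownames(counts)[n_i == 0] %||% which(n_i == 0)
    stop_named("rumenpls_all_zero_sample", "all-zero sample(s): %s",
               paste(bad, collapse = ", "))
  }
  if (any(colSums(counts) == 0))
    stop_named("rumenpls_all_zero_genus",
               "some genera have no non-zero sample; run prevalence_filter first")
  prop <- counts / n_i
  # prior location: geometric mean of each genus's non-zero proportions
  t_j <- apply(prop, 2, function(p) exp(mean(log(p[p > 0]))))
  t_j <- t_j / sum(t_j)
  s_i <- sqrt(n_i)
  post0 <- outer(s_i / (n_i + s_i), t_j) # replacement value for zero cells
  out <- prop
  for (i in seq_len(nrow(counts))) {
    z <- counts[i, ] == 0
    if (!any(z)) next
    out[i, z] <- post0[i, z]
    out[i, !z] <- prop[i, !z] * (1 - sum(post0[i, z]))
  }
  out
}

#' Centered log-ratio transform
#'
#' Maps each strictly positive composition row to
#' `clr_ij = ln(p_ij) - mean_k ln(p_ik)`. Rows of the result sum to zero and
#' the transform is invariant to per-row scaling of the input.
#'
#' @param comp strictly positive matrix, samples x genera (proportions or any
#'   positive equivalent; zeros must be replaced first).
#' @return real matrix of clr coordinates with zero row sums.
#' @export
clr_transform <- function(comp) {
  comp <- assert_matrix_like(comp, "comp")
  if (any(comp <= 0))
    stop_named("rumenpls_nonpositive", "clr requires strictly positive entries; replace zeros first")
  lg <- log(comp)
  lg - rowMeans(lg)
}

#' Archaea:bacteria natural log-ratio
#'
#' Per-sample `ln(total archaeal count / total bacterial count)`. Genera not
#' classified to either domain are excluded from both sums; "unclassified
#' Archaea"/"unclassified Bacteria" style genera count toward their domain via
#' the taxonomy table.
#'
#' @param counts count matrix, samples x genera.
#' @param taxonomy data frame with columns `genus` and `domain`
#'   (`"Archaea"`/`"Bacteria"`; other values are excluded).
#' @return named numeric vector, one log-ratio per sample.
#' @export
archaea_bacteria_logratio <- function(counts, taxonomy) {
  counts <- assert_matrix_like(counts, "counts")
  if (is.null(colnames(counts)))
    stop_named("rumenpls_input_error", "counts must have genus column names")
  if (!all(c("genus", "domain") %in% names(taxonomy)))
    stop_named("rumenpls_input_error", "taxonomy needs columns 'genus' and 'domain'")
  dom <- taxonomy$domain[match(colnames(counts), taxonomy$genus)]
  arch <- which(!is.na(dom) & dom == "Archaea")
  bact <- which(!is.na(dom) & dom == "Bacteria")
  a <- rowSums(counts[, arch, drop = FALSE])
  b <- rowSums(counts[, bact, drop = FALSE])
  bad <- a == 0 | b == 0
  if (any(bad)) {
    ids <- rownames(counts)[bad] %||% which(bad)
    stop_named("rumenpls_zero_domain",
               "zero archaeal or bacterial total in sample(s): %s",
               paste(ids, collapse = ", "))
  }
  structure(log(a / b), names = rownames(counts))
}

#' Scan prevalence thresholds for diet discrimination
#'
#' For each threshold in `grid`: filters the count table, replaces zeros,
#' clr-transforms, fits a one-component discriminant PLS and records its
#' repeated-CV misclassification. The selected threshold minimises the
#' misclassification (ties broken toward the smallest threshold). A threshold
#' that empties the table is recorded as inapplicable (`NA`), not fatal.
#'
#' @param counts count matrix, samples x genera.
#' @param labels two-level factor (diet) aligned with rows of `counts`.
#' @param grid numeric vector of prevalence thresholds in `[0, 1]`.
#' @param cv a [cv_spec()] controlling the repeated cross-validation.
#' @return object of class `prevalence_scan`: data frame of `threshold`,
#'   `n_retained`, `misclassification`, plus `selected` attribute.
#' @export
scan_prevalence <- function(counts, labels, grid, cv = cv_spec(k = 4, reps = 20)) {
  counts <- assert_matrix_like(counts, "counts")
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2 || min(table(labels)) < 2)
    stop_named("rumenpls_input_error", "need two classes with >= 2 samples each")
  if (length(grid) == 0) stop_named("rumenpls_input_error", "grid must be non-empty")
  grid <- sort(unique(grid))
  res <- data.frame(threshold = grid, n_retained = NA_integer_,
                    misclassification = NA_real_)
  for (g in seq_along(grid)) {
    filt <- tryCatch(prevalence_filter(counts, grid[g]),
                     rumenpls_empty_table = function(e) NULL)
    if (is.null(filt) || ncol(filt) < 2) next
    observed <- filt[, colSums(filt) > 0, drop = FALSE] # drop never-seen genera
    if (ncol(observed) < 2) next
    clr <- clr_transform(replace_zeros(observed))
    cvr <- cross_validate(clr, labels, h = 1, cv = cv)
    res$n_retained[g] <- ncol(filt)
    res$misclassification[g] <- cvr$criterion
  }
  if (all(is.na(res$misclassification)))
    stop_named("rumenpls_empty_table", "no threshold in the grid is applicable")
  sel <- res$threshold[which.min(res$misclassification)]
  structure(res, selected = sel, class = c("prevalence_scan", "data.frame"))
}

#' @export
print.prevalence_scan <- function(x, ...) {
  cat("Prevalence scan (one-component DA-PLS repeated-CV misclassification %)\n")
  print.data.frame(x, row.names = FALSE)
  cat("selected threshold:", attr(x, "selected"), "\n")
  invisible(x)
}
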