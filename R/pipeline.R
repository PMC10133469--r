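# End-to-end orchestration: diet effects on phenotypes, DA-PLS of diet on
# clr abundances with univariate follow-up, within-diet PLS of methane
# yield, and archaea:bacteria regressions.

#' Analysis configuration
#'
#' Defaults are the analysis protocol settings: 20% minimum prevalence,
#' 4-fold x 20-replicate CV for diet discrimination, 3-fold x 20-replicate
#' CV for within-diet methane prediction, Q2 stopping threshold 0.0975, VIP
#' threshold 0.8, 60,000-iteration chains and a relevance threshold of
#' one-third of the phenotypic SD.
#'
#' @param min_prevalence prevalence threshold applied before zero replacement.
#' @param prevalence_grid optional threshold grid for [scan_prevalence()]
#'   (`NULL` skips the scan and uses `min_prevalence` directly).
#' @param da_k,da_reps folds/replicates for diet discrimination CV.
#' @param methane_k,methane_reps folds/replicates for methane-yield CV.
#' @param q2_threshold Q2 stopping threshold.
#' @param vip_threshold VIP selection threshold.
#' @param h_max maximum latent dimensions considered.
#' @param chain a [chain_spec()] for all Bayesian models.
#' @param seed master seed; every stage derives its own stream from it.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(min_prevalence = 0.2, prevalence_grid = NULL,
                            da_k = 4, da_reps = 20,
                            methane_k = 3, methane_reps = 20,
                            q2_threshold = 0.0975, vip_threshold = 0.8,
                            h_max = 3, chain = chain_spec(), seed = 1) {
  if (min_prevalence < 0 || min_prevalence > 1)
    stop_named("rumenpls_config_error", "min_prevalence must be in [0, 1]")
  if (q2_threshold < 0 || vip_threshold < 0)
    stop_named("rumenpls_config_error", "thresholds must be non-negative")
  structure(list(min_prevalence = min_prevalence,
                 prevalence_grid = prevalence_grid,
                 da_k = da_k, da_reps = da_reps,
                 methane_k = methane_k, methane_reps = methane_reps,
                 q2_threshold = q2_threshold, vip_threshold = vip_threshold,
                 h_max = h_max, chain = chain, seed = as.integer(seed)),
            class = "analysis_config")
}

check_phenotypes <- function(phen, need_ab = FALSE) {
  base <- c("sample_id", "diet", "breed", "body_weight_kg", "dmi_kg_d",
            "ch4_g_d", "ch4_yield_g_kg_dmi")
  missing <- setdiff(base, names(phen))
  if (length(missing))
    stop_named("rumenpls_input_error", "phenotypes missing column(s): %s",
               paste(missing, collapse = ", "))
  if (need_ab && !"ab_log_ratio" %in% names(phen))
    stop_named("rumenpls_input_error",
               "phenotypes need an 'ab_log_ratio' column; see add_ab_logratio()")
  ratio <- phen$ch4_g_d / phen$dmi_kg_d
  if (any(abs(ratio - phen$ch4_yield_g_kg_dmi) > 1e-6))
    warning("ch4_yield_g_kg_dmi inconsistent with ch4_g_d / dmi_kg_d")
  tab <- table(phen$diet)
  if (length(tab) == 2 && abs(tab[1] - tab[2]) > 1)
    warning("diet groups unbalanced by more than one sample")
  phen$diet <- factor(phen$diet, levels = sort(unique(phen$diet)))
  phen$breed <- factor(phen$breed)
  if ("chamber" %in% names(phen)) phen$chamber <- factor(phen$chamber)
  if ("week" %in% names(phen)) phen$week <- factor(phen$week)
  phen
}

#' Append the archaea:bacteria log-ratio to a phenotype table
#'
#' @param phenotypes phenotype data frame with `sample_id`.
#' @param counts genus count matrix (full table, before prevalence filtering).
#' @param taxonomy taxonomy data frame with `genus` and `domain`.
#' @return the phenotype table with an `ab_log_ratio` column.
#' @export
add_ab_logratio <- function(phenotypes, counts, taxonomy) {
  ab <- archaea_bacteria_logratio(counts, taxonomy)
  phenotypes$ab_log_ratio <- ab[match(phenotypes$sample_id, names(ab))]
  phenotypes
}

with_chain_seed <- function(chain, ...) {
  chain$seed <- derive_seed(chain$seed, ...)
  chain
}

#' Diet effects on intake, methane and A:B
#'
#' For dry matter intake, methane production, methane yield and the
#' archaea:bacteria log-ratio, fits a Bayesian linear model with diet, breed,
#' chamber and week as fixed effects and body weight as a covariate, and
#' summarises the TMR - GRASS difference with its HPD95, P0 and Pr
#' (r = one-third of each trait's phenotypic SD), alongside the posterior
#' marginal mean of each diet.
#'
#' @param phenotypes phenotype table with `ab_log_ratio` (see
#'   [add_ab_logratio()]).
#' @param config an [analysis_config()].
#' @return data frame with one row per trait.
#' @export
run_diet_effects <- function(phenotypes, config = analysis_config()) {
  phen <- check_phenotypes(phenotypes, need_ab = TRUE)
  traits <- c(dmi_kg_d = "Dry matter intake (kg/day)",
              ch4_g_d = "Methane production (g/day)",
              ch4_yield_g_kg_dmi = "Methane yield (g/kg DMI)",
              ab_log_ratio = "Ln(Archaea:Bacteria)")
  out <- vector("list", length(traits))
  rhs <- "diet + breed + chamber + week + body_weight_kg"
  rhs_terms <- intersect(c("diet", "breed", "chamber", "week"), names(phen))
  rhs <- paste(c(rhs_terms, "body_weight_kg"), collapse = " + ")
  for (i in seq_along(traits)) {
    tr <- names(traits)[i]
    fit <- suppressWarnings(bayes_lm(
      stats::as.formula(paste(tr, "~", rhs)), phen,
      chain = with_chain_seed(config$chain, config$seed, 11, i)))
    diet_col <- grep("^diet", fit$coef_names, value = TRUE)[1]
    r <- relevant_threshold(phen[[tr]])
    sm <- posterior_summary(fit, diet_col, r = r, label = traits[i])
    mm <- diet_marginal_means(fit, phen)
    out[[i]] <- data.frame(trait = traits[i], mean_tmr = mm["TMR"],
                           mean_grass = mm["GRASS"],
                           difference = sm$mean, hpd_low = sm$hpd_low,
                           hpd_high = sm$hpd_high, p0 = sm$p0, r = sm$r,
                           pr = sm$pr, effect_size = sm$effect_size,
                           geweke_z = sm$geweke_z, mc_se = sm$mc_se,
                           row.names = NULL)
  }
  do.call(rbind, out)
}

# Posterior marginal mean of each diet level: design-column means with the
# diet dummy set to the level's coding.
diet_marginal_means <- function(fit, phen) {
  xbar <- colMeans(fit$X)
  diet_cols <- grep("^diet", colnames(fit$X), value = TRUE)
  lv <- levels(phen$diet)
  means <- stats::setNames(numeric(length(lv)), lv)
  for (l in lv) {
    row <- xbar
    for (dc in diet_cols) row[dc] <- as.numeric(dc == paste0("diet", l))
    means[l] <- mean(fit$samples %*% row)
  }
  means
}

align_clr <- function(clr, phen) {
  clr <- assert_matrix_like(clr, "clr")
  if (is.null(rownames(clr)))
    stop_named("rumenpls_input_error", "clr matrix needs sample row names")
  if (!all(phen$sample_id %in% rownames(clr)))
    stop_named("rumenpls_input_error", "clr and phenotypes share no complete sample set")
  clr[phen$sample_id, , drop = FALSE]
}

#' Diet discrimination from clr abundances (DA-PLS)
#'
#' Runs [iterative_variable_selection()] in discriminant mode on the clr
#' matrix, validates the final model with repeated CV and its test-label
#' permutation analog, then quantifies each retained genus's diet difference
#' with a univariate Bayesian model (diet + breed + body weight),
#' r = one-third of that genus's clr SD.
#'
#' @param clr clr matrix, samples x genera.
#' @param phenotypes phenotype table.
#' @param config an [analysis_config()].
#' @return list with `selection`, `misclassification`,
#'   `misclassification_permuted` (both [cross_validate()] results) and
#'   `univariate` (per-genus summary data frame).
#' @export
run_da_pls <- function(clr, phenotypes, config = analysis_config()) {
  phen <- check_phenotypes(phenotypes)
  X <- align_clr(clr, phen)
  y <- phen$diet
  cv <- cv_spec(k = config$da_k, reps = config$da_reps,
                seed = derive_seed(config$seed, 21))
  sel <- iterative_variable_selection(X, y, cv = cv,
                                      vip_threshold = config$vip_threshold,
                                      q2_threshold = config$q2_threshold,
                                      h_max = config$h_max)
  Xs <- X[, sel$variables, drop = FALSE]
  cv_perm <- cv
  cv_perm$permute <- "test_labels"
  mis_perm <- cross_validate(Xs, y, sel$h, cv_perm)
  uni <- vector("list", length(sel$variables))
  for (i in seq_along(sel$variables)) {
    g <- sel$variables[i]
    d <- cbind(phen, clr_g = Xs[, g])
    fit <- suppressWarnings(bayes_lm(
      clr_g ~ diet + breed + body_weight_kg, d,
      chain = with_chain_seed(config$chain, config$seed, 31, i)))
    diet_col <- grep("^diet", fit$coef_names, value = TRUE)[1]
    uni[[i]] <- cbind(genus = g,
                      posterior_summary(fit, diet_col,
                                        r = relevant_threshold(Xs[, g]),
                                        label = "TMR - GRASS"))
  }
  list(selection = sel, misclassification = sel$cv_result,
       misclassification_permuted = mis_perm,
       univariate = do.call(rbind, uni))
}

#' Within-diet PLS prediction of methane yield
#'
#' Subsets one diet, runs [iterative_variable_selection()] in regression mode
#' (3-fold x 20 replicates by default) on methane yield, reports predictive
#' ability with its SD and test-response permutation analog, and for each
#' retained genus a univariate Bayesian regression of methane yield on breed,
#' body weight and the genus clr abundance, plus the Pearson correlation on
#' data pre-corrected for breed and body weight.
#'
#' @param clr clr matrix.
#' @param phenotypes phenotype table.
#' @param diet diet label to subset (`"GRASS"` or `"TMR"`).
#' @param config an [analysis_config()].
#' @return list with `selection`, `predictive_ability`,
#'   `predictive_ability_permuted` and `univariate`.
#' @export
run_methane_pls <- function(clr, phenotypes, diet, config = analysis_config()) {
  phen <- check_phenotypes(phenotypes)
  phen <- phen[phen$diet == diet, , drop = FALSE]
  if (nrow(phen) < 6)
    stop_named("rumenpls_input_error", "diet subset '%s' has < 6 samples", diet)
  X <- align_clr(clr, phen)
  y <- phen$ch4_yield_g_kg_dmi
  cv <- cv_spec(k = config$methane_k, reps = config$methane_reps,
                stratified = FALSE,
                seed = derive_seed(config$seed, 41, match(diet, c("GRASS", "TMR"))))
  sel <- iterative_variable_selection(X, y, cv = cv,
                                      vip_threshold = config$vip_threshold,
                                      q2_threshold = config$q2_threshold,
                                      h_max = config$h_max)
  Xs <- X[, sel$variables, drop = FALSE]
  cv_perm <- cv
  cv_perm$permute <- "test_labels"
  pa_perm <- cross_validate(Xs, y, sel$h, cv_perm)
  y_corr <- precorrect(y, phen, chain = with_chain_seed(config$chain, config$seed, 43))
  uni <- vector("list", length(sel$variables))
  for (i in seq_along(sel$variables)) {
    g <- sel$variables[i]
    d <- cbind(phen, clr_g = Xs[, g])
    fit <- suppressWarnings(bayes_lm(
      ch4_yield_g_kg_dmi ~ breed + body_weight_kg + clr_g, d,
      chain = with_chain_seed(config$chain, config$seed, 45, i)))
    sm <- posterior_summary(fit, "clr_g", label = g)
    g_corr <- precorrect(Xs[, g], phen,
                         chain = with_chain_seed(config$chain, config$seed, 47, i))
    rho <- stats::cor(y_corr, g_corr)
    sm$pearson <- rho
    sm$pearson_se <- (1 - rho^2) / sqrt(length(y_corr) - 1)
    uni[[i]] <- cbind(genus = g, sm)
  }
  list(selection = sel, predictive_ability = sel$cv_result,
       predictive_ability_permuted = pa_perm,
       univariate = do.call(rbind, uni))
}

#' Pre-correct a trait for breed and body weight
#'
#' Subtracts the posterior-mean breed and body-weight contributions
#' (centered, so the trait's overall mean is preserved) estimated from a
#' Bayesian linear model of the trait on those effects.
#'
#' @param trait numeric vector aligned with `phenotypes`.
#' @param phenotypes phenotype table providing `breed` and `body_weight_kg`.
#' @param effects character vector of correction terms.
#' @param chain a [chain_spec()].
#' @return corrected numeric vector with unchanged mean.
#' @export
precorrect <- function(trait, phenotypes,
                       effects = c("breed", "body_weight_kg"),
                       chain = chain_spec()) {
  d <- data.frame(.trait = trait, phenotypes, check.names = FALSE)
  fit <- suppressWarnings(bayes_lm(
    stats::as.formula(paste(".trait ~", paste(effects, collapse = " + "))),
    d, chain = chain))
  bhat <- colMeans(fit$samples)
  keep <- setdiff(colnames(fit$X), "(Intercept)")
  Xe <- fit$X[, keep, drop = FALSE]
  Xe <- sweep(Xe, 2, colMeans(Xe))
  drop(trait - Xe %*% bhat[keep])
}

#' Within-diet regression of a methane trait on A:B
#'
#' Bayesian slope of methane production or methane yield on the
#' archaea:bacteria log-ratio within one diet (breed + body weight + A:B),
#' with HPD95 and P0; also reports the model R2 (from posterior-mean
#' residuals) and the Pearson correlation (with its dispersion) on
#' pre-corrected data.
#'
#' @param phenotypes phenotype table with `ab_log_ratio`.
#' @param diet diet label to subset.
#' @param response `"ch4_g_d"` or `"ch4_yield_g_kg_dmi"`.
#' @param config an [analysis_config()].
#' @return one-row data frame with the slope summary, `r2_model`,
#'   `r2_precorrected`, `pearson`, `pearson_se`.
#' @export
run_ab_regression <- function(phenotypes, diet,
                              response = c("ch4_yield_g_kg_dmi", "ch4_g_d"),
                              config = analysis_config()) {
  response <- match.arg(response)
  phen <- check_phenotypes(phenotypes, need_ab = TRUE)
  phen <- phen[phen$diet == diet, , drop = FALSE]
  if (nrow(phen) < 6)
    stop_named("rumenpls_input_error", "diet subset '%s' has < 6 samples", diet)
  fit <- suppressWarnings(bayes_lm(
    stats::as.formula(paste(response, "~ breed + body_weight_kg + ab_log_ratio")),
    phen, chain = with_chain_seed(config$chain, config$seed, 51,
                                  match(diet, c("GRASS", "TMR")))))
  sm <- posterior_summary(fit, "ab_log_ratio",
                          label = paste(response, "on A:B,", diet))
  y <- phen[[response]]
  resid <- y - drop(fit$X %*% colMeans(fit$samples))
  sm$r2_model <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  ch <- with_chain_seed(config$chain, config$seed, 53,
                        match(diet, c("GRASS", "TMR")))
  y_corr <- precorrect(y, phen, chain = ch)
  ab_corr <- precorrect(phen$ab_log_ratio, phen, chain = ch)
  rho <- stats::cor(y_corr, ab_corr)
  sm$r2_precorrected <- rho^2
  sm$pearson <- rho
  sm$pearson_se <- (1 - rho^2) / sqrt(length(y) - 1)
  sm
}

#' Run the full analysis pipeline
#'
#' Preprocesses (A:B, optional prevalence scan, prevalence filter, zero
#' replacement, clr), then runs the diet-effect models, the DA-PLS with
#' univariate follow-up, the within-diet methane PLS for both diets, and the
#' A:B regressions. Deterministic under a fixed master seed. When `outdir`
#' is given, writes `report.json`, tidy CSV tables and a plain-text log.
#'
#' @param config an [analysis_config()].
#' @param input_dir directory with `counts.tsv`, `taxonomy.tsv`,
#'   `phenotypes.csv` (as written by [write_fixture()]); ignored when
#'   `dataset` is given.
#' @param dataset a [generate_dataset()] result (used directly).
#' @param outdir optional output directory.
#' @return list of stage results (`preprocess`, `diet_effects`, `da_pls`,
#'   `methane_pls`, `ab_regression`), invisibly when `outdir` is given.
#' @export
full_run <- function(config = analysis_config(), input_dir = NULL,
                     dataset = NULL, outdir = NULL) {
  if (is.null(dataset) && is.null(input_dir))
    stop_named("rumenpls_input_error", "provide input_dir or dataset")
  if (is.null(dataset)) {
    counts <- read_counts(file.path(input_dir, "counts.tsv"))
    taxonomy <- read_taxonomy(file.path(input_dir, "taxonomy.tsv"))
    phen <- read_phenotypes(file.path(input_dir, "phenotypes.csv"))
  } else {
    counts <- dataset$counts
    taxonomy <- dataset$taxonomy
    phen <- dataset$phenotypes
  }
  log_lines <- c(sprintf("rumenpls full_run; master seed %d", config$seed),
                 sprintf("samples: %d, genera: %d", nrow(counts), ncol(counts)),
                 sprintf("thresholds: prevalence %.2f, Q2 %.4f, VIP %.2f",
                         config$min_prevalence, config$q2_threshold,
                         config$vip_threshold),
                 sprintf("chains: %d iterations, %d burn-in, thin %d",
                         config$chain$iterations, config$chain$burn_in,
                         config$chain$thin))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_named("rumenpls_stage_error", "stage '%s' failed: %s",
                 name, conditionMessage(e)))
  }
  phen <- stage("ab_logratio", add_ab_logratio(phen, counts, taxonomy))
  threshold <- config$min_prevalence
  scan <- NULL
  if (!is.null(config$prevalence_grid)) {
    scan <- stage("prevalence_scan", scan_prevalence(
      counts, phen$diet[match(rownames(counts), phen$sample_id)],
      config$prevalence_grid,
      cv = cv_spec(k = config$da_k, reps = config$da_reps,
                   seed = derive_seed(config$seed, 61))))
    threshold <- attr(scan, "selected")
    log_lines <- c(log_lines, sprintf("prevalence scan selected %.2f", threshold))
  }
  filtered <- stage("prevalence_filter", prevalence_filter(counts, threshold))
  clr <- stage("clr", clr_transform(replace_zeros(filtered)))
  log_lines <- c(log_lines, sprintf("retained %d genera at prevalence %.2f",
                                    ncol(filtered), threshold))
  diet_effects <- stage("diet_effects", run_diet_effects(phen, config))
  da <- stage("da_pls", run_da_pls(clr, phen, config))
  methane <- list(
    GRASS = stage("methane_pls_grass", run_methane_pls(clr, phen, "GRASS", config)),
    TMR = stage("methane_pls_tmr", run_methane_pls(clr, phen, "TMR", config)))
  ab <- do.call(rbind, lapply(c("GRASS", "TMR"), function(d)
    rbind(stage("ab_regression",
                run_ab_regression(phen, d, "ch4_yield_g_kg_dmi", config)),
          stage("ab_regression",
                run_ab_regression(phen, d, "ch4_g_d", config)))))
  report <- list(
    preprocess = list(n_samples = nrow(counts), n_genera = ncol(counts),
                      prevalence_threshold = threshold,
                      n_retained = ncol(filtered),
                      zero_fraction = mean(counts == 0),
                      scan = if (!is.null(scan)) as.data.frame(scan)),
    diet_effects = diet_effects,
    da_pls = da, methane_pls = methane, ab_regression = ab,
    clr = clr, phenotypes = phen,
    config = config, log = log_lines)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(diet_effects, file.path(outdir, "diet_effects.csv"),
                     row.names = FALSE)
    utils::write.csv(da$univariate, file.path(outdir, "da_pls_univariate.csv"),
                     row.names = FALSE)
    sel_tab <- data.frame(genus = da$selection$variables,
                          vip = as.numeric(da$selection$vip),
                          coef = da$selection$jackknife$coef,
                          lower = da$selection$jackknife$lower,
                          upper = da$selection$jackknife$upper,
                          excludes_zero = da$selection$jackknife$excludes_zero)
    utils::write.csv(sel_tab, file.path(outdir, "da_pls_selection.csv"),
                     row.names = FALSE)
    for (d in names(methane))
      utils::write.csv(methane[[d]]$univariate,
                       file.path(outdir, sprintf("methane_pls_%s.csv", tolower(d))),
                       row.names = FALSE)
    utils::write.csv(ab, file.path(outdir, "ab_regression.csv"), row.names = FALSE)
    json <- list(
      preprocess = report$preprocess,
      diet_effects = diet_effects,
      da_pls = list(variables = da$selection$variables, h = da$selection$h,
                    misclassification = da$misclassification$criterion,
                    misclassification_sd = da$misclassification$sd,
                    misclassification_permuted = da$misclassification_permuted$criterion),
      methane_pls = lapply(methane, function(m)
        list(variables = m$selection$variables, h = m$selection$h,
             predictive_ability = m$predictive_ability$criterion,
             predictive_ability_sd = m$predictive_ability$sd,
             predictive_ability_permuted = m$predictive_ability_permuted$criterion)),
      ab_regression = ab,
      seed = config$seed)
    jsonlite::write_json(json, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    writeLines(log_lines, file.path(outdir, "log.txt"))
    return(invisible(report))
  }
  report
}
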