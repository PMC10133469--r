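# Synthetic rumen-microbiome datasets with known ground truth: genus count
# tables with realistic 16S sparsity, diet-shifted genera, and a methane
# yield built from the true underlying clr abundances.

#' Simulation configuration
#'
#' Defaults emulate the study conditions this package targets: 26 animals
#' balanced across two diets (GRASS/TMR), 203 genera with ~78% zero counts
#' per sample at a sequencing depth of ~5.1e5 reads, 22 diet-affected genera,
#' 5 methane-driver genera per diet with one cross-over genus whose
#' coefficient changes sign between diets, and a TMR - GRASS methane yield
#' difference of -10.6 g/kg DMI.
#'
#' @param n_per_diet animals per diet group.
#' @param n_genera number of genera.
#' @param n_diet_affected number of genera shifted between diets.
#' @param diet_effect_size log-scale abundance shift of affected genera
#'   (alternating sign across the affected set).
#' @param n_methane_drivers_per_diet genera driving methane yield in each diet.
#' @param methane_coefficients driver coefficients, g/kg DMI per clr unit
#'   (recycled across the driver set).
#' @param n_crossover how many driver genera are shared between diets with
#'   opposite coefficient signs.
#' @param methane_diet_effect TMR - GRASS difference in methane yield,
#'   g/kg DMI.
#' @param methane_noise_sd residual SD of methane yield (>= 0).
#' @param target_zero_fraction desired average fraction of zero counts per
#'   sample, in (0, 1).
#' @param sequencing_depth_mean mean reads per sample (> 0).
#' @param breed_effect additive breed effect on methane yield (second breed
#'   minus first), g/kg DMI.
#' @param bodyweight_slope methane yield change per kg body weight.
#' @param seed integer RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_per_diet = 13, n_genera = 203, n_diet_affected = 22,
                       diet_effect_size = 3,
                       n_methane_drivers_per_diet = 5,
                       methane_coefficients = c(2.5, -2.5, 2, -2, 1.5),
                       n_crossover = 1,
                       methane_diet_effect = -10.6,
                       methane_noise_sd = 2,
                       target_zero_fraction = 0.78,
                       sequencing_depth_mean = 506000,
                       breed_effect = 0, bodyweight_slope = 0.02,
                       seed = 1) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  err <- function(...) stop_named("rumenpls_config_error", ...)
  if (cfg$n_per_diet < 1) err("n_per_diet must be >= 1")
  if (cfg$n_genera < 2) err("n_genera must be >= 2")
  if (cfg$n_diet_affected > cfg$n_genera)
    err("n_diet_affected (%d) exceeds n_genera (%d)", cfg$n_diet_affected, cfg$n_genera)
  if (cfg$n_methane_drivers_per_diet > cfg$n_genera)
    err("n_methane_drivers_per_diet exceeds n_genera")
  if (cfg$n_crossover > cfg$n_methane_drivers_per_diet)
    err("n_crossover exceeds n_methane_drivers_per_diet")
  if (cfg$target_zero_fraction <= 0 || cfg$target_zero_fraction >= 1)
    err("target_zero_fraction must be in (0, 1)")
  if (cfg$sequencing_depth_mean <= 0) err("sequencing depth must be positive")
  if (cfg$methane_noise_sd < 0) err("methane_noise_sd must be >= 0")
  invisible(cfg)
}

#' Generate a synthetic dataset with known ground truth
#'
#' Per-genus log-normal baseline abundances (the tail heaviness is calibrated
#' so the realised zero fraction matches `target_zero_fraction`), diet-
#' affected genera shifted on the log scale in the TMR group, per-sample
#' multinomial count draws at a depth sampled around
#' `sequencing_depth_mean`, and a methane yield constructed from the *true*
#' underlying clr abundances (before any zero replacement):
#' `yield = intercept + diet + breed + bodyweight_slope * (BW - mean BW) +
#' sum_j coeff_j * clr_j + N(0, noise_sd)` with diet-specific driver sets.
#' Same-seed calls are bit-identical.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_dataset`: list with `counts` (integer
#'   matrix, samples x genera), `taxonomy` (genus/domain/phylum data frame),
#'   `phenotypes` (data frame), `truth` (diet-affected genus effects and
#'   per-diet methane-driver coefficients), `clr_true`.
#' @export
generate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  with_seed(config$seed, {
    n <- 2 * config$n_per_diet
    p <- config$n_genera
    samples <- sprintf("S%02d", seq_len(n))
    genera <- sprintf("Genus%03d", seq_len(p))
    diet <- rep(c("GRASS", "TMR"), each = config$n_per_diet)

    # taxonomy: a small archaeal clade, the rest bacterial
    n_arch <- max(2, round(0.04 * p))
    bact_phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
                    "Actinobacteria", "Fibrobacteres")
    taxonomy <- data.frame(
      genus = genera,
      domain = c(rep("Archaea", n_arch), rep("Bacteria", p - n_arch)),
      phylum = c(rep("Euryarchaeota", n_arch),
                 sample(bact_phyla, p - n_arch, replace = TRUE)),
      stringsAsFactors = FALSE)

    base <- stats::rnorm(p)            # genus baseline, scaled below
    # the first archaeal genus is ubiquitous (the dominant methanogen), so
    # every sample has a positive archaeal total and A:B is always defined
    base[1] <- max(base) + 0.5
    noise <- matrix(stats::rnorm(n * p), n, p) # per-sample variation

    # effect-carrying genera are drawn from the high-abundance tail (the
    # genera that survive a 20% prevalence filter at this sparsity level) so
    # the ground truth remains observable downstream; alternating shift sign.
    # methane drivers take the very top of that pool: near the detection
    # boundary, multinomial sampling noise would swamp a genus's true clr
    # signal and no method could recover its association
    nd <- config$n_methane_drivers_per_diet
    pool_size <- min(p, max(config$n_diet_affected + 3 * nd,
                            floor(p / 4), 2))
    prevalent <- order(base, decreasing = TRUE)[seq_len(pool_size)]
    driver_pool <- prevalent[seq_len(min(3 * nd, pool_size))]
    affected_pool <- setdiff(prevalent, driver_pool)
    if (length(affected_pool) < config$n_diet_affected)
      affected_pool <- setdiff(prevalent, integer(0))
    affected <- sort(sample(affected_pool, config$n_diet_affected))
    effects <- config$diet_effect_size *
      rep_len(c(1, -1), config$n_diet_affected)
    shift <- matrix(0, n, p)
    if (config$n_diet_affected > 0)
      shift[diet == "TMR", affected] <- rep(effects, each = config$n_per_diet)

    depth_mean <- config$sequencing_depth_mean
    depth <- pmax(round(stats::rnorm(n, depth_mean, 0.3 * depth_mean)),
                  max(100, round(0.2 * depth_mean)))

    # calibrate the baseline spread so the expected (Poisson-approximate)
    # zero fraction at the sampled depths matches the target
    zero_frac <- function(sg) {
      z <- sweep(noise, 2, sg * base, "+") + shift
      pr <- exp(z - apply(z, 1, max))
      pr <- pr / rowSums(pr)
      mean(exp(-depth * pr))
    }
    lo <- 0.2; hi <- 25
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (zero_frac(mid) < config$target_zero_fraction) lo <- mid else hi <- mid
    }
    sigma_g <- (lo + hi) / 2
    z <- sweep(noise, 2, sigma_g * base, "+") + shift
    pr <- exp(z - apply(z, 1, max))
    pr <- pr / rowSums(pr)

    counts <- t(vapply(seq_len(n),
                       function(i) drop(stats::rmultinom(1, depth[i], pr[i, ])),
                       integer(p)))
    dimnames(counts) <- list(samples, genera)
    storage.mode(counts) <- "integer"

    clr_true <- log(pr) - rowMeans(log(pr))
    dimnames(clr_true) <- list(samples, genera)

    # methane drivers per diet, sharing n_crossover genera with flipped
    # signs; drawn outside the diet-affected set so the diet effect on
    # methane stays exactly the configured value
    pool <- setdiff(driver_pool, affected)
    if (length(pool) < 2 * nd) pool <- setdiff(seq_len(p), affected)
    drv_grass <- sort(sample(pool, nd))
    drv_tmr_extra <- sort(sample(setdiff(pool, drv_grass), nd - config$n_crossover))
    cross <- if (config$n_crossover > 0) drv_grass[seq_len(config$n_crossover)] else integer(0)
    drv_tmr <- sort(c(cross, drv_tmr_extra))
    coef_grass <- stats::setNames(
      rep_len(config$methane_coefficients, nd), genera[drv_grass])
    coef_tmr <- stats::setNames(
      rep_len(config$methane_coefficients, nd), genera[drv_tmr])
    if (length(cross) > 0) # cross-over genera flip sign in TMR
      coef_tmr[genera[cross]] <- -coef_grass[genera[cross]]

    breed <- rep(rep_len(c("AAx", "LIMx"), config$n_per_diet), 2)
    chamber <- rep_len(sprintf("C%d", 1:6), n)
    week <- rep_len(sprintf("W%d", rep(1:6, each = 2)), n)
    bw <- round(stats::rnorm(n, 505, 40))
    bw <- pmin(pmax(bw, 438), 656)
    dmi <- ifelse(diet == "TMR", stats::rnorm(n, 9.16, 0.8),
                  stats::rnorm(n, 5.95, 0.8))
    dmi <- pmax(dmi, 1.5)

    # driver clr centered within diet: the between-diet methane difference
    # is then exactly methane_diet_effect, leaving the truth unambiguous
    driver_part <- numeric(n)
    for (d in c("GRASS", "TMR")) {
      in_d <- diet == d
      dd <- if (d == "TMR") drv_tmr else drv_grass
      cc <- if (d == "TMR") coef_tmr else coef_grass
      clr_d <- clr_true[in_d, dd, drop = FALSE]
      clr_d <- sweep(clr_d, 2, colMeans(clr_d))
      driver_part[in_d] <- drop(clr_d %*% cc)
    }
    yield <- 25 +
      config$methane_diet_effect * (diet == "TMR") +
      config$breed_effect * (breed == "LIMx") +
      config$bodyweight_slope * (bw - mean(bw)) +
      driver_part +
      stats::rnorm(n, 0, config$methane_noise_sd)

    phenotypes <- data.frame(
      sample_id = samples, diet = diet, breed = breed, chamber = chamber,
      week = week, body_weight_kg = bw, dmi_kg_d = dmi,
      ch4_g_d = yield * dmi, ch4_yield_g_kg_dmi = yield,
      stringsAsFactors = FALSE)

    truth <- list(
      diet_affected = stats::setNames(effects, genera[affected]),
      methane_drivers = list(GRASS = coef_grass, TMR = coef_tmr),
      intercept = 25, methane_diet_effect = config$methane_diet_effect)

    structure(list(counts = counts, taxonomy = taxonomy,
                   phenotypes = phenotypes, truth = truth,
                   clr_true = clr_true, config = config),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic rumen dataset: %d samples x %d genera, %.1f%% zeros\n",
              nrow(x$counts), ncol(x$counts), 100 * mean(x$counts == 0)))
  cat(sprintf("  %d diet-affected genera; %d/%d methane drivers (GRASS/TMR)\n",
              length(x$truth$diet_affected),
              length(x$truth$methane_drivers$GRASS),
              length(x$truth$methane_drivers$TMR)))
  invisible(x)
}

#' Write a dataset as plain-text fixture files
#'
#' Emits `counts.tsv` (first column `sample_id`), `taxonomy.tsv`,
#' `phenotypes.csv` and `truth.json`; these round-trip losslessly through the
#' `read_*` readers.
#'
#' @param dataset a [generate_dataset()] result.
#' @param directory output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_fixture <- function(dataset, directory) {
  if (!inherits(dataset, "synthetic_dataset"))
    stop_named("rumenpls_input_error", "dataset must be a synthetic_dataset")
  if (nrow(dataset$counts) == 0)
    stop_named("rumenpls_config_error", "dataset has no samples")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(directory,
                     c("counts.tsv", "taxonomy.tsv", "phenotypes.csv", "truth.json"))
  cdf <- data.frame(sample_id = rownames(dataset$counts), dataset$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(cdf, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$taxonomy, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(dataset$phenotypes, paths[3], row.names = FALSE, quote = FALSE)
  truth_json <- dataset$truth
  truth_json$diet_affected <- as.list(truth_json$diet_affected)
  truth_json$methane_drivers <- lapply(truth_json$methane_drivers, as.list)
  jsonlite::write_json(truth_json, paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a genus count table
#' @param path a `counts.tsv` with a `sample_id` first column.
#' @return integer matrix, samples x genera.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Read a taxonomy table
#' @param path a `taxonomy.tsv` with columns genus, domain, phylum.
#' @return data frame.
#' @export
read_taxonomy <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a phenotype table
#' @param path a `phenotypes.csv`.
#' @return data frame with factors left as character.
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a ground-truth record
#' @param path a `truth.json` written by [write_fixture()].
#' @return list mirroring the dataset `truth` element.
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$diet_affected <- unlist(tr$diet_affected)
  tr$methane_drivers <- lapply(tr$methane_drivers, unlist)
  tr
}
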