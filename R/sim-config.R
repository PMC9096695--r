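#' Simulation configuration for a synthetic neurodevelopmental cohort
#'
#' Bundles every parameter of the synthetic-cohort generator: cohort size,
#' simulated genome, CNV incidence and length model, the true standardized
#' effects that generate each outcome, the polygenic-score correlation
#' structure, and the brain-deviation coupling. The defaults reproduce the
#' conditions of the community sample the pipeline was designed around:
#' 7101 genotyped youths aged 8 to 21 years carrying 18185 CNVs of at least
#' 50 kb (58% deletions), a European-ancestry subcohort fraction of 63%, and
#' an imaged subcohort of 920.
#'
#' @param n_samples Number of individuals in the cohort.
#' @param n_genes Number of genes tiled over the simulated genome.
#' @param seed Master seed; every component derives its own deterministic
#'   child stream from it.
#' @param cnv_rate Mean number of CNV calls per individual (Poisson).
#' @param deletion_fraction Probability that a call is a deletion.
#' @param size_log_mean,size_log_sd Log-scale location and spread of CNV
#'   length in base pairs; the length distribution is truncated below at
#'   `min_cnv_size` so every generated call survives the size filter.
#' @param min_cnv_size Lower truncation bound for CNV length (bp).
#' @param effect_map Named list: one entry per outcome, each a named numeric
#'   vector of true standardized effects keyed by predictor column name
#'   (risk-score columns, `neighborhood_ses`, `trauma_count`, PGS columns).
#'   Outcomes are built as the effect-weighted sum of z-scored predictors
#'   plus Gaussian noise scaled so the outcome has unit variance.
#' @param outcome_names Outcomes to generate (all must appear in
#'   `effect_map`; missing entries mean a pure-noise outcome).
#' @param pgs_correlation 6x6 correlation matrix of the polygenic scores
#'   (symmetric, unit diagonal, positive semi-definite).
#' @param n_imaged Size of the imaged subcohort.
#' @param baseline_deviation_prob Probability that a low-CNV-risk imaged
#'   individual is classified high brain deviation (the deviation rate the
#'   reference cohort exhibits across the three correlated volume
#'   phenotypes; 0.488 corresponds to three independent phenotypes).
#' @param deviation_coupling Log-odds increment of high brain deviation per
#'   unit of the high-CNV-risk indicator.
#' @param trauma_size,trauma_prob Trauma exposure count ~ Binomial(size, prob).
#' @param n_chromosomes,chromosome_length Simulated genome shape (equal-length
#'   autosome-like chromosomes named chr1..chrN).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_samples = 200, n_genes = 500, seed = 1)
#' cfg$cnv_rate
sim_config <- function(n_samples = 7101,
                       n_genes = 18000,
                       seed = 1L,
                       cnv_rate = 18185 / 7101,
                       deletion_fraction = 10517 / 18185,
                       size_log_mean = log(1.2e5),
                       size_log_sd = 0.9,
                       min_cnv_size = 5e4,
                       effect_map = default_effect_map(),
                       outcome_names = NULL,
                       pgs_correlation = default_pgs_correlation(),
                       n_imaged = 920,
                       baseline_deviation_prob = 0.395,
                       deviation_coupling = 0.56,
                       trauma_size = 8L,
                       trauma_prob = 0.15,
                       n_chromosomes = 22L,
                       chromosome_length = 1.2e8) {
  outcome_names <- outcome_names %||% .outcome_names
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    seed = as.integer(seed), cnv_rate = cnv_rate,
    deletion_fraction = deletion_fraction,
    size_log_mean = size_log_mean, size_log_sd = size_log_sd,
    min_cnv_size = min_cnv_size, effect_map = effect_map,
    outcome_names = outcome_names, pgs_correlation = pgs_correlation,
    n_imaged = as.integer(n_imaged),
    baseline_deviation_prob = baseline_deviation_prob,
    deviation_coupling = deviation_coupling,
    trauma_size = as.integer(trauma_size), trauma_prob = trauma_prob,
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = chromosome_length
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_samples < 1L) abort("`n_samples` must be positive.", class = "cnvrisk_config_error")
  if (cfg$n_genes < 1L) abort("`n_genes` must be positive.", class = "cnvrisk_config_error")
  for (p in c("deletion_fraction", "trauma_prob", "baseline_deviation_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      abort(paste0("`", p, "` must lie in [0, 1]."), class = "cnvrisk_config_error")
    }
  }
  if (cfg$cnv_rate < 0) abort("`cnv_rate` must be non-negative.", class = "cnvrisk_config_error")
  if (cfg$min_cnv_size <= 0) abort("`min_cnv_size` must be positive.", class = "cnvrisk_config_error")
  R <- cfg$pgs_correlation
  if (!is.matrix(R) || nrow(R) != 6L || ncol(R) != 6L ||
      !isTRUE(all.equal(R, t(R))) || !isTRUE(all.equal(unname(diag(R)), rep(1, 6)))) {
    abort("`pgs_correlation` must be a symmetric 6x6 matrix with unit diagonal.",
          class = "cnvrisk_config_error")
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort("`pgs_correlation` must be positive semi-definite.",
          class = "cnvrisk_config_error")
  }
  if (!is.list(cfg$effect_map) ||
      (length(cfg$effect_map) > 0 && is.null(names(cfg$effect_map)))) {
    abort("`effect_map` must be a named list of named numeric vectors.",
          class = "cnvrisk_config_error")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  cohort: n =", x$n_samples, "| imaged:", x$n_imaged, "\n")
  cat("  genome:", x$n_genes, "genes on", x$n_chromosomes, "chromosomes\n")
  cat(sprintf("  CNVs: rate %.2f/person, %.0f%% deletions, length >= %g bp\n",
              x$cnv_rate, 100 * x$deletion_fraction, x$min_cnv_size))
  cat("  outcomes:", length(x$outcome_names), "| seed:", x$seed, "\n")
  invisible(x)
}

#' True standardized generating effects mirroring the reported associations
#'
#' One entry per outcome; each is a named vector of standardized effects on
#' z-scored predictors. Headline values follow the published associations
#' (deletion-pHI on overall accuracy -0.121, duplication-pTS -0.054,
#' deletion-pHI on psychosis-spectrum symptoms 0.05, intelligence PGS on
#' overall accuracy 0.27, trauma on overall psychopathology 0.35, and the
#' secondary PGS/environment effects); remaining cognitive-domain effects
#' are set to mirror the reported pattern of weaker, less specific
#' associations.
#'
#' @return Named list of named numeric vectors.
#' @export
default_effect_map <- function() {
  list(
    overall_accuracy = c(
      del_sum_pHI = -0.121, dup_sum_pTS = -0.054, neighborhood_ses = 0.08,
      pgs_intelligence = 0.27, pgs_mdd = 0.04, pgs_adhd = -0.04
    ),
    executive_accuracy = c(
      del_sum_pHI = -0.10, dup_sum_pTS = -0.05, neighborhood_ses = 0.09,
      pgs_intelligence = 0.25
    ),
    memory_accuracy = c(
      del_sum_pHI = -0.09, dup_sum_pTS = -0.03, neighborhood_ses = 0.05,
      pgs_intelligence = 0.15
    ),
    social_accuracy = c(
      del_sum_pHI = -0.08, dup_sum_pTS = -0.03, neighborhood_ses = 0.05,
      pgs_intelligence = 0.15
    ),
    overall_psychopathology = c(del_sum_pHI = 0.03, trauma_count = 0.35),
    psychosis_spectrum = c(del_sum_pHI = 0.05, trauma_count = 0.30),
    externalizing = c(del_sum_pHI = 0.03, trauma_count = 0.25, pgs_adhd = 0.08),
    fear = c(trauma_count = 0.22),
    mood = c(trauma_count = 0.30, pgs_mdd = 0.06)
  )
}

#' Default polygenic-score correlation matrix
#'
#' Modest positive correlation (0.2) among the five psychiatric PGSs and a
#' weak negative correlation (-0.1) between each of them and the
#' intelligence PGS, a stylized rendering of published cross-disorder
#' genetic correlations.
#'
#' @return A 6x6 correlation matrix named by PGS.
#' @export
default_pgs_correlation <- function() {
  R <- matrix(0.2, 6, 6, dimnames = list(.pgs_names, .pgs_names))
  R[, "pgs_intelligence"] <- R["pgs_intelligence", ] <- -0.1
  diag(R) <- 1
  R
}

# Deterministic child seed for a named component stream. Keeps every stream
# independent of the others while reproducible from the single master seed.
child_seed <- function(seed, stream) {
  offsets <- c(genes = 11L, cnv = 23L, cohort = 37L, brain = 53L,
               outcome = 71L, reference = 89L)
  if (!stream %in% names(offsets)) abort(paste("Unknown seed stream:", stream))
  as.integer((as.numeric(seed) * 1000 + offsets[[stream]]) %%
               .Machine$integer.max)
}
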