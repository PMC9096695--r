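#' Simulate the phenotype/covariate table of a synthetic cohort
#'
#' Generates demographics (age uniform on 8-21 years, balanced sex,
#' self-identified race with the study's group proportions), 10 ancestry
#' principal components, six correlated polygenic scores, two environmental
#' stressors (a continuous neighborhood-SES factor and a 0-8 trauma
#' exposure count), two categorical diagnoses, and every outcome named in
#' the configuration. Each outcome is the effect-weighted sum of z-scored
#' predictors defined by `config$effect_map`, plus Gaussian noise scaled so
#' the outcome has unit variance — the generating effects are therefore
#' standardized by construction. Outcomes carry no age trend; age
#' normalization is a property of the phenotype-preparation step, not of
#' the generator.
#'
#' @param config A [sim_config()].
#' @param scores Per-sample risk-score profile ([score_samples()] output,
#'   optionally [transform_scores()]-augmented) whose columns the
#'   `effect_map` may reference. May be `NULL` if no effect references a
#'   score column.
#' @return A tibble with one row per individual: `sample_id`, `age`, `sex`,
#'   `race_label`, `PC1`..`PC10`, `neighborhood_ses`, `trauma_count`, the
#'   six `pgs_*` columns, `dx_psychosis_spectrum`, `dx_adhd`, `imaged`, and
#'   one column per outcome.
#' @export
sim_cohort <- function(config, scores = NULL) {
  config <- validate_sim_config(config)
  n <- config$n_samples
  set.seed(child_seed(config$seed, "cohort"))
  sample_ids <- sprintf("S%05d", seq_len(n))

  pcs <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("PC", 1:10)))
  pgs <- matrix(rnorm(n * 6), n, 6) %*% chol(config$pgs_correlation)
  colnames(pgs) <- .pgs_names

  cohort <- tibble(
    sample_id = sample_ids,
    age = runif(n, 8, 21),
    sex = sample(c("male", "female"), n, replace = TRUE),
    race_label = sample(c("European American", "African American", "Other"),
                        n, replace = TRUE, prob = c(0.63, 0.26, 0.11)),
    !!!as_tibble(pcs),
    neighborhood_ses = rnorm(n),
    trauma_count = rbinom(n, config$trauma_size, config$trauma_prob),
    !!!as_tibble(pgs)
  )
  cohort$imaged <- seq_len(n) %in% sample.int(n, min(config$n_imaged, n))

  pred <- cohort
  if (!is.null(scores)) {
    pred <- left_join(pred, scores, by = "sample_id")
  }

  set.seed(child_seed(config$seed, "outcome"))
  for (oc in config$outcome_names) {
    effects <- config$effect_map[[oc]]
    cohort[[oc]] <- build_outcome(pred, effects, oc, n)
  }

  # categorical diagnoses: weak positive log-odds coupling with the deletion
  # dosage-sensitivity burden, mirroring the reported logistic associations
  dx_lp <- function(base_rate, beta) {
    z <- if (!is.null(scores) && "del_sum_pHI" %in% names(pred) &&
             sd(pred$del_sum_pHI) > 0) {
      as.numeric(scale(pred$del_sum_pHI))
    } else {
      0
    }
    qlogis(base_rate) + beta * z
  }
  cohort$dx_psychosis_spectrum <- rbinom(n, 1, plogis(dx_lp(0.20, 0.13)))
  cohort$dx_adhd <- rbinom(n, 1, plogis(dx_lp(0.12, 0.11)))
  cohort
}

# One outcome: sum of true standardized effects times z-scored predictors,
# plus noise scaled so the outcome has (empirical) unit variance.
build_outcome <- function(pred, effects, outcome, n) {
  if (is.null(effects) || length(effects) == 0L) {
    return(rnorm(n))
  }
  missing <- setdiff(names(effects), names(pred))
  if (length(missing) > 0L) {
    abort(paste0("effect_map for '", outcome, "' references unknown predictor(s): ",
                 paste(missing, collapse = ", ")),
          class = "cnvrisk_config_error")
  }
  zmat <- vapply(names(effects), function(term) {
    x <- pred[[term]]
    if (!is.numeric(x)) {
      abort(paste0("Predictor '", term, "' in effect_map must be numeric."),
            class = "cnvrisk_config_error")
    }
    if (sd(x) == 0) {
      abort(paste0("Predictor '", term, "' is constant; cannot carry effect on '",
                   outcome, "'."),
            class = "cnvrisk_config_error")
    }
    as.numeric(scale(x))
  }, numeric(n))
  lp <- drop(zmat %*% effects)
  v <- var(lp)
  if (v > 1 + 1e-8) {
    abort(paste0("Generating effects for '", outcome,
                 "' imply variance > 1; shrink the effect_map entries."),
          class = "cnvrisk_config_error")
  }
  lp + rnorm(n, sd = sqrt(max(0, 1 - v)))
}
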