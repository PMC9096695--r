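#' Parameter-recovery simulation for the headline standardized effects
#'
#' Repeatedly generates a full synthetic cohort (genome, CNV calls, risk
#' scores, covariates, environment, PGSs, outcomes) with the published
#' standardized effects as ground truth, runs the pipeline's own models,
#' and collects the estimates. Per replicate it fits: the
#' covariate-adjusted linear model of overall cognitive accuracy and of
#' psychosis-spectrum symptoms on the paired deletion-pHI/duplication-pTS
#' scores (multiancestry cohort), and the combined
#' CNV + environment + PGS model of overall accuracy and of overall
#' psychopathology on the European-ancestry subcohort. Because every
#' outcome has unit variance and effects multiply z-scored predictors,
#' an unbiased pipeline recovers each generating effect on average.
#'
#' @param n_reps Number of replicate cohorts.
#' @param seed Master seed; replicate r uses a deterministic child seed.
#' @param n_samples Cohort size per replicate.
#' @param config_args Named list of [sim_config()] overrides applied to
#'   every replicate.
#' @return A tibble with one row per replicate: `del_pHI_accuracy`,
#'   `dup_pTS_accuracy`, `del_pHI_psychosis`, `pgs_g_accuracy`,
#'   `trauma_psychopathology`, and the realized European-subcohort size
#'   `n_eur`.
#' @export
#' @examples
#' \donttest{
#' rec <- recovery_study(n_reps = 3, seed = 1, n_samples = 800)
#' colMeans(rec)
#' }
recovery_study <- function(n_reps = 200, seed = 1, n_samples = 7101,
                           config_args = list()) {
  cnv_pair <- c("del_sum_pHI", "dup_sum_pTS")
  combined_terms <- c(cnv_pair, "neighborhood_ses", "trauma_count", .pgs_names)
  rows <- purrr::map(seq_len(n_reps), function(r) {
    cfg <- do.call(sim_config, modifyList(
      list(seed = seed * 1000 + r, n_samples = n_samples), config_args
    ))
    genes <- sim_gene_table(cfg)
    calls <- filter_cnvs(sim_cnv_calls(cfg, genes))
    prof <- transform_scores(score_samples(
      calls, genes, samples = sprintf("S%05d", seq_len(cfg$n_samples))
    ))
    dat <- left_join(sim_cohort(cfg, prof), prof, by = "sample_id")

    acc <- tidy(fit_linear(dat, "overall_accuracy", cnv_pair),
                focal_only = TRUE)
    psy <- tidy(fit_linear(dat, "psychosis_spectrum", cnv_pair),
                focal_only = TRUE)
    eur <- suppressMessages(select_subcohort(dat, "european_ancestry"))
    comb_acc <- tidy(fit_linear(eur, "overall_accuracy", combined_terms),
                     focal_only = TRUE)
    comb_psy <- tidy(fit_linear(eur, "overall_psychopathology", combined_terms),
                     focal_only = TRUE)
    pick <- function(td, term) td$estimate[td$term == term]
    tibble(
      del_pHI_accuracy = pick(acc, "del_sum_pHI"),
      dup_pTS_accuracy = pick(acc, "dup_sum_pTS"),
      del_pHI_psychosis = pick(psy, "del_sum_pHI"),
      pgs_g_accuracy = pick(comb_acc, "pgs_intelligence"),
      trauma_psychopathology = pick(comb_psy, "trauma_count"),
      n_eur = nrow(eur)
    )
  })
  bind_rows(rows)
}

#' Parameter-recovery simulation for the brain-deviation association
#'
#' Repeatedly simulates an imaged cohort with a fixed number of high- and
#' low-CNV-risk individuals, a baseline high-deviation probability for
#' the low-risk group, and a log-odds increment for the high-risk group;
#' volumes are drawn through the normative reference, centiles and the
#' deviation classification are recomputed by the pipeline, and the
#' covariate-free logistic coefficient of deviation on risk category is
#' collected.
#'
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @param n_high,n_low Imaged individuals per risk group.
#' @param baseline_prob Low-risk high-deviation probability.
#' @param coupling Generating log-odds increment for high risk.
#' @return Tibble with one `beta` per replicate (log odds, high vs low).
#' @export
deviation_recovery_study <- function(n_reps = 500, seed = 1,
                                     n_high = 59, n_low = 861,
                                     baseline_prob = 0.395,
                                     coupling = 0.56) {
  n <- n_high + n_low
  reference <- make_normative_reference()
  rows <- purrr::map_dbl(seq_len(n_reps), function(r) {
    cfg <- sim_config(
      seed = seed * 1000 + r, n_samples = n, n_imaged = n, cnv_rate = 0,
      effect_map = list(), outcome_names = character(),
      baseline_deviation_prob = baseline_prob,
      deviation_coupling = coupling
    )
    cohort <- sim_cohort(cfg, NULL)
    risk <- tibble(
      sample_id = cohort$sample_id,
      risk_category = sample(rep(c("high", "low"), c(n_high, n_low)))
    )
    brain <- sim_brain(cfg, cohort, risk, reference)
    records <- add_centiles(brain, reference)
    records$deviation <- classify_deviation(
      records[paste0("centile_", .brain_phenotypes)]
    )
    fit <- deviation_association(records)$fit
    td <- tidy(fit)
    td$estimate[td$term == "risk_categoryhigh"]
  })
  tibble(beta = rows)
}
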