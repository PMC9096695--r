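#' Risk-score scheme term pairs
#'
#' The eight annotation schemes compared head-to-head, each entering a
#' model as a paired deletion/duplication term block: dosage sensitivity
#' (pHI/pTS), pLI, 1/LOEUF, log(pLI), gene count, total size,
#' log(1/LOEUF), and the any-dosage-sensitive-content indicator.
#'
#' @return Named list of 2-vectors of profile column names.
#' @export
scheme_terms <- function() {
  list(
    pHI_pTS = c("del_sum_pHI", "dup_sum_pTS"),
    pLI = c("del_sum_pLI", "dup_sum_pLI"),
    invLOEUF = c("del_sum_invLOEUF", "dup_sum_invLOEUF"),
    log_pLI = c("del_log_pLI", "dup_log_pLI"),
    n_genes = c("del_n_genes", "dup_n_genes"),
    total_size = c("del_total_size", "dup_total_size"),
    log_invLOEUF = c("del_log_invLOEUF", "dup_log_invLOEUF"),
    indicator = c("del_pHI_gt0", "dup_pTS_gt0")
  )
}

#' Declared FDR comparison families
#'
#' Family sizes are declared per analysis, never inferred from the number
#' of tests actually reported: 16 for the scheme comparison (8 schemes x
#' 2 terms on one outcome), 34 for the outcome-wide risk-score scan, and
#' 90 for the combined CNV + environment + PGS models.
#'
#' @return Named integer vector.
#' @export
fdr_families <- function() {
  c(scheme_comparison = 16L, outcome_scan = 34L, combined = 90L)
}

#' Simulate a full synthetic study and write its file set
#'
#' Runs the whole generator (gene table, CNV calls, risk scores, cohort,
#' normative reference, brain volumes) and writes every artifact plus the
#' echoed configuration and an md5 manifest, so any downstream subcommand
#' can be replayed from the directory alone.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param force Overwrite an existing output directory?
#' @return Invisibly, a named list of the generated objects.
#' @export
run_simulate <- function(config, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    abort(paste("Output directory exists (use force):", out_dir),
          class = "cnvrisk_io_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  genes <- sim_gene_table(config)
  calls <- sim_cnv_calls(config, genes)
  filtered <- filter_cnvs(calls, min_size_bp = config$min_cnv_size)
  profile <- score_samples(filtered, genes,
                           samples = sprintf("S%05d", seq_len(config$n_samples))) |>
    transform_scores()
  cohort <- sim_cohort(config, profile)
  reference <- make_normative_reference()
  risk <- assign_risk_category(profile)
  brain <- sim_brain(config, cohort, risk, reference)

  write_gene_table(genes, file.path(out_dir, "genes.tsv"))
  write_cnv_calls(calls, file.path(out_dir, "cnv_calls.tsv"))
  write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  write_brain(brain, file.path(out_dir, "brain.csv"))
  write_normative_reference(reference, file.path(out_dir, "normative_reference.tsv"))
  write_run_config(config, file.path(out_dir, "config.txt"))

  files <- dir(out_dir, full.names = TRUE)
  manifest <- tibble(file = basename(files), md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  inform(sprintf("Simulated %d samples, %d genes, %d CNV calls -> %s",
                 config$n_samples, nrow(genes), nrow(calls), out_dir))
  invisible(list(genes = genes, calls = calls, profile = profile,
                 cohort = cohort, brain = brain, reference = reference))
}

#' Filter, optionally exclude pathogenic carriers, score, and transform
#'
#' The scoring pipeline stage: size/chromosome/QC filter, optional
#' pathogenic-CNV sample exclusion, per-sample cumulative scoring under
#' every scheme, and the log/indicator transforms. Total and genic call
#' counts are reported at each step.
#'
#' @param calls CNV calls tibble.
#' @param genes Gene annotation tibble.
#' @param samples Cohort sample ids (zero-CNV samples kept with zero
#'   profiles).
#' @param min_size_bp,include_chrX Passed to [filter_cnvs()].
#' @param pathogenic_regions,reciprocal_overlap Optional pathogenic-region
#'   table for [exclude_pathogenic()].
#' @param rule Gene-overlap rule.
#' @return List: `profile` (transformed), `excluded_samples`, `log`
#'   (tibble of step counts).
#' @export
run_score <- function(calls, genes, samples = NULL,
                      min_size_bp = 5e4, include_chrX = FALSE,
                      pathogenic_regions = NULL, reciprocal_overlap = 0.5,
                      rule = "containment") {
  steps <- list(tibble(step = "input", n_calls = nrow(calls),
                       n_samples = length(unique(calls$sample_id))))
  filtered <- filter_cnvs(calls, min_size_bp, include_chrX)
  steps <- c(steps, list(tibble(step = "size_qc_filter", n_calls = nrow(filtered),
                                n_samples = length(unique(filtered$sample_id)))))
  excluded <- character()
  if (!is.null(pathogenic_regions)) {
    ex <- exclude_pathogenic(filtered, pathogenic_regions, reciprocal_overlap)
    filtered <- ex$calls
    excluded <- ex$excluded_samples
    steps <- c(steps, list(tibble(step = "pathogenic_exclusion",
                                  n_calls = nrow(filtered),
                                  n_samples = length(unique(filtered$sample_id)))))
  }
  samples <- setdiff(samples %||% unique(calls$sample_id), excluded)
  profile <- transform_scores(score_samples(filtered, genes, samples,
                                            rule = rule))
  n_genic <- sum(profile$del_n_genes > 0 | profile$dup_n_genes > 0)
  inform(sprintf("Scored %d samples (%d with genic CNV content).",
                 nrow(profile), n_genic))
  list(profile = profile, excluded_samples = excluded, log = bind_rows(steps))
}

#' Run the full association analysis on a scored cohort
#'
#' Reproduces the analysis tables on one table of cohort covariates joined
#' with a risk-score profile: (1) the scheme comparison for one outcome,
#' each scheme's deletion/duplication pair entering jointly, rows sorted
#' ascending by AIC with FDR over the declared scheme-comparison family;
#' (2) the stepwise ladder (covariates, +CNV, +environment,
#' +environment+CNV) for every outcome; (3) the combined
#' CNV + environment + PGS model on the European-ancestry subcohort with
#' FDR over the declared combined family; and optionally (4) the
#' CNV-by-moderator interaction scan. Outcomes are age-normalized before
#' modelling.
#'
#' @param data Cohort tibble joined with a transformed risk-score profile.
#' @param outcomes Outcome columns to analyze.
#' @param scheme_outcome Outcome used for the scheme comparison.
#' @param families Named FDR family sizes (see [fdr_families()]).
#' @param with_interactions Run the interaction scan?
#' @param out_dir Optional directory for tidy TSV/JSON artifacts.
#' @return List: `scheme_comparison`, `ladders` (list of `cnv_ladder`),
#'   `ladder_summary`, `combined`, and optionally `interactions`.
#' @export
run_analyze <- function(data, outcomes = .outcome_names,
                        scheme_outcome = "overall_accuracy",
                        families = fdr_families(),
                        with_interactions = FALSE,
                        out_dir = NULL) {
  req <- c("scheme_comparison", "outcome_scan", "combined")
  if (!all(req %in% names(families))) {
    abort(paste("Undeclared FDR family; need:", paste(req, collapse = ", ")),
          class = "cnvrisk_config_error")
  }
  data <- data[complete.cases(data[c(outcomes, "age")]), , drop = FALSE]
  for (oc in outcomes) data[[oc]] <- age_normalize(data[[oc]], data$age)

  # -- Table-1-style scheme comparison ------------------------------------
  schemes <- scheme_terms()
  scheme_rows <- purrr::imap(schemes, function(terms, nm) {
    fit <- fit_linear(data, scheme_outcome, terms)
    bind_cols(
      tibble(scheme = nm),
      tidy(fit, focal_only = TRUE),
      select(glance(fit), "AIC", "adj.r.squared", "n")
    )
  }) |> bind_rows()
  scheme_rows$p.adjusted <- bh_adjust(scheme_rows$p.value,
                                      families[["scheme_comparison"]])
  scheme_comparison <- arrange(scheme_rows, .data$AIC, .data$scheme)

  # -- Table-2-style ladder per outcome -----------------------------------
  ladders <- purrr::map(setNames(outcomes, outcomes), function(oc) {
    model_ladder(data, oc, cnv_terms = schemes$pHI_pTS)
  })
  ladder_summary <- purrr::imap(ladders, function(l, oc) {
    mutate(l$comparison, outcome = oc, .before = 1)
  }) |> bind_rows()

  # -- Fig-2-style combined model, European-ancestry subcohort ------------
  eur <- select_subcohort(data, "european_ancestry")
  combined <- purrr::map(setNames(outcomes, outcomes), function(oc) {
    fit <- fit_linear(eur, oc,
                      terms = c(schemes$pHI_pTS, "neighborhood_ses",
                                "trauma_count", .pgs_names))
    mutate(tidy(fit, focal_only = TRUE), outcome = oc, n = fit$glance$n,
           .before = 1)
  }) |> bind_rows()
  combined$p.adjusted <- bh_adjust(combined$p.value, families[["combined"]])

  out <- list(scheme_comparison = scheme_comparison, ladders = ladders,
              ladder_summary = ladder_summary, combined = combined)

  if (with_interactions) {
    out$interactions <- interaction_scan(
      eur, scheme_outcome, cnv_terms = schemes$pHI_pTS,
      moderator_terms = c("neighborhood_ses", "trauma_count", .pgs_names)
    )
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(scheme_comparison, file.path(out_dir, "scheme_comparison.tsv"))
    readr::write_tsv(ladder_summary, file.path(out_dir, "model_ladder.tsv"))
    readr::write_tsv(combined, file.path(out_dir, "combined_model.tsv"))
    if (with_interactions) {
      readr::write_tsv(out$interactions, file.path(out_dir, "interaction_scan.tsv"))
    }
    jsonlite::write_json(
      purrr::map(ladders, "comparison"),
      file.path(out_dir, "ladder_summary.json"),
      dataframe = "rows", pretty = TRUE
    )
  }
  out
}

#' Run the brain-deviation analysis end to end
#'
#' Computes normative centiles for each imaged individual, classifies high
#' deviation (first or tenth decile in at least one phenotype), assigns
#' the CNV-risk category from the risk-score profile, and tests the
#' category-deviation association by logistic regression with the
#' accompanying crosstab.
#'
#' @param brain Brain-volume tibble (`sample_id`, `age`, `sex`, `GMV`,
#'   `sGMV`, `WMV`).
#' @param profile Transformed risk-score profile.
#' @param reference A `normative_reference`.
#' @param scheme,with_medium Passed to [assign_risk_category()].
#' @param out_dir Optional output directory.
#' @return List: `records` (per-sample centiles, deviation, category),
#'   `crosstab`, `fit`.
#' @export
run_deviation <- function(brain, profile, reference,
                          scheme = "pHI_pTS", with_medium = FALSE,
                          out_dir = NULL) {
  records <- add_centiles(brain, reference)
  records$deviation <- classify_deviation(
    records[paste0("centile_", .brain_phenotypes)]
  )
  risk <- assign_risk_category(profile, scheme = scheme,
                               with_medium = with_medium)
  records <- records |>
    select(-any_of("risk_category")) |>
    left_join(risk, by = "sample_id")
  assoc <- deviation_association(records)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(records, file.path(out_dir, "deviation_records.csv"))
    readr::write_tsv(assoc$crosstab, file.path(out_dir, "deviation_crosstab.tsv"))
    jsonlite::write_json(tidy(assoc$fit),
                         file.path(out_dir, "deviation_association.json"),
                         dataframe = "rows", pretty = TRUE)
  }
  list(records = records, crosstab = assoc$crosstab, fit = assoc$fit)
}
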