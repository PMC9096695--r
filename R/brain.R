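#' Normative centile of a brain volume
#'
#' Locates a volume within the age- and sex-specific reference
#' distribution: `pnorm((volume - offset - median(age, sex)) / scale(age,
#' sex))`, with the median and scale curves linearly interpolated between
#' reference grid points. Vectorized over individuals.
#'
#' @param volume Volume(s) in mm^3 (must be positive).
#' @param age Age(s) in years, within the reference support.
#' @param sex `"male"`/`"female"`.
#' @param phenotype One of `"GMV"`, `"sGMV"`, `"WMV"`.
#' @param ref A `normative_reference`.
#' @return Centile(s) in (0, 1).
#' @export
compute_centile <- function(volume, age, sex, phenotype, ref) {
  if (!phenotype %in% unique(ref$phenotype)) {
    abort(paste("Unknown phenotype:", phenotype), class = "cnvrisk_config_error")
  }
  if (any(volume <= 0)) {
    abort("Volumes must be positive.", class = "cnvrisk_validation_error")
  }
  rng <- range(ref$age)
  if (any(age < rng[1] | age > rng[2])) {
    abort(sprintf("Age outside reference support [%g, %g].", rng[1], rng[2]),
          class = "cnvrisk_validation_error")
  }
  offset <- attr(ref, "offset") %||% 0
  mu <- interp_reference(ref, phenotype, sex, age, "median")
  sc <- interp_reference(ref, phenotype, sex, age, "scale")
  pnorm((volume - offset - mu) / sc)
}

#' Add centile columns to a brain-volume table
#'
#' @param brain Tibble with `sample_id`, `age`, `sex`, `GMV`, `sGMV`,
#'   `WMV`.
#' @param ref A `normative_reference`.
#' @return `brain` with `centile_GMV`, `centile_sGMV`, `centile_WMV`
#'   appended.
#' @export
add_centiles <- function(brain, ref) {
  for (ph in .brain_phenotypes) {
    brain[[paste0("centile_", ph)]] <-
      compute_centile(brain[[ph]], brain$age, brain$sex, ph, ref)
  }
  brain
}

#' Classify high brain deviation from three centiles
#'
#' An individual is high deviation when at least one of the three global
#' volume phenotypes falls in the first or tenth decile of the normative
#' distribution — strictly below 0.10 or strictly above 0.90. A centile
#' exactly on a boundary counts as low deviation (a measure-zero event
#' under a continuous reference). The classification is invariant to
#' phenotype order and refuses partial input.
#'
#' @param centiles A numeric vector of 3 centiles, or a 3-column
#'   matrix/data frame (rows = individuals).
#' @return Logical: high deviation?
#' @export
classify_deviation <- function(centiles) {
  m <- if (is.data.frame(centiles) || is.matrix(centiles)) {
    as.matrix(centiles)
  } else {
    matrix(centiles, nrow = 1)
  }
  if (ncol(m) != 3L || anyNA(m)) {
    abort("Exactly 3 non-missing centiles are required per individual.",
          class = "cnvrisk_validation_error")
  }
  unname(apply(m < 0.10 | m > 0.90, 1, any))
}

#' Assign the CNV-risk category from a risk-score profile
#'
#' High risk is a cumulative deletion dosage-sensitivity (pHI) sum
#' strictly greater than 1 or a duplication (pTS) sum strictly greater
#' than 1; under the LOEUF scheme the 1/LOEUF sums are compared against
#' the same threshold. With `with_medium = TRUE`, a nonzero sum not
#' exceeding the threshold is `"medium"`; a sum of exactly 1 is therefore
#' medium (high requires strictly greater than 1).
#'
#' @param profile [score_samples()] output.
#' @param scheme `"pHI_pTS"` (default) or `"LOEUF"`.
#' @param with_medium Add the intermediate category?
#' @param threshold Cumulative-score cutoff for high risk.
#' @return Tibble `sample_id`, `risk_category`
#'   (`"high"`/`"medium"`/`"low"`).
#' @export
assign_risk_category <- function(profile, scheme = c("pHI_pTS", "LOEUF"),
                                 with_medium = FALSE, threshold = 1) {
  scheme <- tryCatch(match.arg(scheme),
                     error = function(e) abort(
                       paste("Unknown risk-score scheme:", scheme[1]),
                       class = "cnvrisk_config_error"))
  del <- if (scheme == "pHI_pTS") profile$del_sum_pHI else profile$del_sum_invLOEUF
  dup <- if (scheme == "pHI_pTS") profile$dup_sum_pTS else profile$dup_sum_invLOEUF
  mx <- pmax(del, dup)
  cat_ <- if_else(mx > threshold, "high",
                  if_else(with_medium & mx > 0, "medium", "low"))
  tibble(sample_id = profile$sample_id, risk_category = cat_)
}

#' Association between CNV-risk category and brain deviation
#'
#' Logistic regression of the high-deviation indicator on the CNV-risk
#' category (plus optional covariates), together with the raw crosstab of
#' deviation counts and within-category percentages (one decimal place).
#' The category enters as a factor with `"low"` as reference, so the
#' high-risk coefficient is the log-odds difference versus low risk.
#'
#' @param records Tibble with `deviation` (logical/0-1) and
#'   `risk_category` columns, e.g. [add_centiles()] output with
#'   `deviation = classify_deviation(...)` and a joined risk category.
#' @param covariates Optional covariate column names.
#' @return List: `fit` (a `cnv_fit`) and `crosstab` (tibble
#'   `risk_category`, `n`, `n_deviant`, `pct_deviant`).
#' @export
deviation_association <- function(records, covariates = character()) {
  if (length(unique(records$risk_category)) < 2L) {
    abort("Need at least 2 risk categories.", class = "cnvrisk_validation_error")
  }
  crosstab <- records |>
    group_by(.data$risk_category) |>
    summarise(
      n = dplyr::n(),
      n_deviant = sum(as.numeric(.data$deviation)),
      .groups = "drop"
    ) |>
    mutate(pct_deviant = round(100 * .data$n_deviant / .data$n, 1)) |>
    arrange(match(.data$risk_category, c("high", "medium", "low")))

  df <- records
  df$deviation <- as.numeric(df$deviation)
  df$risk_category <- relevel(factor(df$risk_category), ref = "low")
  fit <- fit_logistic(df, "deviation", "risk_category",
                      covariates = covariates)
  list(fit = fit, crosstab = crosstab)
}
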