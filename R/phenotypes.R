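#' Age-normalize an outcome
#'
#' Removes the smooth age trend from an outcome and z-scores the result,
#' the standard preparation step before modelling developmental cognitive
#' and psychopathology scores. The default removes a natural cubic spline
#' trend (4 degrees of freedom) by least squares and standardizes the
#' residuals; `method = "bins"` instead z-scores within 2-year age bins.
#'
#' @param outcome Numeric vector.
#' @param age Numeric vector of ages (years), same length.
#' @param method `"spline"` (default) or `"bins"`.
#' @param df Spline degrees of freedom.
#' @return A numeric vector with mean 0, SD 1, and no residual age trend.
#' @export
age_normalize <- function(outcome, age, method = c("spline", "bins"), df = 4) {
  method <- match.arg(method)
  stopifnot(length(outcome) == length(age))
  if (length(outcome) < 30) {
    abort("Need at least 30 observations to age-normalize.",
          class = "cnvrisk_validation_error")
  }
  if (sd(outcome) == 0) {
    abort("Outcome is constant; cannot standardize.",
          class = "cnvrisk_validation_error")
  }
  if (method == "spline") {
    res <- resid(lm(outcome ~ splines::ns(age, df = df)))
  } else {
    bin <- cut(age, breaks = seq(floor(min(age)), ceiling(max(age)) + 2, by = 2),
               include.lowest = TRUE, right = FALSE)
    res <- unsplit(lapply(split(outcome, bin), function(x) {
      if (length(x) > 1 && sd(x) > 0) (x - mean(x)) / sd(x) else x - mean(x)
    }), bin)
  }
  if (sd(res) < 1e-10 * sd(outcome)) {
    # outcome was an exact function of age; the residual is identically zero
    return(rep(0, length(res)))
  }
  as.numeric(scale(res))
}

#' Z-score continuous predictor columns
#'
#' Maps each named continuous column to mean 0, SD 1 (sample SD, n-1
#' denominator). Binary 0/1 and non-numeric columns are left untouched so
#' categorical covariates keep their coding.
#'
#' @param table A cohort tibble.
#' @param terms Character vector of column names to standardize.
#' @return The table with the selected continuous columns z-scored.
#' @export
standardize_predictors <- function(table, terms) {
  missing <- setdiff(terms, names(table))
  if (length(missing) > 0L) {
    abort(paste("Unknown term(s):", paste(missing, collapse = ", ")),
          class = "cnvrisk_config_error")
  }
  for (term in terms) {
    x <- table[[term]]
    if (!is.numeric(x)) next
    ux <- unique(x[!is.na(x)])
    if (length(ux) <= 2L && all(ux %in% c(0, 1))) next
    s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      abort(paste0("Term '", term, "' has zero variance; cannot standardize."),
            class = "cnvrisk_validation_error")
    }
    table[[term]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  table
}

#' Select an analysis subcohort
#'
#' `"multiancestry"` keeps every row, `"european_ancestry"` keeps the
#' European-ancestry stratum (the subcohort in which polygenic scores are
#' interpretable), `"imaged"` keeps individuals with structural imaging.
#' The before/after sample sizes are reported so cohort accounting stays
#' auditable.
#'
#' @param table Cohort tibble with `race_label` and `imaged` columns.
#' @param criterion One of `"multiancestry"`, `"european_ancestry"`,
#'   `"imaged"`.
#' @return The row subset.
#' @export
select_subcohort <- function(table,
                             criterion = c("multiancestry",
                                           "european_ancestry", "imaged")) {
  criterion <- tryCatch(match.arg(criterion),
                        error = function(e) abort(
                          paste("Unknown subcohort criterion:", criterion[1]),
                          class = "cnvrisk_config_error"))
  out <- switch(criterion,
    multiancestry = table,
    european_ancestry = filter(table, .data$race_label == "European American"),
    imaged = filter(table, .data$imaged)
  )
  inform(sprintf("Subcohort '%s': %d of %d rows retained.",
                 criterion, nrow(out), nrow(table)))
  if (nrow(out) == 0L) warn("Subcohort selection matched no rows.")
  out
}
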