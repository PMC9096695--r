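#' Build a synthetic normative brain-volume reference
#'
#' Tabulates age- and sex-specific median and scale curves for the three
#' global volume phenotypes (cortical gray matter GMV, subcortical gray
#' matter sGMV, cerebral white matter WMV) on a 0.1-year grid over ages
#' 8-21, plus a scalar study offset. The curves are a stylized rendering of
#' adolescent growth: GMV declines through adolescence, WMV increases, and
#' sGMV is near-flat; male volumes run higher than female. The reference
#' distribution at a given age and sex is Gaussian(median + offset, scale).
#' This object is synthetic — it stands in for an externally fitted
#' normative growth model, which is supplied as an input file in real use.
#'
#' @param offset Scalar study offset (mm^3) added to every median when
#'   centiles are computed, representing site/study harmonization.
#' @return A `normative_reference`: tibble (`phenotype`, `sex`, `age`,
#'   `median`, `scale`) with the offset stored as an attribute.
#' @export
make_normative_reference <- function(offset = 0) {
  grid <- expand.grid(
    phenotype = .brain_phenotypes,
    sex = c("male", "female"),
    age = seq(8, 21, by = 0.1),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- as_tibble(grid)
  sex_mult <- if_else(grid$sex == "male", 1, 0.90)
  a <- grid$age - 8
  grid$median <- sex_mult * dplyr::case_when(
    grid$phenotype == "GMV"  ~ 680000 - 4200 * a + 60 * a^2,
    grid$phenotype == "sGMV" ~ 62000 - 150 * a,
    grid$phenotype == "WMV"  ~ 380000 + 4800 * a - 120 * a^2
  )
  grid$scale <- sex_mult * dplyr::case_when(
    grid$phenotype == "GMV"  ~ 58000,
    grid$phenotype == "sGMV" ~ 5600,
    grid$phenotype == "WMV"  ~ 43000
  )
  new_normative_reference(grid, offset)
}

new_normative_reference <- function(curves, offset) {
  stopifnot(all(c("phenotype", "sex", "age", "median", "scale") %in% names(curves)))
  if (any(curves$scale <= 0)) {
    abort("Reference scale curves must be strictly positive.",
          class = "cnvrisk_validation_error")
  }
  structure(as_tibble(curves), offset = offset,
            class = c("normative_reference", class(as_tibble(curves))))
}

#' @export
print.normative_reference <- function(x, ...) {
  cat("<normative_reference> offset =", attr(x, "offset"), "\n")
  NextMethod()
}

#' Simulate brain volumes for the imaged subcohort
#'
#' For each imaged individual, a high-deviation indicator is drawn from a
#' logistic model: baseline log-odds `qlogis(baseline_deviation_prob)` for
#' low/medium CNV-risk individuals, incremented by `deviation_coupling` for
#' high-risk individuals. Conditional on the indicator, the three volume
#' centiles are drawn uniformly on the corresponding region (at least one
#' centile in the outer deciles for deviants, all centiles within
#' 0.10-0.90 otherwise), and volumes are obtained by inverting the
#' normative reference at the individual's age and sex. When
#' `baseline_deviation_prob = 1 - 0.8^3 = 0.488` and the coupling is zero,
#' the marginal centiles are exactly three independent uniforms.
#'
#' @param config A [sim_config()].
#' @param cohort Cohort tibble from [sim_cohort()]; only rows with
#'   `imaged == TRUE` receive brain records.
#' @param risk_categories Tibble (`sample_id`, `risk_category`) from
#'   [assign_risk_category()], or `NULL` for an all-low cohort.
#' @param reference A [make_normative_reference()] object (or one read via
#'   [read_normative_reference()]).
#' @return Tibble: `sample_id`, `age`, `sex`, `GMV`, `sGMV`, `WMV`,
#'   `risk_category`.
#' @export
sim_brain <- function(config, cohort, risk_categories = NULL,
                      reference = make_normative_reference()) {
  config <- validate_sim_config(config)
  if (is.null(reference)) {
    abort("A normative reference is required.", class = "cnvrisk_io_error")
  }
  imaged <- filter(cohort, .data$imaged)
  if (!is.null(risk_categories)) {
    imaged <- left_join(imaged, risk_categories, by = "sample_id")
    imaged$risk_category <- dplyr::coalesce(imaged$risk_category, "low")
  } else {
    imaged$risk_category <- "low"
  }
  n <- nrow(imaged)
  set.seed(child_seed(config$seed, "brain"))
  lp <- qlogis(config$baseline_deviation_prob) +
    config$deviation_coupling * (imaged$risk_category == "high")
  deviant <- runif(n) < plogis(lp)
  centiles <- draw_conditional_centiles(deviant)

  offset <- attr(reference, "offset")
  vols <- vapply(seq_along(.brain_phenotypes), function(j) {
    ph <- .brain_phenotypes[j]
    mu <- interp_reference(reference, ph, imaged$sex, imaged$age, "median")
    sc <- interp_reference(reference, ph, imaged$sex, imaged$age, "scale")
    offset + mu + qnorm(centiles[, j]) * sc
  }, numeric(n))
  colnames(vols) <- .brain_phenotypes

  bind_cols(
    select(imaged, "sample_id", "age", "sex", "risk_category"),
    as_tibble(vols)
  ) |>
    select("sample_id", "age", "sex", "GMV", "sGMV", "WMV", "risk_category")
}

# Three centiles, iid uniform conditional on the deviation indicator
# (rejection sampling; exact conditional distribution).
draw_conditional_centiles <- function(deviant) {
  n <- length(deviant)
  out <- matrix(NA_real_, n, 3)
  todo <- rep(TRUE, n)
  while (any(todo)) {
    k <- sum(todo)
    cand <- matrix(runif(3 * k), k, 3)
    is_dev <- apply(cand < 0.10 | cand > 0.90, 1, any)
    ok <- is_dev == deviant[todo]
    rows <- which(todo)[ok]
    out[rows, ] <- cand[ok, , drop = FALSE]
    todo[rows] <- FALSE
  }
  out
}

# Linear interpolation of one reference curve at given ages.
interp_reference <- function(reference, phenotype, sex, age, what) {
  out <- numeric(length(age))
  for (s in unique(sex)) {
    cur <- reference[reference$phenotype == phenotype & reference$sex == s, ]
    idx <- sex == s
    out[idx] <- approx(cur$age, cur[[what]], xout = age[idx], rule = 1)$y
  }
  out
}
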