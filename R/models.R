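#' Default demographic covariate set
#'
#' Sex, self-identified race, and 10 ancestry principal components — the
#' covariate block that opens every model of the stepwise ladder.
#'
#' @return Character vector of column names.
#' @export
assoc_covariates <- function() c("sex", "race_label", paste0("PC", 1:10))

#' Fit a standardized-effect association model
#'
#' Fits a multivariable linear or logistic regression of one outcome on a
#' set of terms plus demographic covariates, reporting standardized
#' effects. Continuous predictors are z-scored (sample SD); for linear
#' models the outcome is z-scored as well, so a coefficient reads as SDs
#' of outcome per SD of predictor. For logistic models the coefficient is
#' the log-odds change per SD of predictor. Categorical covariates are
#' dummy-coded with the most frequent level as reference. Rows missing any
#' modelled column are dropped (complete-case, with the per-model n
#' recorded in `glance()`).
#'
#' @param data Cohort tibble (typically cohort joined with a risk-score
#'   profile).
#' @param outcome Outcome column name. Linear outcomes should already be
#'   age-normalized ([age_normalize()]).
#' @param terms Character vector of focal predictor column names.
#' @param covariates Covariate column names (default [assoc_covariates()];
#'   may be `character(0)` for an unadjusted model).
#' @param family `"linear"` or `"logistic"`.
#' @param standardize Z-score continuous predictors (and, for linear
#'   models, the outcome) before fitting. Disable only if the table was
#'   standardized upstream.
#' @return A `cnv_fit` object; see [tidy.cnv_fit()] and
#'   [glance.cnv_fit()].
#' @export
fit_assoc <- function(data, outcome, terms,
                      covariates = assoc_covariates(),
                      family = c("linear", "logistic"),
                      standardize = TRUE) {
  family <- match.arg(family)
  rhs <- c(terms, covariates)
  cols <- unique(c(outcome, rhs))
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort(paste("Column(s) not in data:", paste(missing, collapse = ", ")),
          class = "cnvrisk_config_error")
  }
  df <- data[cols]
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df)

  # dummy-code categoricals against the most frequent level; covariates that
  # are constant on this row set (e.g. race within an ancestry subcohort)
  # carry no information and are dropped
  for (col in rhs) {
    if (is.character(df[[col]]) || is.factor(df[[col]])) {
      f <- factor(df[[col]])
      if (nlevels(f) < 2L) {
        if (col %in% terms) {
          abort(paste0("Focal term '", col, "' is constant."),
                class = "cnvrisk_validation_error")
        }
        rhs <- setdiff(rhs, col)
        next
      }
      df[[col]] <- relevel(f, ref = names(sort(table(f), decreasing = TRUE))[1])
    }
  }
  if (standardize) {
    df <- standardize_predictors(df, rhs)
    if (family == "linear") {
      if (sd(df[[outcome]]) == 0) {
        abort("Outcome is constant; cannot standardize.",
              class = "cnvrisk_validation_error")
      }
      df[[outcome]] <- as.numeric(scale(df[[outcome]]))
    }
  }

  fml <- as.formula(paste0(
    "`", outcome, "` ~ ",
    if (length(rhs) == 0L) "1" else paste(sprintf("`%s`", rhs), collapse = " + ")
  ))

  if (family == "linear") {
    k_design <- qr(model.matrix(fml, df))$rank
    if (n <= k_design) {
      abort(sprintf("Too few rows (n = %d) for %d parameters.", n, k_design),
            class = "cnvrisk_validation_error")
    }
    model <- lm(fml, data = df)
    if (any(is.na(coef(model)))) {
      abort(paste("Rank-deficient design; collinear term(s):",
                  paste(names(coef(model))[is.na(coef(model))], collapse = ", ")),
            class = "cnvrisk_validation_error")
    }
    smry <- summary(model)
    ct <- smry$coefficients
    dfres <- model$df.residual
    tcrit <- qt(0.975, dfres)
    tidy_tbl <- tibble(
      term = rownames(ct),
      estimate = unname(ct[, 1]),
      std.error = unname(ct[, 2]),
      statistic = unname(ct[, 3]),
      p.value = pmax(unname(ct[, 4]), .Machine$double.xmin),
      conf.low = unname(ct[, 1] - tcrit * ct[, 2]),
      conf.high = unname(ct[, 1] + tcrit * ct[, 2])
    )
    glance_tbl <- tibble(
      AIC = AIC(model), adj.r.squared = smry$adj.r.squared,
      logLik = as.numeric(logLik(model)), n = n,
      k = length(coef(model))
    )
  } else {
    y <- df[[outcome]]
    if (!all(y %in% c(0, 1))) {
      abort("Logistic outcome must be coded 0/1.",
            class = "cnvrisk_validation_error")
    }
    if (length(unique(y)) < 2L) {
      abort("Logistic outcome has a single class.",
            class = "cnvrisk_validation_error")
    }
    sep_warn <- FALSE
    model <- withCallingHandlers(
      glm(fml, data = df, family = binomial(),
          control = list(epsilon = 1e-10, maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          sep_warn <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    if (sep_warn || any(abs(coef(model)[-1]) > 15, na.rm = TRUE)) {
      abort("Perfect (or quasi-perfect) separation detected; coefficients are unstable.",
            class = "cnvrisk_validation_error")
    }
    if (any(is.na(coef(model)))) {
      abort(paste("Rank-deficient design; collinear term(s):",
                  paste(names(coef(model))[is.na(coef(model))], collapse = ", ")),
            class = "cnvrisk_validation_error")
    }
    ct <- summary(model)$coefficients
    tidy_tbl <- tibble(
      term = rownames(ct),
      estimate = unname(ct[, 1]),
      std.error = unname(ct[, 2]),
      statistic = unname(ct[, 3]),
      p.value = pmax(unname(ct[, 4]), .Machine$double.xmin),
      conf.low = unname(ct[, 1] - 1.96 * ct[, 2]),
      conf.high = unname(ct[, 1] + 1.96 * ct[, 2])
    )
    glance_tbl <- tibble(
      AIC = AIC(model), adj.r.squared = NA_real_,
      logLik = as.numeric(logLik(model)), n = n,
      k = length(coef(model))
    )
  }

  structure(
    list(model = model, tidy = tidy_tbl, glance = glance_tbl,
         outcome = outcome, family = family, terms = terms,
         covariates = covariates),
    class = "cnv_fit"
  )
}

#' @rdname fit_assoc
#' @export
fit_linear <- function(data, outcome, terms,
                       covariates = assoc_covariates(), standardize = TRUE) {
  fit_assoc(data, outcome, terms, covariates, family = "linear",
            standardize = standardize)
}

#' @rdname fit_assoc
#' @export
fit_logistic <- function(data, outcome, terms,
                         covariates = assoc_covariates(), standardize = TRUE) {
  fit_assoc(data, outcome, terms, covariates, family = "logistic",
            standardize = standardize)
}

#' @export
print.cnv_fit <- function(x, ...) {
  cat("<cnv_fit>", x$family, "model of", x$outcome,
      sprintf("(n = %d, AIC = %.1f)\n", x$glance$n, x$glance$AIC))
  print(x$tidy[x$tidy$term %in% x$terms, ], ...)
  invisible(x)
}

#' Tidy per-term results of a fitted association model
#'
#' @param x A `cnv_fit`.
#' @param focal_only Return only the focal terms (drop covariate rows)?
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (standardized), `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @exportS3Method generics::tidy
tidy.cnv_fit <- function(x, focal_only = FALSE, ...) {
  if (!focal_only) return(x$tidy)
  # factor terms expand to term+level coefficient names
  focal <- vapply(x$tidy$term, function(tm) {
    any(tm == x$terms | startsWith(tm, x$terms))
  }, logical(1))
  x$tidy[focal, ]
}

#' Model-level summary of a fitted association model
#'
#' @param x A `cnv_fit`.
#' @param ... Unused.
#' @return One-row tibble: `AIC`, `adj.r.squared` (linear only),
#'   `logLik`, `n`, `k`.
#' @exportS3Method generics::glance
glance.cnv_fit <- function(x, ...) x$glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Benjamini-Hochberg step-up FDR adjustment against a declared family
#'
#' Adjusted p for the i-th smallest raw p is
#' `min_{j >= i}(family_size * p_(j) / j)`, capped at 1 and returned in
#' input order. `family_size` may exceed the vector length, which permits
#' adjusting a reported sub-vector against the full declared comparison
#' family (families are declared, never inferred). Ties are handled by
#' stable ordering, which does not affect the adjusted values.
#'
#' @param pvals Raw p values in (0, 1].
#' @param family_size Declared family size, at least `length(pvals)`.
#' @return Adjusted p values, same order as input.
#' @export
bh_adjust <- function(pvals, family_size = length(pvals)) {
  if (length(pvals) == 0L) return(numeric())
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1)) {
    abort("p values must lie in (0, 1].", class = "cnvrisk_validation_error")
  }
  if (family_size < length(pvals)) {
    abort("`family_size` must be at least length(pvals).",
          class = "cnvrisk_config_error")
  }
  ord <- order(pvals)
  m <- length(pvals)
  stepped <- rev(cummin(rev(family_size * pvals[ord] / seq_len(m))))
  out <- numeric(m)
  out[ord] <- pmin(stepped, 1)
  out
}

#' Fit the stepwise model ladder for one outcome
#'
#' Fits the four nested/union models compared in the main ladder —
#' demographic covariates only; covariates + CNV risk scores; covariates +
#' environmental factors; covariates + environment + CNV scores — and,
#' when `pgs_terms` is supplied, a fifth model adding the polygenic
#' scores. All models are fitted on the identical complete-case row set
#' across the union of all terms, so AIC values are directly comparable;
#' a row-set mismatch is an internal error.
#'
#' @param data Cohort tibble joined with a risk-score profile.
#' @param outcome Age-normalized outcome column.
#' @param cnv_terms CNV risk-score column pair (deletion and duplication
#'   scores of one scheme enter jointly).
#' @param env_terms Environmental stressor columns.
#' @param pgs_terms Optional polygenic-score columns.
#' @param covariates Demographic covariates.
#' @return A `cnv_ladder`: `comparison` tibble (model, n, k, AIC,
#'   adj.r.squared, delta_AIC vs the previous row) plus the list of fits.
#' @export
model_ladder <- function(data, outcome, cnv_terms,
                         env_terms = c("neighborhood_ses", "trauma_count"),
                         pgs_terms = NULL,
                         covariates = assoc_covariates()) {
  all_terms <- unique(c(outcome, covariates, cnv_terms, env_terms, pgs_terms))
  df <- data[all_terms]
  df <- data[complete.cases(df), , drop = FALSE]

  blocks <- list(
    covariates = character(),
    cnv = cnv_terms,
    environment = env_terms,
    environment_cnv = c(env_terms, cnv_terms)
  )
  if (!is.null(pgs_terms)) {
    blocks$environment_cnv_pgs <- c(env_terms, cnv_terms, pgs_terms)
  }
  fits <- purrr::imap(blocks, function(terms, nm) {
    fit_linear(df, outcome, terms, covariates = covariates)
  })
  ns <- vapply(fits, function(f) f$glance$n, numeric(1))
  if (length(unique(ns)) != 1L) {
    abort("Internal error: ladder models fitted on differing row sets.",
          class = "cnvrisk_internal_error")
  }
  comparison <- purrr::imap(fits, function(f, nm) {
    mutate(glance(f), model = nm, .before = 1)
  }) |>
    bind_rows() |>
    mutate(delta_AIC = .data$AIC - dplyr::lag(.data$AIC)) |>
    select("model", "n", "k", "AIC", "adj.r.squared", "delta_AIC")
  structure(list(comparison = comparison, fits = fits, outcome = outcome),
            class = "cnv_ladder")
}

#' @export
print.cnv_ladder <- function(x, ...) {
  cat("<cnv_ladder> outcome:", x$outcome, "\n")
  print(x$comparison, ...)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cnv_ladder <- function(x, ...) {
  purrr::imap(x$fits, function(f, nm) mutate(tidy(f), model = nm, .before = 1)) |>
    bind_rows()
}

#' @exportS3Method generics::glance
glance.cnv_ladder <- function(x, ...) x$comparison

#' Exploratory CNV-by-moderator interaction scan
#'
#' One linear model per (CNV score, moderator) pair: covariates, both main
#' effects, and the product of the two z-scored terms. Interaction p
#' values are Benjamini-Hochberg adjusted jointly within the scan family.
#'
#' @param data Cohort tibble joined with a risk-score profile.
#' @param outcome Age-normalized outcome column.
#' @param cnv_terms CNV risk-score columns.
#' @param moderator_terms Environmental or PGS columns.
#' @param covariates Demographic covariates.
#' @return Tibble, one row per pair: `cnv_term`, `moderator`, the
#'   interaction `estimate`, `std.error`, `statistic`, `p.value`,
#'   `p.adjusted`; full fits in the `fits` attribute.
#' @export
interaction_scan <- function(data, outcome, cnv_terms, moderator_terms,
                             covariates = assoc_covariates()) {
  pairs <- tidyr::expand_grid(cnv_term = cnv_terms, moderator = moderator_terms)
  if (any(pairs$cnv_term == pairs$moderator)) {
    abort("A term cannot interact with itself.",
          class = "cnvrisk_validation_error")
  }
  fits <- purrr::pmap(pairs, function(cnv_term, moderator) {
    df <- standardize_predictors(data, c(cnv_term, moderator))
    df$.interaction <- df[[cnv_term]] * df[[moderator]]
    fit_linear(df, outcome, c(cnv_term, moderator, ".interaction"),
               covariates = covariates)
  })
  rows <- purrr::map2(fits, seq_len(nrow(pairs)), function(f, i) {
    int <- f$tidy[f$tidy$term == ".interaction", ]
    bind_cols(pairs[i, ], select(int, -"term"))
  }) |> bind_rows()
  rows$p.adjusted <- bh_adjust(rows$p.value)
  attr(rows, "fits") <- fits
  rows
}
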