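test_that("a noise-free identity fit returns beta 1 with underflow-safe p", {
  set.seed(1)
  d <- tibble::tibble(y = rnorm(50))
  d$x <- d$y
  f <- suppressWarnings(fit_linear(d, "y", "x", covariates = character()))
  td <- tidy(f, focal_only = TRUE)
  expect_equal(td$estimate, 1, tolerance = 1e-10)
  expect_gt(td$p.value, 0)
  expect_equal(glance(f)$adj.r.squared, 1, tolerance = 1e-10)
})

test_that("linear fits equal the normal-equations oracle on small fixtures", {
  set.seed(2)
  for (rep in 1:5) {
    n <- sample(6:50, 1)
    d <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n))
    d$y <- 0.5 * d$x1 - 0.3 * d$x2 + rnorm(n)
    f <- fit_linear(d, "y", c("x1", "x2"), covariates = character(),
                    standardize = FALSE)
    td <- tidy(f)
    orc <- ols_oracle(cbind(1, d$x1, d$x2), d$y)
    expect_equal(td$estimate, orc$beta, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(td$std.error, orc$se, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(td$statistic, orc$t, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(td$p.value, orc$p, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("type-I error is calibrated at the nominal 5% under the null", {
  set.seed(3)
  pvals <- replicate(800, {
    d <- tibble::tibble(y = rnorm(40), x = rnorm(40))
    tidy(fit_linear(d, "y", "x", covariates = character()),
         focal_only = TRUE)$p.value
  })
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 800))
})

test_that("standardized effects are invariant to affine rescaling of raw variables", {
  set.seed(4)
  d <- tibble::tibble(x = rnorm(200, 10, 4), w = rnorm(200))
  d$y <- 0.4 * d$x + 0.2 * d$w + rnorm(200)
  f1 <- fit_linear(d, "y", c("x", "w"), covariates = character())
  d2 <- dplyr::mutate(d, x = 3 * x + 5, y = 0.5 * y - 2)
  f2 <- fit_linear(d2, "y", c("x", "w"), covariates = character())
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-10)
  expect_equal(tidy(f1)$p.value, tidy(f2)$p.value, tolerance = 1e-10)
  expect_equal(glance(f1)$AIC, glance(f2)$AIC, tolerance = 1e-8)
})

test_that("rank-deficient designs and undersized samples are rejected", {
  set.seed(5)
  d <- tibble::tibble(x = rnorm(30))
  d$x2 <- 2 * d$x
  d$y <- rnorm(30)
  expect_error(fit_linear(d, "y", c("x", "x2"), covariates = character()),
               class = "cnvrisk_validation_error")
  expect_error(fit_linear(d[1:3, ], "y", c("x", "x2"),
                          covariates = character()),
               class = "cnvrisk_validation_error")
})

test_that("logistic fit on a 2x2 table equals the closed-form log odds ratio", {
  d <- tibble::tibble(
    group = rep(c(1, 0), c(59, 861)),
    dev = c(rep(c(1, 0), c(32, 27)), rep(c(1, 0), c(340, 521)))
  )
  f <- fit_logistic(d, "dev", "group", covariates = character())
  beta <- tidy(f, focal_only = TRUE)$estimate
  expect_equal(beta, log((32 * 521) / (27 * 340)), tolerance = 1e-6)
  # intercept equals the low-group log odds
  expect_equal(tidy(f)$estimate[1], log(340 / 521), tolerance = 1e-6)
})

test_that("a null logistic predictor gives beta near 0 and the class-balance intercept", {
  set.seed(6)
  d <- tibble::tibble(y = rbinom(4000, 1, 0.3), x = rnorm(4000))
  f <- fit_logistic(d, "y", "x", covariates = character())
  td <- tidy(f)
  expect_lt(abs(td$estimate[td$term == "x"]), 0.1)
  expect_equal(td$estimate[1], qlogis(mean(d$y)), tolerance = 0.05)
})

test_that("logistic parameter recovery: known coefficient 0.5 at n = 5000", {
  set.seed(7)
  est <- replicate(20, {
    x <- rnorm(5000)
    y <- rbinom(5000, 1, plogis(-1 + 0.5 * x))
    d <- tibble::tibble(y = y, x = x)
    tidy(fit_logistic(d, "y", "x", covariates = character()),
         focal_only = TRUE)$estimate
  })
  expect_lt(abs(mean(est) - 0.5), 3 * sd(est) / sqrt(20))
})

test_that("degenerate logistic inputs error with a diagnostic", {
  d <- tibble::tibble(y = rep(1, 50), x = rnorm(50))
  expect_error(fit_logistic(d, "y", "x", covariates = character()),
               "single class", class = "cnvrisk_validation_error")
  d2 <- tibble::tibble(x = c(rnorm(25, -3), rnorm(25, 3)))
  d2$y <- as.numeric(d2$x > 0)
  expect_error(fit_logistic(d2, "y", "x", covariates = character()),
               "separation", class = "cnvrisk_validation_error")
})

test_that("BH step-up matches hand computation, the brute-force oracle, and p.adjust", {
  expect_equal(bh_adjust(0.03, family_size = 1), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  set.seed(8)
  for (rep in 1:20) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_adjust(p), bf_bh(p))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
    m <- length(p) + sample(0:10, 1)
    expect_equal(bh_adjust(p, m), bf_bh(p, m))
  }
})

test_that("BH output is monotone along the sorted raw order, bounded by 1, and validates input", {
  set.seed(9)
  p <- runif(50)
  adj <- bh_adjust(p, family_size = 80)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_true(all(adj <= 1 & adj > 0))
  expect_error(bh_adjust(c(0.1, 0)), class = "cnvrisk_validation_error")
  expect_error(bh_adjust(c(0.1, 1.2)), class = "cnvrisk_validation_error")
  expect_error(bh_adjust(runif(10), family_size = 5),
               class = "cnvrisk_config_error")
})

test_that("the model ladder fits nested models on one row set with comparable AIC", {
  cfg <- small_config()
  genes <- sim_gene_table(cfg)
  prof <- transform_scores(score_samples(filter_cnvs(sim_cnv_calls(cfg, genes)),
                                         genes,
                                         samples = sprintf("S%05d", 1:400)))
  dat <- dplyr::left_join(sim_cohort(cfg, prof), prof, by = "sample_id")
  lad <- model_ladder(dat, "overall_accuracy",
                      cnv_terms = c("del_sum_pHI", "dup_sum_pTS"))
  expect_equal(lad$comparison$model,
               c("covariates", "cnv", "environment", "environment_cnv"))
  expect_equal(length(unique(lad$comparison$n)), 1)
  expect_true(all(is.finite(lad$comparison$AIC)))
  expect_s3_class(autoplot(lad), "ggplot")
})

test_that("under an all-null effect map the ladder's adjusted r2 values sit near zero", {
  cfg <- sim_config(n_samples = 2000, n_genes = 2000, seed = 31,
                    effect_map = list(), n_imaged = 100)
  genes <- sim_gene_table(cfg)
  prof <- transform_scores(score_samples(filter_cnvs(sim_cnv_calls(cfg, genes)),
                                         genes,
                                         samples = sprintf("S%05d", 1:2000)))
  dat <- dplyr::left_join(sim_cohort(cfg, prof), prof, by = "sample_id")
  lad <- model_ladder(dat, "overall_accuracy",
                      cnv_terms = c("del_sum_pHI", "dup_sum_pTS"))
  expect_true(all(abs(lad$comparison$adj.r.squared) < 0.01))
})

test_that("interaction scan controls the null, detects strong products, and rejects self-pairs", {
  set.seed(10)
  n <- 1500
  d <- tibble::tibble(cnv = rnorm(n), ses = rnorm(n), trauma = rnorm(n))
  d$y <- 0.1 * d$cnv + 0.2 * d$ses + rnorm(n)
  scan0 <- interaction_scan(d, "y", "cnv", c("ses", "trauma"),
                            covariates = character())
  expect_equal(sum(scan0$p.adjusted < 0.05), 0)

  d$y2 <- 0.1 * d$cnv + 0.2 * d$ses + 0.3 * scale(d$cnv) * scale(d$ses) + rnorm(n)
  scan1 <- interaction_scan(d, "y2", "cnv", c("ses", "trauma"),
                            covariates = character())
  hit <- scan1[scan1$moderator == "ses", ]
  expect_lt(hit$p.adjusted, 0.05)

  expect_error(interaction_scan(d, "y", "cnv", c("cnv", "ses"),
                                covariates = character()),
               class = "cnvrisk_validation_error")
})
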