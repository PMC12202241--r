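test_that("SUR with identical regressors collapses to equation-wise OLS", {
  at <- test_table()
  covs <- c("arm", "gender_identity", "age_years", "gsi_t0")
  spec <- sur_spec("QALY_EQ5D", cost_covariates = covs, effect_covariates = covs)
  fit <- fit_sur(at, spec)
  d <- fit$model$data
  ols_cost <- coef(lm(spec$cost_formula, d))
  ols_eff <- coef(lm(spec$effect_formula, d))
  expect_equal(unname(fit$coefficients$cost), unname(ols_cost), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients$effect), unname(ols_eff), tolerance = 1e-8)
})

test_that("with uncorrelated errors FGLS tracks OLS on large samples", {
  set.seed(404)
  n <- 4000
  d <- tibble::tibble(
    arm = sample(c("IG", "CG"), n, replace = TRUE),
    age_years = rnorm(n, 27, 8),
    x_extra = rnorm(n),
    cost_t1 = 500 * (arm == "IG") + 10 * age_years + rnorm(n, 0, 300),
    qaly = 0.01 * (arm == "IG") + 0.001 * x_extra + rnorm(n, 0, 0.05)
  )
  spec <- sur_spec("QALY_EQ5D",
                   cost_covariates = c("arm", "age_years"),
                   effect_covariates = c("arm", "x_extra"))
  fit <- fit_sur(d, spec)
  ols_cost <- coef(lm(cost_t1 ~ arm + age_years, d))
  expect_equal(unname(fit$coefficients$cost), unname(ols_cost), tolerance = 1e-3)
  expect_lt(abs(stats::cov2cor(fit$sigma)[1, 2]), 0.05)
})

test_that("the one-way F test equals the squared two-sample t statistic", {
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(sample(10:60, 1), mean = runif(1, -2, 2))
    b <- rnorm(sample(10:60, 1), mean = runif(1, -2, 2))
    cmp <- unadjusted_comparison(a, b)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(cmp$f_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(cmp$p_value, tt$p.value, tolerance = 1e-10)
    expect_equal(cmp$difference, mean(a) - mean(b), tolerance = 1e-12)
  }
  expect_error(unadjusted_comparison(1, c(1, 2)),
               class = "trialcea_estimation_error")
  sep <- unadjusted_comparison(c(1, 1, 1), c(0, 0, 0))
  expect_equal(sep$difference, 1)
  expect_equal(sep$p_value, 0)
})

test_that("residual covariance is symmetric positive semi-definite", {
  at <- test_table()
  for (eff in c("QALY_EQ5D", "QALY_VAS", "RELIABLE_IMPROVEMENT")) {
    fit <- fit_sur(at, sur_spec(eff))
    expect_equal(fit$sigma, t(fit$sigma))
    expect_true(all(eigen(fit$sigma, only.values = TRUE)$values > -1e-12))
  }
})

test_that("rank-deficient designs fail naming the collinear column", {
  at <- test_table()
  at$age_copy <- at$age_years
  spec <- sur_spec("QALY_EQ5D",
                   cost_covariates = c("arm", "age_years", "age_copy"))
  err <- expect_error(fit_sur(at, spec), class = "trialcea_estimation_error")
  expect_match(conditionMessage(err), "age_copy")
  expect_error(fit_sur(at[1:4, ], sur_spec("QALY_EQ5D")),
               class = "trialcea_estimation_error")
})

test_that("adjusted contrasts equal the arm coefficient and pass the null check", {
  at <- test_table()
  fit <- fit_sur(at, sur_spec("QALY_EQ5D"))
  adj <- adjusted_contrast(fit)
  expect_equal(adj$difference, adj$mean_ig - adj$mean_cg, tolerance = 1e-9)
  expect_equal(adj$difference[1],
               unname(fit$coefficients$cost["armIG"]), tolerance = 1e-9)
  expect_equal(adj$difference[2],
               unname(fit$coefficients$effect["armIG"]), tolerance = 1e-9)

  # null-effect world: the adjusted differences sit within 3 SEs of zero
  null_cfg <- generator_config(
    n_ig = 300, n_cg = 300, seed = 83,
    utility_baseline_mean = c(IG = 0.85, CG = 0.85),
    utility_effect_t1 = c(IG = 0, CG = 0),
    vas_baseline_mean = c(IG = 70, CG = 70),
    vas_effect_t1 = c(IG = 0, CG = 0),
    reliable_improvement_prob = c(IG = 0.15, CG = 0.15),
    ig_extra_cost_mean = 1e-9, intervention_cost_mean = 0,
    intervention_cost_sd = 1e-9
  )
  null_at <- build_analysis_table(generate_cohort(null_cfg),
                                  default_unit_costs())
  null_adj <- adjusted_contrast(fit_sur(null_at, sur_spec("QALY_EQ5D")))
  expect_true(all(abs(null_adj$difference) < 3 * null_adj$se))
})

test_that("the gender-identity reference category does not change contrasts", {
  at <- test_table()
  fit_a <- fit_sur(at, sur_spec("QALY_EQ5D"))
  at2 <- at
  at2$gender_identity <- factor(
    at2$gender_identity,
    levels = c("nonbinary", "trans_masculine", "trans_feminine")
  )
  fit_b <- fit_sur(at2, sur_spec("QALY_EQ5D"))
  expect_equal(unname(fit_a$coefficients$cost["armIG"]),
               unname(fit_b$coefficients$cost["armIG"]), tolerance = 1e-9)
  expect_equal(unname(fit_a$coefficients$effect["armIG"]),
               unname(fit_b$coefficients$effect["armIG"]), tolerance = 1e-9)
})

test_that("the linear probability model yields adjusted proportions in [0, 1]", {
  at <- test_table()
  adj <- adjusted_contrast(fit_sur(at, sur_spec("RELIABLE_IMPROVEMENT")))
  props <- unlist(adj[adj$outcome == "RELIABLE_IMPROVEMENT",
                      c("mean_ig", "mean_cg")])
  expect_true(all(props >= 0 & props <= 1))
})

test_that("tidy and glance summarize the fit in broom shape", {
  fit <- fit_sur(test_table(), sur_spec("QALY_EQ5D"))
  td <- tidy(fit)
  expect_true(all(c("equation", "term", "estimate", "std.error", "p.value")
                  %in% names(td)))
  expect_equal(nrow(td),
               length(fit$coefficients$cost) + length(fit$coefficients$effect))
  gl <- glance(fit)
  expect_equal(gl$n, fit$n_used)
  expect_true(abs(gl$resid_correlation) <= 1)
})
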