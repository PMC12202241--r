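make_draws <- function(dc, de, point = c(delta_cost = mean(dc),
                                         delta_effect = mean(de))) {
  structure(
    tibble::tibble(replicate = seq_along(dc), delta_cost = dc, delta_effect = de),
    B = length(dc), seed = 0, point_estimate = point, n = length(dc),
    n_failed_refits = 0L,
    class = c("cea_draws", class(tibble::tibble()))
  )
}

test_that("draw sets are reproducible and seed-sensitive", {
  at <- test_table()
  spec <- sur_spec("QALY_EQ5D")
  d1 <- bootstrap_contrasts(at, spec, B = 60, seed = 9)
  d2 <- bootstrap_contrasts(at, spec, B = 60, seed = 9)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_identical(attr(d1, "point_estimate"), attr(d2, "point_estimate"))
  d3 <- bootstrap_contrasts(at, spec, B = 60, seed = 10)
  expect_false(identical(d1$delta_cost, d3$delta_cost))
  expect_equal(attr(d1, "n_failed_refits"), 0L)
  # stratified resampling is likewise deterministic
  s1 <- bootstrap_contrasts(at, spec, B = 30, seed = 4, stratify_by_arm = TRUE)
  s2 <- bootstrap_contrasts(at, spec, B = 30, seed = 4, stratify_by_arm = TRUE)
  expect_identical(s1$delta_cost, s2$delta_cost)
})

test_that("bootstrap spread agrees with the analytic robust standard error", {
  at <- test_table()
  spec <- sur_spec("QALY_EQ5D")
  draws <- bootstrap_contrasts(at, spec, B = 600, seed = 5)
  fit <- fit_sur(at, spec)
  se_analytic <- adjusted_contrast(fit)$se[1]
  expect_lt(abs(sd(draws$delta_cost) - se_analytic) / se_analytic, 0.25)
})

test_that("a resample that is the identity reproduces the point estimate", {
  # all-identical rows make every resample the identity resample
  at <- test_table()[rep(1, 30), ]
  at$arm <- rep(c("IG", "CG"), 15)
  at$cost_t1 <- ifelse(at$arm == "IG", 100, 50) # degenerate but full rank
  at$qaly <- ifelse(at$arm == "IG", 0.2, 0.1)
  spec <- sur_spec("QALY_EQ5D", cost_covariates = "arm",
                   effect_covariates = "arm")
  draws <- bootstrap_contrasts(at, spec, B = 5, seed = 2)
  expect_true(all(abs(draws$delta_cost - 50) < 1e-9))
  expect_true(all(abs(draws$delta_effect - 0.1) < 1e-9))
  expect_equal(unname(attr(draws, "point_estimate")["delta_cost"]), 50)
})

test_that("BCa with z0 = a = 0 reduces exactly to the percentile interval", {
  dc <- c(-(50:1), 50:1) # symmetric around the point estimate 0
  draws <- make_draws(dc, rep(0.01, 100), point = c(delta_cost = 0,
                                                    delta_effect = 0.01))
  ci <- bca_interval(draws, "delta_cost", jackknife = c(-1, 0, 1), level = 0.9)
  expect_equal(ci$z0, 0)
  expect_equal(ci$acceleration, 0)
  expect_equal(c(ci$lower, ci$upper),
               unname(quantile(dc, c(0.05, 0.95), type = 7)), tolerance = 1e-12)
})

test_that("BCa endpoints match an independently coded textbook oracle", {
  # independent oracle: straight transcription of the BCa construction
  bca_oracle <- function(th, t0, jack, level) {
    z0 <- qnorm(mean(th < t0))
    m <- mean(jack)
    a <- sum((m - jack)^3) / (6 * sum((m - jack)^2)^1.5)
    zq <- qnorm(c((1 - level) / 2, 1 - (1 - level) / 2))
    adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
    quantile(th, adj, type = 7, names = FALSE)
  }
  set.seed(77)
  for (i in 1:10) {
    th <- rlnorm(1000, 7, 0.6) # skewed draw cloud
    t0 <- quantile(th, runif(1, 0.35, 0.65), names = FALSE)
    jack <- rlnorm(80, 7, 0.5)
    draws <- make_draws(th, rep(0.01, 1000),
                        point = c(delta_cost = t0, delta_effect = 0.01))
    ci <- bca_interval(draws, "delta_cost", jackknife = jack, level = 0.95)
    expect_equal(c(ci$lower, ci$upper), bca_oracle(th, t0, jack, 0.95),
                 tolerance = 1e-9)
  }
})

test_that("degenerate draw sets yield a flagged degenerate interval", {
  draws <- make_draws(rep(42, 20), rep(0.1, 20))
  expect_warning(
    ci <- bca_interval(draws, "delta_cost", jackknife = c(1, 2, 3)),
    "identical"
  )
  expect_equal(ci$lower, 42)
  expect_equal(ci$upper, 42)
})

test_that("draw sets serialize to CSV + JSON sidecar and restore losslessly", {
  at <- test_table()
  draws <- bootstrap_contrasts(at, sur_spec("QALY_EQ5D"), B = 25, seed = 31)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_draws(draws, tmp)
  back <- read_draws(tmp)
  expect_equal(as.data.frame(back), as.data.frame(draws), tolerance = 1e-12)
  expect_equal(attr(back, "point_estimate"), attr(draws, "point_estimate"),
               tolerance = 1e-12)
  expect_equal(attr(back, "B"), 25)
})
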