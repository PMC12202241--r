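test_that("profile scoring hits the documented extremes and enumerates all states", {
  vs <- synthetic_value_set()
  expect_equal(score_profile("11111", vs), 1.0, tolerance = 1e-12)
  expect_equal(score_profile("55555", vs), -0.661, tolerance = 1e-9)
  expect_identical(attr(vs, "floor"), score_profile("55555", vs))

  profs <- all_profiles()
  expect_length(unique(profs), 3125L)
  scores <- score_profile(profs, vs)
  expect_equal(max(scores), 1.0, tolerance = 1e-12)
  expect_equal(min(scores), -0.661, tolerance = 1e-9)
  expect_identical(profs[which.max(scores)], "11111")
  expect_identical(profs[which.min(scores)], "55555")

  expect_error(score_profile("11161", vs), class = "trialcea_validation_error")
  expect_error(score_profile("1111", vs), class = "trialcea_validation_error")
})

test_that("worsening any single dimension never raises the index", {
  vs <- synthetic_value_set()
  set.seed(42)
  profs <- sample(all_profiles(), 200)
  for (p in profs) {
    digits <- as.integer(strsplit(p, "")[[1]])
    for (d in 1:5) {
      if (digits[d] == 5) next
      worse <- digits
      worse[d] <- worse[d] + 1L
      expect_lte(score_profile(paste(worse, collapse = ""), vs),
                 score_profile(p, vs))
    }
  }
})

test_that("value-set round trip and invariant checks", {
  vs <- synthetic_value_set()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_value_set(vs, tmp)
  back <- read_value_set(tmp)
  expect_equal(score_profile(all_profiles()[c(1, 500, 3125)], back),
               score_profile(all_profiles()[c(1, 500, 3125)], vs),
               tolerance = 1e-12)
  # a decrement that increases with level is rejected
  bad <- tibble::as_tibble(vs)
  bad$decrement[bad$dimension == "MO" & bad$level == 5] <- -0.01
  expect_error(value_set(bad), class = "trialcea_validation_error")
})

test_that("QALY trapezoid reproduces the worked horizon values", {
  expect_equal(round(qaly_auc(1, 1), 2), 0.33)
  expect_equal(round(qaly_auc(-0.661, -0.661), 2), -0.22)
  expect_equal(round(qaly_auc(0.83, 0.85), 2), 0.28)
  expect_equal(qaly_auc(1, 1, horizon_months = 12), 1)
  expect_error(qaly_auc(0.5, 0.5, horizon_months = 0),
               class = "trialcea_config_error")
  expect_error(qaly_auc(1.2, 0.5), class = "trialcea_validation_error")
})

test_that("QALYs are monotone in each utility and linear in the horizon", {
  set.seed(7)
  u <- runif(50, -0.661, 1)
  v <- runif(50, -0.661, 1)
  eps <- 0.05
  shift_ok <- u + eps <= 1
  expect_true(all(qaly_auc(pmin(u + eps, 1), v) >= qaly_auc(u, v)))
  expect_true(all(qaly_auc(u, pmin(v + eps, 1)) >= qaly_auc(u, v)))
  expect_equal(qaly_auc(u, v, 8), 2 * qaly_auc(u, v, 4), tolerance = 1e-12)
})

test_that("EQ-VAS QALYs rescale by 100 and match hand arithmetic", {
  expect_equal(vas_qaly(100, 100), 1 / 3, tolerance = 1e-12)
  expect_equal(vas_qaly(0, 0), 0)
  expect_equal(round(vas_qaly(68.52, 70.07), 4), 0.2310)
  expect_error(vas_qaly(120, 50), class = "trialcea_validation_error")
})

test_that("reliable-change threshold matches the Jacobson-Truax formula", {
  expect_equal(rci_threshold(), 5.46)
  expect_equal(rci_threshold(rci_params(reliability = 1)), 0)
  expect_equal(rci_threshold(rci_params(reference_sd = 10, reliability = 0.84)),
               11.09)
  # unrounded value is available via the rounding control
  expect_equal(rci_threshold(rci_params(rounding = 4)), 5.4563, tolerance = 1e-4)
  expect_error(rci_params(reliability = 1.1), class = "trialcea_validation_error")
})

test_that("reliable improvement is inclusive at the threshold and shift-invariant", {
  expect_true(reliable_improvement(20, 14.54))        # reduction exactly 5.46
  expect_false(reliable_improvement(20, 14.55))
  expect_false(reliable_improvement(20, 20))
  expect_false(reliable_improvement(10, 16))          # deterioration
  set.seed(3)
  g0 <- runif(100, 10, 50)
  g1 <- g0 + runif(100, -15, 10)
  g1 <- pmin(pmax(g1, 0), 72)
  base <- reliable_improvement(g0, g1)
  shifted <- reliable_improvement(g0 + 5, g1 + 5)
  expect_identical(base, shifted)
})

test_that("add_health_effects scores profiles where the index is missing", {
  vs <- synthetic_value_set()
  co <- tibble::as_tibble(hand_cohort())
  co$eq5d_profile_t0 <- c("11111", NA, "21121")
  co$eq5d_index_t0[1] <- NA
  co <- as_cohort(co)
  out <- add_health_effects(co, vs = vs)
  expect_equal(out$eq5d_index_t0[1], 1.0)            # filled from profile
  expect_equal(out$eq5d_index_t0[3], 0.85)           # existing index untouched
  expect_equal(out$qaly, qaly_auc(out$eq5d_index_t0, out$eq5d_index_t1))
  expect_identical(out$reliable_improvement, c(TRUE, FALSE, FALSE))
})
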