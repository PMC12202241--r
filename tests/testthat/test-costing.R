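test_that("CPI inflation is proportional, invertible and strict about years", {
  cpi <- tibble::tibble(year = 2018:2020, index = c(100, 102.5, 105))
  expect_equal(inflate(100, 2019, 2019, cpi), 100)
  expect_equal(inflate(100, 2018, 2020, cpi), 105)
  set.seed(5)
  x <- runif(20, 0, 5000)
  expect_equal(inflate(inflate(x, 2018, 2020, cpi), 2020, 2018, cpi), x,
               tolerance = 1e-12)
  expect_error(inflate(100, 2010, 2020, cpi), class = "trialcea_config_error")
})

test_that("presenteeism and indirect costs follow the human-capital rules", {
  expect_equal(productivity_days_lost(10, 37), 0)
  expect_equal(productivity_days_lost(0, 20), 20)
  expect_equal(productivity_days_lost(5, 20), 10)
  expect_error(productivity_days_lost(11, 5), class = "trialcea_validation_error")

  uc <- tiny_unit_costs() # wage 25 euro/h, 8 h days
  expect_equal(indirect_cost(0, 0, uc), 0)
  expect_equal(indirect_cost(1, 0, uc), 200)
  a <- indirect_cost(2, 3, uc)
  expect_equal(a, indirect_cost(2, 0, uc) + indirect_cost(0, 3, uc))
})

test_that("the hand-computed participant costs out exactly by perspective", {
  co <- hand_cohort()
  uc <- tiny_unit_costs()
  # A at follow-up: 2 GP x 30 = 60; 4 h informal care x 25 = 100;
  # indirect: 1 day absent + (1 - 5/10) * 20 days = 11 days x 8 h x 25
  pp <- cost_participant(co[1, ], "T1", uc, "PP")
  sp <- cost_participant(co[1, ], "T1", uc, "SP")
  expect_equal(pp$total, 60)
  expect_equal(sp$cost_gp, 60)
  expect_equal(sp$cost_informal_care, 100)
  expect_equal(sp$indirect_cost, 11 * 8 * 25)
  expect_equal(sp$total, 160 + 2200)
  # B: no service use, IG at follow-up with intervention costs only
  zero <- tibble::as_tibble(co)[2, ]
  zero$ru_t1_gp <- 0
  zero$ru_t0_informal_care <- 0
  zero$intervention_cost_t1 <- 734
  zero <- as_cohort(zero)
  expect_equal(cost_participant(zero, "T1", uc, "PP")$total,
               734 + 0) # intervention costs are payer costs
  expect_equal(cost_participant(zero, "T1", uc, "SP")$total, 734)
  # C: control arm never carries intervention costs
  expect_equal(cost_participant(co[3, ], "T1", uc, "PP")$total, 30)
})

test_that("unknown resource categories fail loudly, naming the category", {
  co <- tibble::as_tibble(hand_cohort())
  co$ru_t1_acupuncture <- c(1, 0, 0)
  co <- as_cohort(co)
  err <- expect_error(cost_cohort(co, tiny_unit_costs(), "SP"),
                      class = "trialcea_config_error")
  expect_match(conditionMessage(err), "acupuncture")
})

test_that("totals are additive, perspective-monotone and missing-aware", {
  co <- test_cohort()
  uc <- default_unit_costs()
  sp <- cost_cohort(co, uc, "SP")
  pp <- cost_cohort(co, uc, "PP")
  cat_cols <- grep("^cost_", names(sp), value = TRUE)
  recomposed <- rowSums(sp[, cat_cols]) + sp$intervention_cost + sp$indirect_cost
  expect_equal(sp$total, recomposed, tolerance = 1e-6)
  expect_true(all(pp$total <= sp$total + 1e-9))
  # removing a category removes exactly its contribution
  keep <- setdiff(uc$entries$category, "transportation")
  sub <- cost_cohort(co, uc, "SP", categories = keep)
  expect_equal(sub$total, sp$total - sp$cost_transportation, tolerance = 1e-9)
  # mental-health scope reproduces the subset sum
  mh <- uc$entries$category[uc$entries$mental_health]
  mh_costs <- cost_cohort(co, uc, "SP", categories = mh, include_indirect = FALSE)
  expect_equal(mh_costs$total,
               rowSums(sp[, paste0("cost_", mh)]) + sp$intervention_cost,
               tolerance = 1e-9)
  # a missing quantity propagates to a missing total, never a zero
  co2 <- tibble::as_tibble(co)
  co2$ru_t1_medication[5] <- NA
  co2 <- as_cohort(co2)
  sp2 <- cost_cohort(co2, uc, "SP", windows = "T1")
  expect_true(is.na(sp2$total[5]))
})

test_that("winsorization matches a brute-force oracle and is idempotent", {
  expect_equal(winsorize_totals(rep(7, 10)), rep(7, 10))
  v <- as.numeric(1:100)
  w <- winsorize_totals(v, 95)
  cap <- 1 + 0.95 * 99 # type-7 quantile of 1..100, by hand
  expect_equal(max(w), cap)
  expect_equal(w[v <= cap], v[v <= cap])

  # independent sorted-array oracle on random heavy-tailed data
  oracle <- function(x, p) {
    s <- sort(x)
    h <- (length(s) - 1) * p + 1
    lo <- floor(h)
    q <- s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
    ifelse(x > q, q, x)
  }
  set.seed(11)
  for (i in 1:20) {
    x <- rlnorm(sample(20:200, 1), 6, 1.5)
    w1 <- winsorize_totals(x, 95)
    expect_equal(w1, oracle(x, 0.95), tolerance = 1e-10)
    expect_lte(mean(w1), mean(x))
  }
  # exact idempotence: under the linear-interpolation quantile convention the
  # fixed point is exact whenever the percentile lands on an order statistic,
  # i.e. 0.95 * (n - 1) is an integer
  for (n in c(21, 61, 101, 181)) {
    x <- rlnorm(n, 6, 1.5)
    w1 <- winsorize_totals(x, 95)
    expect_equal(winsorize_totals(w1, 95), w1, tolerance = 1e-12)
  }
  expect_error(winsorize_totals(numeric(0)), class = "trialcea_validation_error")
})

test_that("the bundled unit-cost and CPI tables load through the CSV reader", {
  uc <- read_unit_costs(
    system.file("extdata", "unit_costs_synthetic.csv", package = "trialcea"),
    cpi_path = system.file("extdata", "cpi_synthetic.csv", package = "trialcea")
  )
  ref <- default_unit_costs()
  expect_equal(uc$entries, ref$entries)
  expect_equal(uc$cpi, ref$cpi)
  expect_error(read_unit_costs("no-such-file.csv"), class = "trialcea_io_error")
})
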