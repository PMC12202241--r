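# Shared fixtures, all built in code.

# minimal unit-cost table for hand-computed examples: one payer-covered
# contact category and informal care (valued at the care wage, outside the
# payer perspective)
tiny_unit_costs <- function() {
  unit_cost_table(
    tibble::tibble(
      category = c("gp", "informal_care"),
      unit = c("contact", "care_hour"),
      euro_per_unit = c(30, NA),
      price_year = c(2020, 2020),
      mental_health = c(TRUE, FALSE),
      payer = c(TRUE, FALSE)
    ),
    cpi = tibble::tibble(year = c(2019, 2020), index = c(100, 105)),
    target_year = 2020,
    care_wage_per_hour = 25, gross_wage_per_hour = 25, hours_per_workday = 8
  )
}

# three hand-written participants; A carries the worked costing example
# (2 GP contacts + 4 h informal care at follow-up)
hand_cohort <- function() {
  as_cohort(tibble::tibble(
    participant_id = c("A", "B", "C"),
    arm = c("IG", "IG", "CG"),
    age_years = c(25, 30, 28),
    gender_identity = c("trans_masculine", "nonbinary", "trans_feminine"),
    eq5d_index_t0 = c(0.80, 0.90, 0.85),
    eq5d_index_t1 = c(0.85, 0.88, 0.80),
    eq_vas_t0 = c(70, 80, 75),
    eq_vas_t1 = c(72, 78, 70),
    gsi_t0 = c(20, 30, 25),
    gsi_t1 = c(14.54, 28, 26),
    ru_t0_gp = c(1, 0, 2),
    ru_t1_gp = c(2, 0, 1),
    ru_t0_informal_care = c(0, 2, 0),
    ru_t1_informal_care = c(4, 0, 0),
    work_days_absent_t1 = c(1, 0, 2),
    work_days_present_t1 = c(20, 40, 30),
    work_performance_t1 = c(5, 10, 8),
    intervention_cost_t1 = c(0, 500, 0),
    flag_intention_to_treat = TRUE,
    flag_analysis_population = TRUE,
    flag_per_protocol = c(TRUE, TRUE, FALSE)
  ))
}

# moderate synthetic cohort reused across regression/bootstrap tests
test_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(generator_config(seed = 20240601))
    }
    cache
  }
})

test_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_analysis_table(test_cohort(), default_unit_costs(),
                                     synthetic_value_set(), analysis_config())
    }
    cache
  }
})
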