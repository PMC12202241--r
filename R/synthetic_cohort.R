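#' Generator configuration for synthetic two-arm trials
#'
#' The defaults state the world the generator emulates: a two-arm trial of
#' 88 intervention (IG) vs 80 waiting-list control (CG) participants with
#' baseline EQ-5D-5L utilities around 0.83/0.87 (SD 0.19), right-skewed
#' zero-inflated category costs whose 6-month baseline societal total is
#' roughly 3400-3700 euros with an SE of 650-800 euros at n about 84,
#' reliable-improvement probabilities on the BSI-18 GSI of 0.23 (IG) vs
#' 0.09 (CG), and a follow-up cost increment of about 1390 euros in the IG
#' composed of roughly 656 euros of additional service use plus a fixed
#' intervention cost averaging 734 euros (SD 94, so the SE at n = 88 is the
#' reported 10 euros).
#'
#' Costs are drawn per category as zero-inflated lognormals; a shared
#' latent Gaussian factor with loading `cost_effect_correlation` ties
#' utilities and costs together. GSI change is a mixture: with the
#' configured arm probability a responder draws a reduction at or above the
#' reliable-change threshold, otherwise change is a truncated normal kept
#' strictly below it, so the classification margins equal the configured
#' probabilities exactly.
#'
#' @param n_ig,n_cg Arm sizes.
#' @param seed Master seed; one substream per participant is derived from
#'   it, so participant `i` is identical under changed `n`.
#' @param utility_baseline_mean,utility_sd,utility_effect_t1,utility_change_sd
#'   Baseline utility means per arm (named `IG`, `CG`), their SD, additive
#'   follow-up change per arm, and the SD of that change.
#' @param vas_baseline_mean,vas_sd,vas_effect_t1,vas_change_sd EQ-VAS
#'   analogues on the 0-100 scale.
#' @param gsi_baseline_mean,gsi_sd,gsi_change_sd Baseline BSI-18 GSI mean
#'   and SD, and the SD of non-responder change.
#' @param responder_margin_sd SD of the half-normal margin a responder's
#'   reduction adds above the threshold.
#' @param reliable_improvement_prob Named per-arm responder probabilities.
#' @param rci [rci_params()] defining the reliable-change threshold.
#' @param cost_category_params Tibble `category`, `p_zero`, `meanlog`,
#'   `sdlog` of 6-month-window quantities.
#' @param t1_use_factor Multiplier on follow-up quantity means beyond the
#'   window-length ratio; the default 0.40 encodes the waiting-list-design
#'   restraint in service use seen at follow-up.
#' @param ig_extra_cost_mean Mean euro value of additional IG service use at
#'   follow-up, injected as extra `ig_extra_category` quantity (gamma,
#'   shape 4).
#' @param ig_extra_category Category receiving the IG increment.
#' @param intervention_cost_mean,intervention_cost_sd Fixed per-IG-participant
#'   intervention cost distribution (normal, floored at 0).
#' @param cost_effect_correlation Loading of the shared latent factor in
#'   `(-1, 1)`; a modelling choice (no joint cost-effect distribution is
#'   observable from published summaries), default 0.2.
#' @param gender_identity_probs Simplex over trans_masculine, trans_feminine,
#'   nonbinary.
#' @param age_mean,age_sd Age distribution (years, truncated at 18).
#' @param p_any_absence,absence_meanlog,absence_sdlog Zero-inflated lognormal
#'   work-absence days over the follow-up window.
#' @param days_present_mean,days_present_sd Days at work (normal, >= 0).
#' @param work_performance_mean,work_performance_sd 0-10 performance rating
#'   (normal, clipped).
#' @param per_protocol_prob Probability a participant remains per-protocol.
#' @param profile_mode Draw 5-digit EQ-5D-5L profiles and score them through
#'   `vs` instead of simulating the index directly.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(
    n_ig = 88, n_cg = 80, seed = 1,
    utility_baseline_mean = c(IG = 0.83, CG = 0.87),
    utility_sd = 0.19,
    utility_effect_t1 = c(IG = 0.02, CG = -0.03),
    utility_change_sd = 0.15,
    vas_baseline_mean = c(IG = 68.52, CG = 72.73),
    vas_sd = 21,
    vas_effect_t1 = c(IG = 1.55, CG = -2.28),
    vas_change_sd = 10,
    gsi_baseline_mean = 25, gsi_sd = 12, gsi_change_sd = 5,
    responder_margin_sd = 4,
    reliable_improvement_prob = c(IG = 0.23, CG = 0.09),
    rci = rci_params(),
    cost_category_params = default_cost_category_params(),
    t1_use_factor = 0.40,
    ig_extra_cost_mean = 656,
    ig_extra_category = "medical_counseling",
    intervention_cost_mean = 734, intervention_cost_sd = 94,
    cost_effect_correlation = 0.2,
    gender_identity_probs = c(trans_masculine = 0.434, trans_feminine = 0.339,
                              nonbinary = 0.227),
    age_mean = 26.8, age_sd = 10,
    p_any_absence = 0.35, absence_meanlog = log(3) - 0.18, absence_sdlog = 0.6,
    days_present_mean = 35, days_present_sd = 12,
    work_performance_mean = 9.5, work_performance_sd = 0.8,
    per_protocol_prob = 0.96,
    profile_mode = FALSE) {
  cfg <- as.list(environment())
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_ig < 1 || cfg$n_cg < 1) {
    stop_trialcea("arm sizes must be positive.", "trialcea_config_error")
  }
  probs <- c(cfg$reliable_improvement_prob, cfg$p_any_absence,
             cfg$per_protocol_prob, cfg$gender_identity_probs,
             cfg$cost_category_params$p_zero)
  if (any(probs < 0 | probs > 1)) {
    stop_trialcea("all probabilities must lie in [0, 1].", "trialcea_config_error")
  }
  if (abs(sum(cfg$gender_identity_probs) - 1) > 1e-9) {
    stop_trialcea("gender_identity_probs must sum to 1.", "trialcea_config_error")
  }
  sds <- c(cfg$utility_sd, cfg$utility_change_sd, cfg$vas_sd, cfg$vas_change_sd,
           cfg$gsi_sd, cfg$gsi_change_sd, cfg$responder_margin_sd,
           cfg$age_sd, cfg$cost_category_params$sdlog)
  if (any(sds <= 0)) {
    stop_trialcea("all standard deviations must be > 0.", "trialcea_config_error")
  }
  if (abs(cfg$cost_effect_correlation) >= 1) {
    stop_trialcea("cost_effect_correlation must lie in (-1, 1).", "trialcea_config_error")
  }
  for (arm in c("IG", "CG")) {
    for (f in c("utility_baseline_mean", "utility_effect_t1", "vas_baseline_mean",
                "vas_effect_t1", "reliable_improvement_prob")) {
      if (!arm %in% names(cfg[[f]])) {
        stop_trialcea(sprintf("`%s` must be named with IG and CG.", f),
                      "trialcea_config_error")
      }
    }
  }
  invisible(cfg)
}

#' Default per-category quantity parameters (6-month window)
#'
#' Zero-inflated lognormal parameters for the nine resource-use categories
#' of [default_unit_costs()], calibrated once so the 6-month baseline
#' societal total averages about 3500 euros with a heavy right tail
#' (SD roughly twice the mean), dominated by inpatient stays and care hours.
#'
#' @return A tibble with columns `category`, `p_zero`, `meanlog`, `sdlog`.
#' @export
default_cost_category_params <- function() {
  tibble::tribble(
    ~category,                  ~p_zero, ~meanlog, ~sdlog,
    "inpatient_rehabilitation",    0.85,      2.3,    1.2,
    "outpatient_physician",        0.15,      2.5,    0.8,
    "outpatient_nonphysician",     0.60,      1.5,    0.8,
    "medical_aids",                0.80,      0.6,    0.9,
    "medical_counseling",          0.70,      1.2,    0.9,
    "psychotherapy",               0.75,      1.6,    0.7,
    "transportation",              0.30,      1.8,    0.9,
    "medication",                  0.35,      1.9,    0.8,
    "nursing_care",                0.70,      4.2,    1.2
  )
}

#' Default (synthetic) unit-cost table and CPI series
#'
#' German-health-system-*shaped* but synthetic unit costs for the nine
#' default categories, all expressed in 2020 euros, with informal/formal
#' care (`nursing_care`) valued at the care wage. `mental_health` flags the
#' categories retained under the mental-health-only cost scope. The CPI
#' series is likewise synthetic and only exercises the inflation mechanism.
#'
#' @return A [unit_cost_table()].
#' @export
default_unit_costs <- function() {
  entries <- tibble::tribble(
    ~category,                  ~unit,       ~euro_per_unit, ~price_year, ~mental_health,
    "inpatient_rehabilitation", "day",                  350,        2020, FALSE,
    "outpatient_physician",     "contact",               45,        2020, TRUE,
    "outpatient_nonphysician",  "contact",               35,        2020, FALSE,
    "medical_aids",             "item",                  60,        2020, FALSE,
    "medical_counseling",       "contact",               50,        2020, TRUE,
    "psychotherapy",            "session",               90,        2020, TRUE,
    "transportation",           "trip",                  15,        2020, FALSE,
    "medication",               "pack",                  40,        2020, TRUE,
    "nursing_care",             "care_hour",             NA,        2020, FALSE
  )
  cpi <- tibble::tibble(year = 2015:2020,
                        index = c(100, 100.5, 102.0, 103.8, 105.3, 105.8))
  unit_cost_table(entries, cpi = cpi, target_year = 2020,
                  care_wage_per_hour = 25, gross_wage_per_hour = 28,
                  hours_per_workday = 8)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic two-arm trial cohort
#'
#' Deterministic given `config$seed`: each participant owns a substream
#' derived from the master seed and their index, so the first `k`
#' participants of an arm are unchanged when the arm grows. See
#' [generator_config()] for the statistical structure.
#'
#' @param config A [generator_config()].
#' @param uc Unit-cost table used to convert the configured euro increment
#'   of the intervention arm into extra quantities of
#'   `config$ig_extra_category` (default [default_unit_costs()]).
#' @param vs Value set used in profile mode.
#' @return A validated `cea_cohort` tibble with `n_ig + n_cg` rows.
#' @examples
#' cohort <- generate_cohort(generator_config(n_ig = 20, n_cg = 20, seed = 7))
#' dplyr::count(cohort, arm)
#' @export
generate_cohort <- function(config = generator_config(),
                            uc = default_unit_costs(),
                            vs = synthetic_value_set()) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  n <- cfg$n_ig + cfg$n_cg
  arms <- rep(c("IG", "CG"), c(cfg$n_ig, cfg$n_cg))
  cats <- cfg$cost_category_params$category
  extra_price <- unname(unit_price(uc, cfg$ig_extra_category))
  thr <- rci_threshold(cfg$rci)
  rho <- cfg$cost_effect_correlation
  recall0 <- 6
  recall1 <- 4
  t1_shift <- log(recall1 / recall0) + log(cfg$t1_use_factor)

  cols <- list(
    participant_id = sprintf("P%04d", seq_len(n)),
    arm = arms,
    age_years = numeric(n), gender_identity = character(n),
    eq5d_profile_t0 = rep(NA_character_, n), eq5d_profile_t1 = rep(NA_character_, n),
    eq5d_index_t0 = numeric(n), eq5d_index_t1 = numeric(n),
    eq_vas_t0 = numeric(n), eq_vas_t1 = numeric(n),
    gsi_t0 = numeric(n), gsi_t1 = numeric(n),
    work_days_absent_t1 = numeric(n), work_days_present_t1 = numeric(n),
    work_performance_t1 = numeric(n),
    intervention_cost_t1 = numeric(n),
    flag_intention_to_treat = rep(TRUE, n),
    flag_analysis_population = rep(TRUE, n),
    flag_per_protocol = logical(n)
  )
  ru0 <- matrix(0, n, length(cats), dimnames = list(NULL, paste0("ru_t0_", cats)))
  ru1 <- matrix(0, n, length(cats), dimnames = list(NULL, paste0("ru_t1_", cats)))

  for (i in seq_len(n)) {
    set.seed(participant_seed(cfg$seed, i))
    arm <- arms[i]

    cols$gender_identity[i] <- sample(names(cfg$gender_identity_probs), 1,
                                      prob = cfg$gender_identity_probs)
    cols$age_years[i] <- max(18, rnorm(1, cfg$age_mean, cfg$age_sd))

    z <- rnorm(1) # shared latent factor: costs and utility both load on it

    e_u <- rho * z + sqrt(1 - rho^2) * rnorm(1)
    u0 <- clip(cfg$utility_baseline_mean[[arm]] + cfg$utility_sd * e_u,
               utility_floor(), 1)
    u1 <- clip(u0 + cfg$utility_effect_t1[[arm]] + rnorm(1, 0, cfg$utility_change_sd),
               utility_floor(), 1)

    v0 <- clip(rnorm(1, cfg$vas_baseline_mean[[arm]], cfg$vas_sd), 0, 100)
    v1 <- clip(v0 + cfg$vas_effect_t1[[arm]] + rnorm(1, 0, cfg$vas_change_sd), 0, 100)

    responder <- runif(1) < cfg$reliable_improvement_prob[[arm]]
    if (responder) {
      # responders need headroom to improve by >= the threshold
      floor0 <- max(10, thr + 1)
      for (try in 1:1000) {
        g0 <- rnorm(1, cfg$gsi_baseline_mean, cfg$gsi_sd)
        if (g0 >= floor0) break
        g0 <- floor0 # pathological configs: fall back to the floor
      }
      g0 <- min(g0, 72)
      red <- min(thr + abs(rnorm(1, 0, cfg$responder_margin_sd)), g0)
      g1 <- g0 - red
    } else {
      g0 <- clip(rnorm(1, cfg$gsi_baseline_mean, cfg$gsi_sd), 0, 72)
      delta <- 0
      for (try in 1:100) {
        cand <- rnorm(1, 0, cfg$gsi_change_sd)
        if (cand < min(thr, g0)) {
          delta <- cand
          break
        }
      }
      g1 <- min(g0 - delta, 72)
    }

    for (k in seq_along(cats)) {
      p0 <- cfg$cost_category_params$p_zero[k]
      mu <- cfg$cost_category_params$meanlog[k]
      sg <- cfg$cost_category_params$sdlog[k]
      # rho*z shifts the log-mean; -rho^2/2 keeps the marginal mean at target
      ru0[i, k] <- if (runif(1) < p0) 0 else rlnorm(1, mu + rho * z - rho^2 / 2, sg)
      ru1[i, k] <- if (runif(1) < p0) 0 else {
        rlnorm(1, mu + t1_shift + rho * z - rho^2 / 2, sg)
      }
    }
    extra_qty <- rgamma(1, shape = 4,
                        scale = cfg$ig_extra_cost_mean / (4 * extra_price))
    if (arm == "IG") {
      k <- match(cfg$ig_extra_category, cats)
      ru1[i, k] <- ru1[i, k] + extra_qty
    }

    iv <- max(0, rnorm(1, cfg$intervention_cost_mean, cfg$intervention_cost_sd))
    cols$intervention_cost_t1[i] <- if (arm == "IG") iv else 0

    cols$work_days_absent_t1[i] <- if (runif(1) < cfg$p_any_absence) {
      rlnorm(1, cfg$absence_meanlog, cfg$absence_sdlog)
    } else 0
    cols$work_days_present_t1[i] <- max(0, rnorm(1, cfg$days_present_mean,
                                                 cfg$days_present_sd))
    cols$work_performance_t1[i] <- clip(
      rnorm(1, cfg$work_performance_mean, cfg$work_performance_sd), 0, 10
    )

    cols$flag_per_protocol[i] <- runif(1) < cfg$per_protocol_prob

    if (cfg$profile_mode) {
      prof0 <- draw_profile(u0)
      prof1 <- draw_profile(u1)
      cols$eq5d_profile_t0[i] <- prof0
      cols$eq5d_profile_t1[i] <- prof1
      u0 <- score_profile(prof0, vs)
      u1 <- score_profile(prof1, vs)
    }
    cols$eq5d_index_t0[i] <- u0
    cols$eq5d_index_t1[i] <- u1
    cols$eq_vas_t0[i] <- v0
    cols$eq_vas_t1[i] <- v1
    cols$gsi_t0[i] <- g0
    cols$gsi_t1[i] <- g1
  }

  out <- dplyr::bind_cols(tibble::as_tibble(cols),
                          tibble::as_tibble(ru0), tibble::as_tibble(ru1))
  as_cohort(out, recall_months_t0 = recall0, recall_months_t1 = recall1)
}

# map a utility to a plausible 5-digit profile: dimension levels follow the
# overall severity (1 - u) / (1 - floor) plus dimension-specific noise
draw_profile <- function(u) {
  sev <- (1 - u) / (1 - utility_floor())
  lat <- sev + rnorm(5, 0, 0.12)
  lv <- cut(lat, breaks = c(-Inf, 0.12, 0.30, 0.55, 0.80, Inf), labels = FALSE)
  paste(lv, collapse = "")
}

#' Mask fields completely at random
#'
#' Marks outcome, covariate, resource-use and work fields absent with the
#' given per-field probability (missing completely at random). Identifiers,
#' arm assignment, analysis flags and intervention costs are never masked.
#'
#' @param cohort A cohort tibble.
#' @param rate Per-field masking probability in `[0, 1]`.
#' @param seed Seed for the masking pattern.
#' @return The cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort, rate, seed = 1) {
  assert_number(rate, "rate", lower = 0, upper = 1)
  maskable <- c(
    "age_years", "gender_identity",
    "eq5d_profile_t0", "eq5d_profile_t1", "eq5d_index_t0", "eq5d_index_t1",
    "eq_vas_t0", "eq_vas_t1", "gsi_t0", "gsi_t1",
    "work_days_absent_t1", "work_days_present_t1", "work_performance_t1",
    grep("^ru_t[01]_", names(cohort), value = TRUE)
  )
  maskable <- intersect(maskable, names(cohort))
  if (rate == 0) return(cohort)
  set.seed(seed)
  for (col in maskable) {
    mask <- runif(nrow(cohort)) < rate
    cohort[[col]][mask] <- NA
  }
  cohort
}
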