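#' QALYs over a short follow-up by linear interpolation
#'
#' Quality-adjusted life years over the trial horizon are the area under the
#' linear interpolant of the utility index between the two assessments: with
#' only two time points this is the trapezoid, `(u_t0 + u_t1) / 2 *
#' horizon_months / 12`. With utilities fixed at the instrument bounds over a
#' 4-month horizon the attainable range is `[-0.22, 0.33]` after 2-dp
#' rounding. No discounting is applied (sub-year horizon).
#'
#' @param u_t0,u_t1 Utility indices at baseline and follow-up, each in
#'   `[-0.661, 1]` (vectorised; `NA` propagates).
#' @param horizon_months Follow-up length in months (default 4).
#' @return QALYs accrued over the horizon.
#' @examples
#' qaly_auc(1, 1)        # 1/3
#' qaly_auc(-0.661, -0.661)
#' @export
qaly_auc <- function(u_t0, u_t1, horizon_months = 4) {
  assert_number(horizon_months, "horizon_months", class = "trialcea_config_error")
  if (horizon_months <= 0) {
    stop_trialcea("`horizon_months` must be > 0.", "trialcea_config_error")
  }
  check_range(u_t0, "u_t0", utility_floor(), 1)
  check_range(u_t1, "u_t1", utility_floor(), 1)
  (u_t0 + u_t1) / 2 * horizon_months / 12
}

#' QALYs from the EQ-VAS
#'
#' The 0-100 visual-analogue rating is rescaled to `[0, 1]` by dividing by
#' 100 and fed through the same trapezoid as [qaly_auc()].
#'
#' @param v_t0,v_t1 EQ-VAS scores in `[0, 100]`.
#' @inheritParams qaly_auc
#' @return QALYs accrued over the horizon.
#' @export
vas_qaly <- function(v_t0, v_t1, horizon_months = 4) {
  check_range(v_t0, "v_t0", 0, 100)
  check_range(v_t1, "v_t1", 0, 100)
  qaly_auc(v_t0 / 100, v_t1 / 100, horizon_months)
}

check_range <- function(x, name, lower, upper) {
  bad <- which(!is.na(x) & (x < lower | x > upper))
  if (length(bad)) {
    stop_trialcea(
      sprintf(
        "`%s` outside [%s, %s] at position %s (value %s).",
        name, format(lower), format(upper), bad[1], format(x[bad[1]])
      ),
      "trialcea_validation_error"
    )
  }
  invisible(x)
}

#' Reliable-change parameters and threshold (Jacobson-Truax)
#'
#' `rci_params()` bundles the reference-population constants; defaults are
#' the BSI-18 GSI reference values used to define reliable improvement in
#' the trial (SD 7.44, Cronbach alpha 0.93; the reference mean 4.66 is
#' carried as metadata but plays no role in the threshold).
#' `rci_threshold()` evaluates the Jacobson-Truax criterion
#' `z * SD * sqrt(2) * sqrt(1 - reliability)` and rounds it to
#' `rounding` decimals; the classification uses the *rounded* value because
#' that is how the criterion is reported and applied (default 5.46).
#'
#' @param reference_sd Reference-population SD of the score.
#' @param reliability Internal consistency (Cronbach alpha) in `[0, 1]`.
#' @param z Standard-normal quantile (1.96 for the conventional 95% band).
#' @param rounding Decimals the threshold is rounded to (default 2).
#' @param reference_mean Reference mean, metadata only.
#' @return `rci_params()`: a list of class `rci_params`; `rci_threshold()`:
#'   a single number in score points.
#' @examples
#' rci_threshold()                       # 5.46
#' rci_threshold(rci_params(reference_sd = 10, reliability = 0.84))
#' @export
rci_params <- function(reference_sd = 7.44, reliability = 0.93, z = 1.96,
                       rounding = 2, reference_mean = 4.66) {
  assert_number(reference_sd, "reference_sd", lower = 1e-12)
  assert_number(reliability, "reliability", lower = 0, upper = 1)
  assert_number(z, "z", lower = 0)
  structure(
    list(
      reference_sd = reference_sd, reliability = reliability, z = z,
      rounding = rounding, reference_mean = reference_mean
    ),
    class = "rci_params"
  )
}

#' @rdname rci_params
#' @param p An `rci_params` object.
#' @export
rci_threshold <- function(p = rci_params()) {
  stopifnot(inherits(p, "rci_params"))
  raw <- p$z * p$reference_sd * sqrt(2) * sqrt(1 - p$reliability)
  round_half_up(raw, p$rounding)
}

#' Classify reliable improvement on a distress score
#'
#' A participant shows reliable improvement when the score *reduction*
#' between baseline and follow-up meets or exceeds the reliable-change
#' threshold (inclusive: a reduction of exactly the threshold counts).
#' Deterioration is never improvement. The classification depends only on
#' the change, not the level.
#'
#' @param score_t0,score_t1 Scores at baseline and follow-up, in `[0, 72]`
#'   for the BSI-18 GSI (vectorised).
#' @param threshold Reliable-change threshold in score points
#'   (default [rci_threshold()] = 5.46).
#' @return Logical vector; `NA` where either score is missing.
#' @export
reliable_improvement <- function(score_t0, score_t1, threshold = rci_threshold()) {
  check_range(score_t0, "score_t0", 0, 72)
  check_range(score_t1, "score_t1", 0, 72)
  assert_number(threshold, "threshold", lower = 0)
  (score_t0 - score_t1) >= threshold
}

#' Attach per-participant health effects to a cohort
#'
#' Computes the EQ-5D-5L utility index at both assessments (scoring the
#' 5-digit profile through `vs` where the index is absent but a profile is
#' present), QALYs over the follow-up horizon, EQ-VAS QALYs, and the
#' reliable-improvement indicator on the BSI-18 GSI.
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @param vs Value set used when profiles must be scored
#'   (default [synthetic_value_set()]).
#' @param rci Reliable-change parameters, an [rci_params()] object.
#' @param horizon_months Follow-up horizon; defaults to the cohort's
#'   follow-up recall window.
#' @return The cohort with columns `eq5d_index_t0/t1` (filled where
#'   scoreable), `qaly`, `qaly_vas` and `reliable_improvement` appended.
#' @export
add_health_effects <- function(cohort, vs = synthetic_value_set(),
                               rci = rci_params(), horizon_months = NULL) {
  horizon_months <- horizon_months %||% attr(cohort, "recall_months_t1") %||% 4
  out <- cohort
  for (tp in c("t0", "t1")) {
    idx <- paste0("eq5d_index_", tp)
    prof <- paste0("eq5d_profile_", tp)
    if (prof %in% names(out)) {
      fill <- is.na(out[[idx]]) & !is.na(out[[prof]])
      if (any(fill)) out[[idx]][fill] <- score_profile(out[[prof]][fill], vs)
    }
  }
  thr <- rci_threshold(rci)
  out$qaly <- qaly_auc(out$eq5d_index_t0, out$eq5d_index_t1, horizon_months)
  out$qaly_vas <- vas_qaly(out$eq_vas_t0, out$eq_vas_t1, horizon_months)
  out$reliable_improvement <- reliable_improvement(out$gsi_t0, out$gsi_t1, thr)
  out
}
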