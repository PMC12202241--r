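#' Configure one cost-effectiveness analysis run
#'
#' Bundles every switch of the pipeline: analysis population, costing
#' perspective, effect measure, optional gender-identity subgroup,
#' winsorization percentile, cost scope, intervention-cost mode, bootstrap
#' size and seed, WTP grid and significance level. One effect measure per
#' run; sensitivity variants are expressed as overrides via
#' [run_sensitivity_suite()].
#'
#' @param population `"analysis"` (the primary analysis population),
#'   `"per_protocol"`, or `"complete_case"` (analysis population restricted
#'   to rows complete on every model variable — numerically identical to
#'   the per-model filtering already applied at fit time, made explicit).
#' @param perspective `"SP"` societal (includes indirect costs) or `"PP"`
#'   payer.
#' @param effect_measure `"QALY_EQ5D"`, `"QALY_VAS"` or
#'   `"RELIABLE_IMPROVEMENT"`.
#' @param subgroup Optional gender-identity category to restrict to; the
#'   gender-identity covariate is then dropped from both equations (it is
#'   constant within the subgroup).
#' @param winsorize Optional percentile (e.g. 95) at which window totals
#'   are winsorized.
#' @param cost_scope `"all"` or `"mental_health_only"` (categories flagged
#'   `mental_health` in the unit-cost table, plus intervention costs;
#'   indirect costs excluded).
#' @param intervention_cost_mode `"standard"` uses the per-participant
#'   intervention costs carried in the cohort; `"high"` replaces them with
#'   the scalar `intervention_cost_high` (wage-based revaluation
#'   sensitivity).
#' @param intervention_cost_high Scalar euro replacement under `"high"`.
#' @param B,seed Bootstrap replications (default 1000) and seed.
#' @param wtp_grid WTP grid; `NULL` picks [default_wtp_grid()] for the
#'   effect measure.
#' @param alpha Two-sided significance level (default 0.05), recorded in
#'   the manifest.
#' @param rci Reliable-change parameters, see [rci_params()].
#' @param stratify_by_arm,iterate Passed to [bootstrap_contrasts()] and
#'   [fit_sur()].
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(population = c("analysis", "per_protocol", "complete_case"),
                            perspective = c("SP", "PP"),
                            effect_measure = c("QALY_EQ5D", "QALY_VAS",
                                               "RELIABLE_IMPROVEMENT"),
                            subgroup = NULL, winsorize = NULL,
                            cost_scope = c("all", "mental_health_only"),
                            intervention_cost_mode = c("standard", "high"),
                            intervention_cost_high = 1101,
                            B = 1000, seed = 1, wtp_grid = NULL, alpha = 0.05,
                            rci = rci_params(),
                            stratify_by_arm = FALSE, iterate = FALSE) {
  cfg <- list(
    population = match.arg(population),
    perspective = match.arg(perspective),
    effect_measure = match.arg(effect_measure),
    subgroup = subgroup, winsorize = winsorize,
    cost_scope = match.arg(cost_scope),
    intervention_cost_mode = match.arg(intervention_cost_mode),
    intervention_cost_high = intervention_cost_high,
    B = B, seed = seed, wtp_grid = wtp_grid, alpha = alpha, rci = rci,
    stratify_by_arm = stratify_by_arm, iterate = iterate
  )
  if (B > 0 && (is.null(seed) || is.na(seed))) {
    stop_trialcea("a seed is mandatory when B > 0.", "trialcea_config_error")
  }
  if (!is.null(cfg$subgroup) &&
      !cfg$subgroup %in% c("trans_masculine", "trans_feminine", "nonbinary")) {
    stop_trialcea("unknown subgroup.", "trialcea_config_error")
  }
  structure(cfg, class = "analysis_config")
}

config_spec <- function(cfg) {
  if (is.null(cfg$subgroup)) {
    sur_spec(cfg$effect_measure)
  } else {
    sur_spec(cfg$effect_measure,
             cost_covariates = c("arm", "age_years", "cost_t0"),
             effect_covariates = c("arm", "age_years", "eq5d_index_t0", "gsi_t0"))
  }
}

#' Assemble the per-participant analysis table
#'
#' Applies the population and subgroup filters, computes health effects
#' ([add_health_effects()]) and window cost totals ([cost_cohort()]) under
#' the configured perspective, scope and intervention-cost mode, optionally
#' winsorizes the window totals, and returns one row per participant with
#' everything the regression stage needs.
#'
#' @param cohort A validated cohort tibble.
#' @param uc A [unit_cost_table()].
#' @param vs A [value_set()].
#' @param cfg An [analysis_config()].
#' @return A tibble with identifiers, covariates, `cost_t0`, `cost_t1`,
#'   `qaly`, `qaly_vas`, `reliable_improvement` and the raw outcome columns.
#' @export
build_analysis_table <- function(cohort, uc, vs = synthetic_value_set(),
                                 cfg = analysis_config()) {
  stopifnot(inherits(cfg, "analysis_config"))
  d <- dplyr::filter(cohort, .data$flag_analysis_population)
  if (cfg$population == "per_protocol") {
    d <- dplyr::filter(d, .data$flag_per_protocol)
  }
  if (!is.null(cfg$subgroup)) {
    d <- dplyr::filter(d, .data$gender_identity == cfg$subgroup)
  }
  if (nrow(d) == 0) {
    stop_trialcea("no participants left after population/subgroup filters.",
                  "trialcea_estimation_error")
  }
  d <- add_health_effects(d, vs = vs, rci = cfg$rci)
  if (cfg$intervention_cost_mode == "high") {
    d$intervention_cost_t1 <- ifelse(d$arm == "IG", cfg$intervention_cost_high, 0)
  }
  mh_only <- cfg$cost_scope == "mental_health_only"
  categories <- if (mh_only) {
    uc$entries$category[uc$entries$mental_health]
  }
  costs <- cost_cohort(d, uc, perspective = cfg$perspective,
                       categories = categories, include_indirect = !mh_only)
  totals <- costs |>
    dplyr::select("participant_id", "window", "total") |>
    tidyr::pivot_wider(names_from = "window", values_from = "total",
                       names_glue = "cost_{tolower(window)}")
  out <- dplyr::left_join(d, totals, by = "participant_id")
  if (!is.null(cfg$winsorize)) {
    out$cost_t0 <- winsorize_totals(out$cost_t0, cfg$winsorize)
    out$cost_t1 <- winsorize_totals(out$cost_t1, cfg$winsorize)
  }
  if (cfg$population == "complete_case") {
    spec <- config_spec(cfg)
    out <- out[complete.cases(out[, intersect(spec$variables, names(out))]), ]
  }
  out
}

#' Run the full cost-effectiveness analysis
#'
#' Executes the stated chain — health effects, costing, complete-case SUR,
#' participant bootstrap, ICER, plane and acceptability curve — and returns
#' every artifact plus a machine-readable manifest. Reruns with the same
#' inputs and config are identical.
#'
#' @inheritParams build_analysis_table
#' @return An object of class `cea_analysis`: `unadjusted` (trial-summary
#'   table of group means and F tests), `adjusted` (SUR-adjusted means and
#'   differences), `fit`, `draws`, `icer`, `plane`, `ceac`, `intervals`
#'   (BCa for both contrasts), `table` (the analysis table) and `manifest`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(generator_config(n_ig = 60, n_cg = 60, seed = 3))
#' res <- run_analysis(cohort, default_unit_costs(),
#'                     cfg = analysis_config(B = 100, seed = 42))
#' res$adjusted
#' }
#' @export
run_analysis <- function(cohort, uc = default_unit_costs(),
                         vs = synthetic_value_set(), cfg = analysis_config()) {
  at <- build_analysis_table(cohort, uc, vs, cfg)
  spec <- config_spec(cfg)

  unadj_rows <- purrr::imap(
    c(intervention_cost = "intervention_cost_t1",
      total_cost_t0 = "cost_t0", total_cost_t1 = "cost_t1",
      eq5d_index_t0 = "eq5d_index_t0", eq5d_index_t1 = "eq5d_index_t1",
      eq_vas_t0 = "eq_vas_t0", eq_vas_t1 = "eq_vas_t1"),
    function(col, label) {
      cmp <- unadjusted_comparison(at[[col]][at$arm == "IG"],
                                   at[[col]][at$arm == "CG"])
      dplyr::bind_cols(tibble::tibble(measure = label), cmp)
    }
  )
  unadjusted <- dplyr::bind_rows(unadj_rows)

  fit <- fit_sur(at, spec, iterate = cfg$iterate)
  adjusted <- adjusted_contrast(fit)
  draws <- bootstrap_contrasts(at, spec, B = cfg$B, seed = cfg$seed,
                               stratify_by_arm = cfg$stratify_by_arm)
  pt <- attr(draws, "point_estimate")
  icer_res <- icer(pt[["delta_cost"]], pt[["delta_effect"]])
  grid <- cfg$wtp_grid %||% default_wtp_grid(cfg$effect_measure)
  curve <- ceac(draws, grid)
  plane <- plane_summary(draws)
  jk <- jackknife_contrasts(at, spec)
  intervals <- dplyr::bind_rows(
    bca_interval(draws, "delta_cost", level = 1 - cfg$alpha,
                 jackknife = jk[, "delta_cost"]),
    bca_interval(draws, "delta_effect", level = 1 - cfg$alpha,
                 jackknife = jk[, "delta_effect"])
  )
  manifest <- list(
    config = unclass_config(cfg),
    n_input = nrow(cohort), n_analysis = nrow(at), n_model = fit$n_used,
    n_failed_refits = attr(draws, "n_failed_refits"),
    package_version = as.character(utils::packageVersion("trialcea")),
    schema_version = cohort_schema_version()
  )
  structure(
    list(unadjusted = unadjusted, adjusted = adjusted, fit = fit,
         draws = draws, icer = icer_res, plane = plane, ceac = curve,
         intervals = intervals, table = at, manifest = manifest),
    class = "cea_analysis"
  )
}

unclass_config <- function(cfg) {
  out <- unclass(cfg)
  out$rci <- unclass(out$rci)
  out$wtp_grid <- if (is.null(out$wtp_grid)) "default" else range(out$wtp_grid)
  out
}

#' @export
print.cea_analysis <- function(x, ...) {
  cat(sprintf("Cost-effectiveness analysis (n = %d, perspective %s, effect %s)\n",
              x$manifest$n_model, x$manifest$config$perspective,
              x$manifest$config$effect_measure))
  cat("\nAdjusted contrasts (SUR):\n")
  print(as.data.frame(x$adjusted), row.names = FALSE, digits = 4)
  cat(sprintf("\nICER: %s €/effect unit (quadrant %s)\n",
              format(round(x$icer$icer, 2), big.mark = ","), x$icer$quadrant))
  ne <- x$plane$fraction[x$plane$quadrant == "NE"]
  cat(sprintf("Bootstrap draws in NE quadrant: %.1f%%\n", 100 * ne))
  invisible(x)
}

#' @rdname run_analysis
#' @param x A `cea_analysis` result.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.cea_analysis <- function(x, ...) {
  tibble::tibble(
    n = x$manifest$n_model,
    delta_cost = x$icer$delta_cost,
    delta_effect = x$icer$delta_effect,
    icer = x$icer$icer,
    quadrant = x$icer$quadrant,
    B = x$manifest$config$B,
    effect_measure = x$manifest$config$effect_measure,
    perspective = x$manifest$config$perspective
  )
}

#' Write run artifacts to a directory
#'
#' Emits `unadjusted.csv`, `adjusted.csv`, `draws.csv` (+ JSON sidecar),
#' `ceac.csv`, `plane.csv`, `intervals.csv` and `manifest.json`. Reruns
#' with identical inputs produce byte-identical files (the manifest holds
#' no timestamps).
#'
#' @param result A [run_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(result, dir) {
  stopifnot(inherits(result, "cea_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$unadjusted, file.path(dir, "unadjusted.csv"))
  readr::write_csv(result$adjusted, file.path(dir, "adjusted.csv"))
  write_draws(result$draws, file.path(dir, "draws.csv"))
  readr::write_csv(result$ceac, file.path(dir, "ceac.csv"))
  readr::write_csv(result$plane, file.path(dir, "plane.csv"))
  readr::write_csv(result$intervals, file.path(dir, "intervals.csv"))
  headline <- list(
    delta_cost = result$icer$delta_cost,
    delta_effect = result$icer$delta_effect,
    icer = result$icer$icer,
    quadrant = result$icer$quadrant,
    manifest = result$manifest
  )
  jsonlite::write_json(headline, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run a suite of sensitivity analyses
#'
#' Applies a list of config overrides to a base configuration and reports
#' one headline row per variant (adjusted cost and effect differences and
#' the ICER). Failures in one variant are caught and reported in the
#' `error` column without aborting the suite.
#'
#' @inheritParams build_analysis_table
#' @param base_cfg The base [analysis_config()].
#' @param variants Named list; each element is a list of `analysis_config`
#'   argument overrides (e.g. `list(winsorized = list(winsorize = 95))`).
#' @return A tibble with one row per run (`base` first): `variant`, `n`,
#'   `delta_cost`, `delta_effect`, `icer`, `quadrant`, `error`.
#' @export
run_sensitivity_suite <- function(cohort, uc = default_unit_costs(),
                                  vs = synthetic_value_set(),
                                  base_cfg = analysis_config(),
                                  variants = list()) {
  runs <- c(list(base = list()), variants)
  purrr::imap_dfr(runs, function(overrides, label) {
    res <- tryCatch(
      {
        cfg <- do.call(analysis_config, modifyList(config_args(base_cfg), overrides))
        g <- glance(run_analysis(cohort, uc, vs, cfg))
        tibble::tibble(
          variant = label, n = g$n, delta_cost = g$delta_cost,
          delta_effect = g$delta_effect, icer = g$icer, quadrant = g$quadrant,
          error = NA_character_
        )
      },
      error = function(e) {
        tibble::tibble(
          variant = label, n = NA_integer_, delta_cost = NA_real_,
          delta_effect = NA_real_, icer = NA_real_, quadrant = NA_character_,
          error = conditionMessage(e)
        )
      }
    )
    res
  })
}

config_args <- function(cfg) {
  out <- unclass(cfg)
  out[!vapply(out, is.null, logical(1))]
}
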