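#' Unit-cost tables
#'
#' A unit-cost table carries everything needed to turn resource-use
#' quantities into euros: per-category unit costs (with their price year),
#' a consumer-price-index series used to inflate prices to a common target
#' year, the hourly wage at which informal/formal care time is valued
#' (substitution approach), and the gross hourly wage plus working-day
#' length used for human-capital productivity costs.
#'
#' Categories whose `unit` is `"care_hour"` are valued at
#' `care_wage_per_hour` rather than their own `euro_per_unit`, mirroring the
#' convention that informal care could have been substituted by formal care.
#' A logical `mental_health` column marks the categories retained by the
#' mental-health-only cost scope, and a logical `payer` column marks which
#' categories a health-care payer covers: payer-perspective totals drop
#' non-payer categories and indirect costs. Both default to `TRUE` for every
#' category, so by default the payer perspective is the societal one minus
#' indirect costs.
#'
#' @param entries Data frame with columns `category`, `unit`,
#'   `euro_per_unit`, `price_year` and optionally `mental_health` (logical,
#'   default `TRUE` for counseling/therapy-type rows is *not* guessed —
#'   absent column means all `TRUE`).
#' @param cpi Data frame with columns `year`, `index`, or `NULL` when all
#'   prices are already in target-year euros.
#' @param target_year Year all costs are expressed in (default 2020).
#' @param care_wage_per_hour Hourly wage valuing informal/formal care.
#' @param gross_wage_per_hour Gross hourly wage valuing lost work time.
#' @param hours_per_workday Working-day length in hours (default 8).
#' @return A list of class `unit_cost_table`.
#' @export
unit_cost_table <- function(entries, cpi = NULL, target_year = 2020,
                            care_wage_per_hour = 25,
                            gross_wage_per_hour = 28,
                            hours_per_workday = 8) {
  entries <- tibble::as_tibble(entries)
  need <- c("category", "unit", "euro_per_unit", "price_year")
  if (!all(need %in% names(entries))) {
    stop_trialcea(
      sprintf("unit-cost table needs columns %s.", paste(need, collapse = ", ")),
      "trialcea_schema_error"
    )
  }
  if (!"mental_health" %in% names(entries)) entries$mental_health <- TRUE
  if (!"payer" %in% names(entries)) entries$payer <- TRUE
  if (anyDuplicated(entries$category)) {
    stop_trialcea("unit-cost categories must be unique.", "trialcea_validation_error")
  }
  if (any(entries$euro_per_unit < 0, na.rm = TRUE) ||
      care_wage_per_hour < 0 || gross_wage_per_hour < 0 || hours_per_workday <= 0) {
    stop_trialcea("monetary values must be >= 0 and workday > 0 h.",
                  "trialcea_validation_error")
  }
  if (!is.null(cpi)) cpi <- tibble::as_tibble(cpi)[, c("year", "index")]
  structure(
    list(
      entries = entries, cpi = cpi, target_year = target_year,
      care_wage_per_hour = care_wage_per_hour,
      gross_wage_per_hour = gross_wage_per_hour,
      hours_per_workday = hours_per_workday
    ),
    class = "unit_cost_table"
  )
}

#' Read a unit-cost table (and optional CPI series) from CSV
#'
#' @param path Unit-cost CSV with columns `category`, `unit`,
#'   `euro_per_unit`, `price_year`, optional `mental_health`.
#' @param cpi_path Optional CPI CSV with columns `year`, `index`.
#' @inheritParams unit_cost_table
#' @return A `unit_cost_table`.
#' @export
read_unit_costs <- function(path, cpi_path = NULL, target_year = 2020,
                            care_wage_per_hour = 25, gross_wage_per_hour = 28,
                            hours_per_workday = 8) {
  if (!file.exists(path)) {
    stop_trialcea(sprintf("unit-cost file not found: %s", path), "trialcea_io_error")
  }
  entries <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cpi <- if (!is.null(cpi_path)) {
    readr::read_csv(cpi_path, show_col_types = FALSE, progress = FALSE)
  }
  unit_cost_table(entries, cpi, target_year, care_wage_per_hour,
                  gross_wage_per_hour, hours_per_workday)
}

#' Inflate an amount between price years with a CPI series
#'
#' @param amount Euro amount(s).
#' @param from_year,to_year Price years, both present in `cpi`.
#' @param cpi Data frame (`year`, `index`) or named numeric vector.
#' @return `amount * cpi[to_year] / cpi[from_year]`.
#' @examples
#' cpi <- data.frame(year = 2019:2020, index = c(100, 105))
#' inflate(100, 2019, 2020, cpi)
#' @export
inflate <- function(amount, from_year, to_year, cpi) {
  if (is.data.frame(cpi)) cpi <- setNames(cpi$index, cpi$year)
  f <- cpi[as.character(from_year)]
  t <- cpi[as.character(to_year)]
  if (anyNA(f) || anyNA(t)) {
    stop_trialcea(
      sprintf("CPI series lacks year %s.",
              paste(unique(c(from_year, to_year)[c(anyNA(f), anyNA(t))]), collapse = ", ")),
      "trialcea_config_error"
    )
  }
  amount * unname(t / f)
}

#' Presenteeism: performance-weighted days lost
#'
#' Reduced productivity at work is converted to whole-day equivalents as
#' `(1 - w/10) * d`, where `w` is the 0-10 overall work-performance rating
#' and `d` the days at work during the recall window.
#'
#' @param w Work performance in `[0, 10]` (vectorised).
#' @param d Days at work, `>= 0`.
#' @return Day equivalents lost to reduced productivity.
#' @export
productivity_days_lost <- function(w, d) {
  check_range(w, "w", 0, 10)
  check_range(d, "d", 0, Inf)
  (1 - w / 10) * d
}

#' Indirect (productivity) costs under the human-capital approach
#'
#' Days absent plus presenteeism day-equivalents are converted to hours at
#' the working-day length and valued at the gross wage.
#'
#' @param absent_days Days absent from work, `>= 0`.
#' @param productivity_days Day equivalents from [productivity_days_lost()].
#' @param uc A [unit_cost_table()] supplying wage and workday length.
#' @return Euro cost (vectorised).
#' @export
indirect_cost <- function(absent_days, productivity_days, uc) {
  stopifnot(inherits(uc, "unit_cost_table"))
  check_range(absent_days, "absent_days", 0, Inf)
  check_range(productivity_days, "productivity_days", 0, Inf)
  (absent_days + productivity_days) * uc$hours_per_workday * uc$gross_wage_per_hour
}

unit_price <- function(uc, categories) {
  e <- uc$entries[match(categories, uc$entries$category), ]
  missing_cat <- categories[is.na(e$category)]
  if (length(missing_cat)) {
    stop_trialcea(
      sprintf("resource-use categories missing from the unit-cost table: %s",
              paste(missing_cat, collapse = ", ")),
      "trialcea_config_error"
    )
  }
  price <- ifelse(e$unit == "care_hour", uc$care_wage_per_hour, e$euro_per_unit)
  if (!is.null(uc$cpi)) {
    for (i in seq_along(price)) {
      if (e$unit[i] != "care_hour" && e$price_year[i] != uc$target_year) {
        price[i] <- inflate(price[i], e$price_year[i], uc$target_year, uc$cpi)
      }
    }
  } else if (any(e$price_year != uc$target_year & e$unit != "care_hour")) {
    stop_trialcea("price years differ from target year but no CPI series given.",
                  "trialcea_config_error")
  }
  setNames(price, categories)
}

#' Cost a cohort: per-participant, per-window euro totals
#'
#' Multiplies each `ru_<window>_<category>` quantity by the (inflated) unit
#' cost, adds per-participant intervention costs (follow-up window,
#' intervention arm only) and — under the societal perspective at follow-up —
#' indirect costs from absenteeism and presenteeism. Payer-perspective (PP)
#' totals exclude indirect costs, so PP <= SP always holds. Missing
#' quantities propagate to a missing total (the analysis is complete-case;
#' zero and missing are distinct states).
#'
#' @param cohort Cohort tibble (see [read_cohort()]).
#' @param uc A [unit_cost_table()].
#' @param perspective `"SP"` (societal) or `"PP"` (payer).
#' @param windows Which recall windows to cost (default both).
#' @param intervention_cost Scalar fallback when the cohort lacks an
#'   `intervention_cost_t1` column; applied to intervention-arm participants
#'   at follow-up.
#' @param categories Optional subset of categories to retain (e.g. the
#'   mental-health-related ones); default all categories present.
#' @param include_indirect Include indirect costs under SP at follow-up
#'   (default `TRUE`; the instrument collects work data at follow-up only,
#'   so baseline windows never carry indirect costs).
#' @return A tibble with one row per participant and window: `cost_<category>`
#'   columns, `intervention_cost`, `indirect_cost`, `total`.
#' @export
cost_cohort <- function(cohort, uc, perspective = c("SP", "PP"),
                        windows = c("T0", "T1"), intervention_cost = 0,
                        categories = NULL, include_indirect = TRUE) {
  perspective <- match.arg(perspective)
  stopifnot(inherits(uc, "unit_cost_table"))
  out <- purrr::map(windows, function(win) {
    pre <- paste0("ru_", tolower(win), "_")
    ru_cols <- grep(paste0("^", pre), names(cohort), value = TRUE)
    cats <- sub(pre, "", ru_cols)
    if (!is.null(categories)) {
      keep <- cats %in% categories
      ru_cols <- ru_cols[keep]
      cats <- cats[keep]
    }
    if (perspective == "PP" && length(cats)) {
      payer_cats <- uc$entries$category[uc$entries$payer]
      keep <- cats %in% payer_cats
      ru_cols <- ru_cols[keep]
      cats <- cats[keep]
    }
    prices <- unit_price(uc, cats)
    cost_mat <- if (length(ru_cols)) {
      sweep(as.matrix(cohort[, ru_cols, drop = FALSE]), 2, prices, `*`)
    } else {
      matrix(0, nrow(cohort), 0)
    }
    res <- tibble::tibble(
      participant_id = cohort$participant_id,
      arm = cohort$arm,
      window = win,
      perspective = perspective
    )
    if (length(cats)) {
      colnames(cost_mat) <- paste0("cost_", cats)
      res <- dplyr::bind_cols(res, tibble::as_tibble(cost_mat))
    }
    iv <- rep(0, nrow(cohort))
    if (win == "T1") {
      base_iv <- if ("intervention_cost_t1" %in% names(cohort)) {
        cohort$intervention_cost_t1
      } else {
        rep(intervention_cost, nrow(cohort))
      }
      iv <- ifelse(cohort$arm == "IG", base_iv, 0)
    }
    res$intervention_cost <- iv
    ind <- rep(0, nrow(cohort))
    if (win == "T1" && perspective == "SP" && include_indirect &&
        all(c("work_days_absent_t1", "work_days_present_t1", "work_performance_t1")
            %in% names(cohort))) {
      ind <- indirect_cost(
        cohort$work_days_absent_t1,
        productivity_days_lost(cohort$work_performance_t1, cohort$work_days_present_t1),
        uc
      )
    }
    res$indirect_cost <- ind
    res$total <- rowSums(cbind(cost_mat, iv, ind))
    res
  })
  dplyr::bind_rows(out)
}

#' Cost a single participant
#'
#' Convenience wrapper over [cost_cohort()] for one record.
#'
#' @param rec A one-row cohort tibble.
#' @inheritParams cost_cohort
#' @param window `"T0"` or `"T1"`.
#' @return A one-row cost-breakdown tibble.
#' @export
cost_participant <- function(rec, window = c("T1", "T0"), uc,
                             perspective = c("SP", "PP"),
                             intervention_cost = 0, ...) {
  window <- match.arg(window)
  cost_cohort(rec, uc, perspective = match.arg(perspective), windows = window,
              intervention_cost = intervention_cost, ...)
}

#' Winsorize cost totals at an empirical percentile
#'
#' Values above the empirical percentile (linear-interpolation quantile,
#' R type 7) are replaced by it; everything below is untouched, so the
#' operation is idempotent and never increases the mean. Missing values are
#' ignored for the percentile and passed through.
#'
#' @param values Euro totals.
#' @param percentile Percentile in `(0, 100)` (default 95).
#' @return Winsorized values, same length and order.
#' @export
winsorize_totals <- function(values, percentile = 95) {
  assert_number(percentile, "percentile", lower = 1e-9, upper = 100 - 1e-9)
  if (length(values) == 0 || all(is.na(values))) {
    stop_trialcea("cannot winsorize an empty set of values.", "trialcea_validation_error")
  }
  cap <- quantile(values, percentile / 100, na.rm = TRUE, type = 7, names = FALSE)
  pmin(values, cap)
}
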