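#' Cohort CSV schema
#'
#' A cohort is a tibble with one row per participant. Fixed columns:
#'
#' * `participant_id` (unique string), `arm` (`"IG"`/`"CG"`),
#'   `age_years` (>= 0), `gender_identity` (`"trans_masculine"`,
#'   `"trans_feminine"`, `"nonbinary"`)
#' * `eq5d_profile_t0`, `eq5d_profile_t1` — optional 5-digit EQ-5D-5L
#'   profiles (each digit 1-5)
#' * `eq5d_index_t0`, `eq5d_index_t1` in `[-0.661, 1]`
#' * `eq_vas_t0`, `eq_vas_t1` in `[0, 100]`
#' * `gsi_t0`, `gsi_t1` in `[0, 72]`
#' * `work_days_absent_t1`, `work_days_present_t1` (>= 0),
#'   `work_performance_t1` in `[0, 10]`
#' * `intervention_cost_t1` (>= 0; optional, 0 when absent)
#' * `flag_intention_to_treat`, `flag_analysis_population`,
#'   `flag_per_protocol` (logical analysis-population markers)
#'
#' plus any number of resource-use columns `ru_t0_<category>` /
#' `ru_t1_<category>` (quantities >= 0) whose categories are matched against
#' the unit-cost table at costing time. Missing numeric cells are written as
#' empty strings and read back as `NA` — never silently as zero, because the
#' complete-case analysis must distinguish "no use" from "not answered".
#' The first line of the file is a comment
#' `# trialcea_cohort schema_version=... recall_months_t0=... recall_months_t1=...`
#' carrying the recall-window metadata (6 months before baseline, 4 months
#' after, in the study design emulated here).
#'
#' @name cohort-schema
NULL

cohort_fixed_cols <- function() {
  c(
    "participant_id", "arm", "age_years", "gender_identity",
    "eq5d_profile_t0", "eq5d_profile_t1",
    "eq5d_index_t0", "eq5d_index_t1",
    "eq_vas_t0", "eq_vas_t1", "gsi_t0", "gsi_t1",
    "work_days_absent_t1", "work_days_present_t1", "work_performance_t1",
    "intervention_cost_t1",
    "flag_intention_to_treat", "flag_analysis_population", "flag_per_protocol"
  )
}

cohort_required_cols <- function() {
  setdiff(cohort_fixed_cols(),
          c("eq5d_profile_t0", "eq5d_profile_t1", "intervention_cost_t1"))
}

#' Construct / validate a cohort tibble
#'
#' `as_cohort()` coerces a data frame to the cohort schema (attaching the
#' recall-window attributes) and runs [validate_cohort()], which checks every
#' field invariant and reports violations with row numbers and field names.
#'
#' @param x A data frame following the [cohort-schema].
#' @param recall_months_t0,recall_months_t1 Recall-window lengths in months
#'   (defaults 6 and 4).
#' @return A validated cohort tibble of class `cea_cohort`.
#' @export
as_cohort <- function(x, recall_months_t0 = 6, recall_months_t1 = 4) {
  x <- tibble::as_tibble(x)
  if (recall_months_t0 <= 0 || recall_months_t1 <= 0) {
    stop_trialcea("recall windows must be strictly positive.", "trialcea_config_error")
  }
  missing_cols <- setdiff(cohort_required_cols(), names(x))
  if (length(missing_cols)) {
    stop_trialcea(
      sprintf("cohort is missing mandatory columns: %s",
              paste(missing_cols, collapse = ", ")),
      "trialcea_schema_error"
    )
  }
  for (col in c("eq5d_profile_t0", "eq5d_profile_t1")) {
    if (!col %in% names(x)) x[[col]] <- NA_character_
    x[[col]] <- as.character(x[[col]])
  }
  if (!"intervention_cost_t1" %in% names(x)) x$intervention_cost_t1 <- 0
  attr(x, "recall_months_t0") <- recall_months_t0
  attr(x, "recall_months_t1") <- recall_months_t1
  attr(x, "schema_version") <- cohort_schema_version()
  class(x) <- unique(c("cea_cohort", class(x)))
  validate_cohort(x)
}

cohort_schema_version <- function() "1.0"

field_bounds <- function() {
  list(
    age_years = c(0, Inf),
    eq5d_index_t0 = c(utility_floor(), 1), eq5d_index_t1 = c(utility_floor(), 1),
    eq_vas_t0 = c(0, 100), eq_vas_t1 = c(0, 100),
    gsi_t0 = c(0, 72), gsi_t1 = c(0, 72),
    work_days_absent_t1 = c(0, Inf), work_days_present_t1 = c(0, Inf),
    work_performance_t1 = c(0, 10),
    intervention_cost_t1 = c(0, Inf)
  )
}

#' @rdname as_cohort
#' @export
validate_cohort <- function(x) {
  problems <- character()
  note <- function(rows, field, msg) {
    sprintf("row %s: `%s` %s", rows, field, msg)
  }
  if (anyDuplicated(x$participant_id)) {
    dup <- x$participant_id[duplicated(x$participant_id)][1]
    problems <- c(problems, sprintf("duplicated participant_id '%s'", dup))
  }
  bad_arm <- which(!x$arm %in% c("IG", "CG"))
  if (length(bad_arm)) {
    problems <- c(problems, note(bad_arm[1], "arm", "must be 'IG' or 'CG'"))
  }
  bad_gi <- which(!is.na(x$gender_identity) &
                    !x$gender_identity %in%
                      c("trans_masculine", "trans_feminine", "nonbinary"))
  if (length(bad_gi)) {
    problems <- c(problems, note(bad_gi[1], "gender_identity", "unknown category"))
  }
  bounds <- field_bounds()
  ru_cols <- grep("^ru_t[01]_", names(x), value = TRUE)
  for (col in ru_cols) bounds[[col]] <- c(0, Inf)
  for (field in names(bounds)) {
    if (!field %in% names(x)) next
    b <- bounds[[field]]
    v <- x[[field]]
    bad <- which(!is.na(v) & (v < b[1] | v > b[2]))
    if (length(bad)) {
      problems <- c(problems, note(
        bad[1], field,
        sprintf("value %s outside [%s, %s]", format(v[bad[1]]), format(b[1]), format(b[2]))
      ))
    }
  }
  for (col in c("eq5d_profile_t0", "eq5d_profile_t1")) {
    v <- x[[col]]
    ok <- is.na(v) | grepl("^[1-5]{5}$", v)
    if (!all(ok)) {
      problems <- c(problems, note(which(!ok)[1], col, "is not a 5-digit profile with digits 1-5"))
    }
  }
  if (length(problems)) {
    stop_trialcea(
      c("cohort validation failed:", setNames(problems, rep("x", length(problems)))),
      "trialcea_validation_error"
    )
  }
  x
}

#' Read and write cohort CSV files
#'
#' The interchange format is documented in [cohort-schema]. `read_cohort()`
#' validates every row and fails with row-indexed diagnostics; rejecting bad
#' files at the boundary keeps downstream stages assumption-free.
#' `write_cohort()` writes a file that `read_cohort()` parses back into an
#' equal cohort (floats round-trip through full precision).
#'
#' @param path CSV path.
#' @param schema_version Expected schema version (only `"1.0"` exists).
#' @return `read_cohort()`: a validated `cea_cohort` tibble;
#'   `write_cohort()`: `path`, invisibly.
#' @export
read_cohort <- function(path, schema_version = cohort_schema_version()) {
  if (!file.exists(path)) {
    stop_trialcea(sprintf("cohort file not found: %s", path), "trialcea_io_error")
  }
  header <- readLines(path, n = 1L)
  meta <- list(schema_version = schema_version, recall_months_t0 = 6, recall_months_t1 = 4)
  if (startsWith(header, "#")) {
    kv <- regmatches(header, gregexpr("[a-z_0-9]+=[^ ]+", header))[[1]]
    for (pair in kv) {
      parts <- strsplit(pair, "=", fixed = TRUE)[[1]]
      meta[[parts[1]]] <- parts[2]
    }
  }
  if (!identical(as.character(meta$schema_version), schema_version)) {
    stop_trialcea(
      sprintf("cohort file declares schema_version %s; expected %s.",
              meta$schema_version, schema_version),
      "trialcea_schema_error"
    )
  }
  first_lines <- readLines(path, n = 2L)
  header_line <- first_lines[!startsWith(first_lines, "#")][1]
  col_names <- strsplit(header_line, ",", fixed = TRUE)[[1]]
  chr_cols <- c("participant_id", "arm", "gender_identity",
                "eq5d_profile_t0", "eq5d_profile_t1")
  lgl_cols <- grep("^flag_", col_names, value = TRUE)
  ctypes <- lapply(setNames(col_names, col_names), function(nm) {
    if (nm %in% chr_cols) readr::col_character()
    else if (nm %in% lgl_cols) readr::col_logical()
    else readr::col_double()
  })
  raw <- readr::read_csv(
    path, na = "", comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = do.call(readr::cols, ctypes)
  )
  as_cohort(
    raw,
    recall_months_t0 = as.numeric(meta$recall_months_t0),
    recall_months_t1 = as.numeric(meta$recall_months_t1)
  )
}

#' @rdname read_cohort
#' @param cohort A validated cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  meta <- sprintf(
    "# trialcea_cohort schema_version=%s recall_months_t0=%s recall_months_t1=%s",
    attr(cohort, "schema_version") %||% cohort_schema_version(),
    attr(cohort, "recall_months_t0") %||% 6,
    attr(cohort, "recall_months_t1") %||% 4
  )
  body <- readr::format_csv(as.data.frame(cohort), na = "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(meta, con)
  cat(body, file = con)
  invisible(path)
}
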