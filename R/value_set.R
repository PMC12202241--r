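#' EQ-5D-5L value sets
#'
#' A value set maps each 5-digit EQ-5D-5L health profile (one level 1-5 per
#' dimension: mobility MO, self-care SC, usual activities UA, pain/discomfort
#' PD, anxiety/depression AD) to a societal utility index. The mapping is
#' additive: the no-problem profile `"11111"` scores the intercept (1), and
#' each dimension level beyond 1 subtracts a decrement. National value sets
#' (e.g. the German one) are external publications; supply them as a CSV via
#' [read_value_set()]. For offline work the package bundles a *synthetic*
#' value set whose extreme profiles hit exactly 1 and -0.661, the range of
#' the German tariff.
#'
#' @param decrements A data frame with columns `dimension` (MO, SC, UA, PD,
#'   AD), `level` (2-5) and `decrement` (non-positive utility decrements,
#'   non-increasing in level within a dimension).
#' @param intercept Utility of the no-problem profile; 1 for every published
#'   EQ-5D-5L tariff.
#'
#' @return A tibble of class `eq5d_value_set` with attributes `intercept` and
#'   `floor` (the index of `"55555"`).
#' @examples
#' vs <- synthetic_value_set()
#' score_profile("11111", vs)
#' score_profile("55555", vs)
#' @export
value_set <- function(decrements, intercept = 1) {
  dims <- c("MO", "SC", "UA", "PD", "AD")
  decrements <- tibble::as_tibble(decrements)
  need <- c("dimension", "level", "decrement")
  if (!all(need %in% names(decrements))) {
    stop_trialcea(
      sprintf("value set needs columns %s.", paste(need, collapse = ", ")),
      "trialcea_schema_error"
    )
  }
  decrements <- dplyr::arrange(decrements, .data$dimension, .data$level)
  if (!setequal(unique(decrements$dimension), dims) ||
      !all(decrements$level %in% 2:5) ||
      nrow(decrements) != 20L) {
    stop_trialcea(
      "value set must hold exactly levels 2-5 for dimensions MO, SC, UA, PD, AD.",
      "trialcea_validation_error"
    )
  }
  if (any(decrements$decrement > 0)) {
    stop_trialcea("value-set decrements must be <= 0.", "trialcea_validation_error")
  }
  bad <- decrements |>
    dplyr::group_by(.data$dimension) |>
    dplyr::summarise(ok = all(diff(.data$decrement) <= 1e-12), .groups = "drop")
  if (!all(bad$ok)) {
    stop_trialcea(
      "value-set decrements must be non-increasing in level within each dimension.",
      "trialcea_validation_error"
    )
  }
  floor_val <- intercept + sum(decrements$decrement[decrements$level == 5L])
  structure(
    decrements,
    intercept = intercept,
    floor = floor_val,
    class = c("eq5d_value_set", class(decrements))
  )
}

#' @rdname value_set
#' @export
synthetic_value_set <- function() {
  # dimension maxima sum to 1.661 exactly so "55555" scores 1 - 1.661 = -0.661;
  # within-dimension level fractions are monotone. Synthetic: NOT a national
  # tariff, only shape- and range-faithful.
  dim_max <- c(MO = 0.400, SC = 0.300, UA = 0.300, PD = 0.360, AD = 0.301)
  frac <- c(`2` = 0.20, `3` = 0.45, `4` = 0.75, `5` = 1.00)
  grid <- tidyr::expand_grid(dimension = names(dim_max), level = 2:5)
  grid$decrement <- -dim_max[grid$dimension] * frac[as.character(grid$level)]
  value_set(grid, intercept = 1)
}

#' Read a value set from CSV
#'
#' Expected columns: `dimension`, `level`, `decrement`, with one extra row
#' `dimension = "intercept", level = 0` carrying the intercept, or an
#' `intercept` passed explicitly.
#'
#' @param path CSV file path.
#' @return An `eq5d_value_set`.
#' @export
read_value_set <- function(path) {
  if (!file.exists(path)) {
    stop_trialcea(sprintf("value-set file not found: %s", path), "trialcea_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  icpt_row <- raw$dimension == "intercept"
  intercept <- if (any(icpt_row)) raw$decrement[icpt_row][1] else 1
  value_set(raw[!icpt_row, , drop = FALSE], intercept = intercept)
}

#' @rdname read_value_set
#' @param vs An `eq5d_value_set`.
#' @export
write_value_set <- function(vs, path) {
  out <- tibble::as_tibble(vs)
  out <- dplyr::bind_rows(
    tibble::tibble(dimension = "intercept", level = 0L, decrement = attr(vs, "intercept")),
    out
  )
  readr::write_csv(out, path)
  invisible(path)
}

parse_profile <- function(profile) {
  if (is.na(profile)) return(rep(NA_integer_, 5))
  chars <- strsplit(as.character(profile), "", fixed = TRUE)[[1]]
  if (length(chars) != 5L || !all(chars %in% as.character(1:5))) {
    stop_trialcea(
      sprintf("invalid EQ-5D-5L profile '%s': need 5 digits, each 1-5.", profile),
      "trialcea_validation_error"
    )
  }
  as.integer(chars)
}

#' Score EQ-5D-5L profiles against a value set
#'
#' @param profile Character vector of 5-digit profiles such as `"21132"`.
#' @param vs An [value_set()] object.
#' @return Numeric utility indices in `[floor, 1]`.
#' @export
score_profile <- function(profile, vs) {
  stopifnot(inherits(vs, "eq5d_value_set"))
  dims <- c("MO", "SC", "UA", "PD", "AD")
  # lookup matrix: dimensions x levels 1-5 (level 1 decrement is 0)
  lut <- matrix(0, nrow = 5, ncol = 5, dimnames = list(dims, 1:5))
  lut[cbind(vs$dimension, vs$level)] <- vs$decrement
  icpt <- attr(vs, "intercept")
  vapply(profile, function(p) {
    lv <- parse_profile(p)
    if (anyNA(lv)) return(NA_real_)
    icpt + sum(lut[cbind(dims, lv)])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Enumerate all EQ-5D-5L health profiles
#'
#' The descriptive system spans 5 dimensions x 5 levels = 3125 states.
#'
#' @return Character vector of the 3125 profiles in lexicographic order.
#' @export
all_profiles <- function() {
  g <- expand.grid(AD = 1:5, PD = 1:5, UA = 1:5, SC = 1:5, MO = 1:5)
  sort(paste0(g$MO, g$SC, g$UA, g$PD, g$AD))
}
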