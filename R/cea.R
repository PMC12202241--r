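#' Incremental cost-effectiveness ratio with quadrant classification
#'
#' The ICER is the incremental cost per incremental unit of effect,
#' `delta_cost / delta_effect`. The pair is placed on the
#' cost-effectiveness plane: NE (costlier, more effective), SE (cheaper,
#' more effective — the intervention dominates), NW (costlier, less
#' effective — dominated), SW (cheaper, less effective). Boundary rule:
#' `delta_effect = 0` yields an undefined ratio (flagged, never a division
#' error) and `delta_cost = 0` is classed with the non-negative-cost
#' half-plane (NE/NW).
#'
#' @param delta_cost Incremental cost in euros (IG - CG).
#' @param delta_effect Incremental effect (QALYs or probability of reliable
#'   improvement).
#' @return A one-row tibble of class `icer_result`: `delta_cost`,
#'   `delta_effect`, `icer` (`NA` when undefined), `quadrant`, `dominance`.
#' @examples
#' icer(1390, 0.138)
#' @export
icer <- function(delta_cost, delta_effect) {
  assert_number(delta_cost, "delta_cost")
  assert_number(delta_effect, "delta_effect")
  quadrant <- classify_quadrant(delta_cost, delta_effect)
  ratio <- if (delta_effect == 0) NA_real_ else delta_cost / delta_effect
  dominance <- switch(quadrant,
    SE = "intervention_dominant",
    NW = "intervention_dominated",
    "none"
  )
  structure(
    tibble::tibble(
      delta_cost = delta_cost, delta_effect = delta_effect,
      icer = ratio, quadrant = quadrant, dominance = dominance
    ),
    class = c("icer_result", class(tibble::tibble()))
  )
}

# vectorised quadrant rule; zero effect joins the "less effective" side,
# zero cost the "costlier" side (ties have probability zero for continuous
# draws; the rule only needs to be deterministic and documented)
classify_quadrant <- function(delta_cost, delta_effect) {
  dplyr::case_when(
    delta_effect > 0 & delta_cost >= 0 ~ "NE",
    delta_effect > 0 & delta_cost < 0 ~ "SE",
    delta_effect <= 0 & delta_cost >= 0 ~ "NW",
    TRUE ~ "SW"
  )
}

#' Net monetary benefit
#'
#' `nmb = wtp * delta_effect - delta_cost`: the incremental effect valued
#' at the willingness-to-pay threshold, minus the incremental cost. The
#' intervention is cost-effective at `wtp` when the NMB is positive.
#'
#' @param wtp Willingness to pay per effect unit (euros).
#' @param delta_effect,delta_cost Incremental effect and cost.
#' @return Euro net benefit (vectorised over any argument).
#' @export
nmb <- function(wtp, delta_effect, delta_cost) {
  wtp * delta_effect - delta_cost
}

#' Default willingness-to-pay grids
#'
#' 0 to 300,000 euros per QALY in 1,000-euro steps, and 0 to 30,000 euros
#' per additional reliable improvement in 100-euro steps — covering every
#' threshold commonly discussed for these effect measures (50,000 and
#' 150,000 euros per QALY; 5,000 and 15,000 euros per improvement).
#'
#' @param effect_name Effect measure the grid is for.
#' @return Numeric vector of WTP values.
#' @export
default_wtp_grid <- function(effect_name = c("QALY_EQ5D", "QALY_VAS",
                                             "RELIABLE_IMPROVEMENT")) {
  effect_name <- match.arg(effect_name)
  if (effect_name == "RELIABLE_IMPROVEMENT") seq(0, 30000, by = 100)
  else seq(0, 300000, by = 1000)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability of cost-effectiveness
#' is estimated from the bootstrap draws under one of two definitions:
#'
#' * `"net_benefit"` (default): the fraction of draws with strictly
#'   positive net monetary benefit, `wtp * delta_effect - delta_cost > 0`.
#'   Quadrant-safe; ties count as not cost-effective.
#' * `"icer_below_wtp"`: the verbal "proportion of bootstrapped ICERs below
#'   the threshold", completed with the quadrant rule that makes it agree
#'   with the net-benefit sign: SE draws (dominant) always count, NW draws
#'   never, and in SW — where a *lower* ICER is worse — a draw counts when
#'   its ICER exceeds the threshold.
#'
#' The two definitions agree exactly when every draw lies in the NE
#' quadrant. Under `net_benefit` the curve is non-decreasing in WTP
#' whenever all draws have positive incremental effect.
#'
#' @param draws A [bootstrap_contrasts()] draw set (or any data frame with
#'   `delta_cost`, `delta_effect`).
#' @param wtp_grid Ordered willingness-to-pay values.
#' @param definition Curve definition, see above.
#' @return A tibble of class `ceac_curve`: `wtp`, `probability`,
#'   `definition`.
#' @export
ceac <- function(draws, wtp_grid, definition = c("net_benefit", "icer_below_wtp")) {
  definition <- match.arg(definition)
  if (!length(wtp_grid)) {
    stop_trialcea("wtp_grid must be nonempty.", "trialcea_validation_error")
  }
  if (!nrow(draws)) stop_trialcea("empty draw set.", "trialcea_validation_error")
  dc <- draws$delta_cost
  de <- draws$delta_effect
  prob <- if (definition == "net_benefit") {
    vapply(wtp_grid, function(l) mean(l * de - dc > 0), numeric(1))
  } else {
    quad <- classify_quadrant(dc, de)
    ratio <- ifelse(de == 0, NA_real_, dc / de)
    vapply(wtp_grid, function(l) {
      ok <- (quad == "NE" & ratio < l) |
        (quad == "SE") |
        (quad == "SW" & ratio > l)
      mean(ok & !is.na(ratio) | (quad == "SE"))
    }, numeric(1))
  }
  structure(
    tibble::tibble(wtp = wtp_grid, probability = prob, definition = definition),
    class = c("ceac_curve", class(tibble::tibble()))
  )
}

#' Cost-effectiveness plane quadrant fractions
#'
#' Fractions of bootstrap draws falling in each quadrant of the
#' cost-effectiveness plane (they sum to 1; boundary draws follow the
#' [icer()] tie rule).
#'
#' @param draws Draw set with `delta_cost`, `delta_effect`.
#' @return A tibble `quadrant`, `fraction` covering NE, NW, SE, SW.
#' @export
plane_summary <- function(draws) {
  if (!nrow(draws)) stop_trialcea("empty draw set.", "trialcea_validation_error")
  quad <- factor(classify_quadrant(draws$delta_cost, draws$delta_effect),
                 levels = c("NE", "NW", "SE", "SW"))
  tab <- table(quad) / length(quad)
  tibble::tibble(quadrant = names(tab), fraction = as.numeric(tab))
}
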