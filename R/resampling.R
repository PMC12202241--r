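#' Bootstrap the adjusted cost and effect differences
#'
#' Resamples participants with replacement (the participant is the unit of
#' resampling, so each draw keeps a participant's costs and effects paired),
#' refits the SUR system on every replicate, and records the adjusted
#' IG-CG difference in costs and in the effect. Replicates whose refit
#' fails (e.g. a collinear resample) are redrawn with fresh resamples, up
#' to `10 * B` total attempts, and the number of redraws is reported —
#' silently dropping them would bias the acceptability-curve denominator.
#' The draw set is exactly reproducible given `(seed, B, data)`.
#'
#' @param data Analysis table (see [build_analysis_table()]).
#' @param spec A [sur_spec()].
#' @param B Number of bootstrap replications (the analysis default is 1000).
#' @param seed Seed for the resampling stream.
#' @param stratify_by_arm Resample within arms, preserving arm sizes
#'   (default `FALSE`: plain nonparametric resampling of the whole sample).
#' @return A tibble of class `cea_draws` with columns `replicate`,
#'   `delta_cost`, `delta_effect`; attributes carry `B`, `seed`, the
#'   full-sample point estimates and the failed-refit count.
#' @export
bootstrap_contrasts <- function(data, spec, B = 1000, seed = 1,
                                stratify_by_arm = FALSE) {
  stopifnot(inherits(spec, "sur_spec"))
  if (B < 1) stop_trialcea("B must be >= 1.", "trialcea_config_error")
  fit <- fit_sur(data, spec)
  mp <- fit$model
  point <- point_contrast(fit)
  n <- mp$n
  arm_ig <- mp$data$arm == "IG"
  idx_ig <- which(arm_ig)
  idx_cg <- which(!arm_ig)
  at_c <- arm_term(fit, "cost")
  at_e <- arm_term(fit, "effect")
  k1 <- ncol(mp$X1)

  set.seed(seed)
  dc <- numeric(B)
  de <- numeric(B)
  failed <- 0L
  b <- 1L
  attempts <- 0L
  while (b <= B) {
    attempts <- attempts + 1L
    if (attempts > 10L * B) {
      stop_trialcea("bootstrap retry budget exhausted: refits keep failing.",
                    "trialcea_estimation_error")
    }
    idx <- if (stratify_by_arm) {
      c(sample(idx_ig, length(idx_ig), replace = TRUE),
        sample(idx_cg, length(idx_cg), replace = TRUE))
    } else {
      sample.int(n, n, replace = TRUE)
    }
    est <- tryCatch(
      {
        f <- sur_fgls(mp$X1[idx, , drop = FALSE], mp$y1[idx],
                      mp$X2[idx, , drop = FALSE], mp$y2[idx])
        c(f$beta[at_c$index], f$beta[at_e$index])
      },
      error = function(e) NULL
    )
    if (is.null(est) || !all(is.finite(est))) {
      failed <- failed + 1L
      next
    }
    dc[b] <- est[1]
    de[b] <- est[2]
    b <- b + 1L
  }
  structure(
    tibble::tibble(replicate = seq_len(B), delta_cost = dc, delta_effect = de),
    B = B, seed = seed,
    point_estimate = point,
    n = n, n_failed_refits = failed,
    class = c("cea_draws", class(tibble::tibble()))
  )
}

point_contrast <- function(fit) {
  c(delta_cost = unname(fit$coefficients$cost[arm_term(fit, "cost")$name]),
    delta_effect = unname(fit$coefficients$effect[arm_term(fit, "effect")$name]))
}

#' Leave-one-out (jackknife) contrast estimates
#'
#' Refits the SUR system dropping one participant at a time and records the
#' arm coefficients of both equations; the jackknife skewness of these
#' estimates supplies the BCa acceleration. Rows whose leave-one-out refit
#' fails are dropped.
#'
#' @inheritParams bootstrap_contrasts
#' @return A matrix with columns `delta_cost`, `delta_effect`, one row per
#'   usable leave-one-out estimate.
#' @export
jackknife_contrasts <- function(data, spec) {
  fit <- fit_sur(data, spec)
  mp <- fit$model
  at_c <- arm_term(fit, "cost")
  at_e <- arm_term(fit, "effect")
  out <- matrix(NA_real_, mp$n, 2, dimnames = list(NULL, c("delta_cost", "delta_effect")))
  for (i in seq_len(mp$n)) {
    f <- tryCatch(
      sur_fgls(mp$X1[-i, , drop = FALSE], mp$y1[-i],
               mp$X2[-i, , drop = FALSE], mp$y2[-i]),
      error = function(e) NULL
    )
    if (!is.null(f)) out[i, ] <- c(f$beta[at_c$index], f$beta[at_e$index])
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Bias-corrected accelerated (BCa) bootstrap interval
#'
#' Standard BCa construction: the bias-correction constant `z0` is the
#' normal quantile of the fraction of draws below the full-sample point
#' estimate; the acceleration `a` is the jackknife skewness of the
#' leave-one-out estimates,
#' `a = sum((m - jk)^3) / (6 * sum((m - jk)^2)^{3/2})`; the interval
#' endpoints are the draw quantiles (linear-interpolation, R type 7) at the
#' adjusted levels `Phi(z0 + (z0 + z_alpha) / (1 - a (z0 + z_alpha)))`.
#' With `z0 = 0` and `a = 0` the interval reduces exactly to the plain
#' percentile interval. If all draws are equal a degenerate `[v, v]`
#' interval is returned with a warning.
#'
#' @param draws A [bootstrap_contrasts()] draw set.
#' @param statistic `"delta_cost"` or `"delta_effect"`.
#' @param data,spec The analysis table and [sur_spec()] the draws came
#'   from; used for the jackknife. Ignored when `jackknife` is supplied.
#' @param level Interval level (default 0.95).
#' @param jackknife Optional precomputed leave-one-out estimates of the
#'   statistic (numeric vector), for custom statistics or testing.
#' @return A one-row tibble of class `bca_interval`: `statistic`, `lower`,
#'   `upper`, `level`, `z0`, `acceleration`, `point`.
#' @export
bca_interval <- function(draws, statistic = c("delta_cost", "delta_effect"),
                         data = NULL, spec = NULL, level = 0.95,
                         jackknife = NULL) {
  statistic <- match.arg(statistic)
  th <- draws[[statistic]]
  if (!length(th)) stop_trialcea("empty draw set.", "trialcea_validation_error")
  point <- attr(draws, "point_estimate")[[statistic]]
  if (max(th) - min(th) < .Machine$double.eps) {
    warn("all bootstrap draws are identical; returning a degenerate interval.")
    return(new_bca(statistic, th[1], th[1], level, 0, 0, point))
  }
  prop_below <- mean(th < point)
  if (prop_below == 0 || prop_below == 1) {
    warn("point estimate outside the draw range; z0 clamped.")
    prop_below <- clip(prop_below, 1 / (2 * length(th)), 1 - 1 / (2 * length(th)))
  }
  z0 <- qnorm(prop_below)
  if (is.null(jackknife)) {
    if (is.null(data) || is.null(spec)) {
      stop_trialcea("supply `data` and `spec` (or `jackknife`) for the acceleration.",
                    "trialcea_config_error")
    }
    jk <- jackknife_contrasts(data, spec)[, statistic]
  } else {
    jk <- jackknife
  }
  dev <- mean(jk) - jk
  denom <- 6 * sum(dev^2)^1.5
  a <- if (denom < .Machine$double.eps) 0 else sum(dev^3) / denom
  zl <- qnorm((1 - level) / 2)
  zu <- qnorm(1 - (1 - level) / 2)
  alpha1 <- pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
  alpha2 <- pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))
  q <- quantile(th, c(alpha1, alpha2), type = 7, names = FALSE)
  new_bca(statistic, q[1], q[2], level, z0, a, point)
}

new_bca <- function(statistic, lower, upper, level, z0, a, point) {
  structure(
    tibble::tibble(
      statistic = statistic, lower = lower, upper = upper, level = level,
      z0 = z0, acceleration = a, point = point
    ),
    class = c("bca_interval", class(tibble::tibble()))
  )
}

#' @rdname bootstrap_contrasts
#' @param x A `cea_draws` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.cea_draws <- function(x, ...) {
  pt <- attr(x, "point_estimate")
  tibble::tibble(
    B = attr(x, "B"), seed = attr(x, "seed"), n = attr(x, "n"),
    n_failed_refits = attr(x, "n_failed_refits"),
    delta_cost = unname(pt["delta_cost"]),
    delta_effect = unname(pt["delta_effect"]),
    sd_delta_cost = sd(x$delta_cost),
    sd_delta_effect = sd(x$delta_effect)
  )
}

#' Serialize / restore a bootstrap draw set
#'
#' The draw set is written as a CSV (`replicate`, `delta_cost`,
#' `delta_effect`) with a JSON sidecar (`<path>.json`) holding seed, B,
#' point estimates and failure counts, so downstream cost-effectiveness
#' summaries are re-runnable without refitting.
#'
#' @param draws A `cea_draws` object.
#' @param path CSV path; the sidecar goes to `paste0(path, ".json")`.
#' @return `write_draws()`: `path` invisibly; `read_draws()`: the restored
#'   `cea_draws`.
#' @export
write_draws <- function(draws, path) {
  readr::write_csv(tibble::as_tibble(draws), path)
  meta <- list(
    B = attr(draws, "B"), seed = attr(draws, "seed"), n = attr(draws, "n"),
    n_failed_refits = attr(draws, "n_failed_refits"),
    point_estimate = as.list(attr(draws, "point_estimate"))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    tibble::as_tibble(d),
    B = meta$B, seed = meta$seed, n = meta$n,
    n_failed_refits = meta$n_failed_refits,
    point_estimate = unlist(meta$point_estimate),
    class = c("cea_draws", class(tibble::tibble()))
  )
}
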