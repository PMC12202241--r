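#' Specify the two-equation cost/effect regression system
#'
#' The cost equation regresses follow-up total costs on arm, gender
#' identity, age and baseline-window total costs; the effect equation
#' regresses the chosen effect (EQ-5D-5L QALYs, EQ-VAS QALYs, or the
#' reliable-improvement indicator as a linear probability model) on arm,
#' gender identity, age, baseline utility index and baseline GSI. Both
#' equations are estimated jointly by seemingly unrelated regression so the
#' cross-equation error correlation between costs and effects is carried
#' into the uncertainty of the cost-effectiveness ratio.
#'
#' @param effect_name One of `"QALY_EQ5D"`, `"QALY_VAS"`,
#'   `"RELIABLE_IMPROVEMENT"`.
#' @param cost_covariates,effect_covariates Right-hand-side variable names;
#'   `arm` must appear in both.
#' @return A list of class `sur_spec` with the two formulas.
#' @export
sur_spec <- function(effect_name = c("QALY_EQ5D", "QALY_VAS", "RELIABLE_IMPROVEMENT"),
                     cost_covariates = c("arm", "gender_identity", "age_years", "cost_t0"),
                     effect_covariates = c("arm", "gender_identity", "age_years",
                                           "eq5d_index_t0", "gsi_t0")) {
  effect_name <- match.arg(effect_name)
  if (!"arm" %in% cost_covariates || !"arm" %in% effect_covariates) {
    stop_trialcea("`arm` must be a covariate in both equations.", "trialcea_config_error")
  }
  effect_col <- switch(effect_name,
    QALY_EQ5D = "qaly", QALY_VAS = "qaly_vas",
    RELIABLE_IMPROVEMENT = "reliable_improvement"
  )
  structure(
    list(
      effect_name = effect_name,
      cost_formula = stats::reformulate(cost_covariates, response = "cost_t1"),
      effect_formula = stats::reformulate(effect_covariates, response = effect_col),
      variables = unique(c("cost_t1", effect_col, cost_covariates, effect_covariates))
    ),
    class = "sur_spec"
  )
}

model_parts <- function(data, spec) {
  vars <- intersect(spec$variables, names(data))
  missing_vars <- setdiff(spec$variables, names(data))
  if (length(missing_vars)) {
    stop_trialcea(
      sprintf("analysis table lacks model variables: %s",
              paste(missing_vars, collapse = ", ")),
      "trialcea_schema_error"
    )
  }
  cc <- complete.cases(data[, vars, drop = FALSE])
  d <- data[cc, , drop = FALSE]
  d$arm <- factor(d$arm, levels = c("CG", "IG")) # CG reference: coef is IG - CG
  if ("gender_identity" %in% names(d) && !is.factor(d$gender_identity)) {
    d$gender_identity <- factor(
      d$gender_identity,
      levels = intersect(c("trans_masculine", "trans_feminine", "nonbinary"),
                         unique(d$gender_identity))
    )
  }
  eff <- all.vars(spec$effect_formula)[1]
  if (is.logical(d[[eff]])) d[[eff]] <- as.numeric(d[[eff]])
  X1 <- model.matrix(spec$cost_formula, d)
  X2 <- model.matrix(spec$effect_formula, d)
  list(
    data = d, n = nrow(d),
    X1 = X1, y1 = d[[all.vars(spec$cost_formula)[1]]],
    X2 = X2, y2 = d[[eff]]
  )
}

check_rank <- function(X, eq) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop_trialcea(
      sprintf("%s equation design is rank deficient; collinear columns: %s",
              eq, paste(drop, collapse = ", ")),
      "trialcea_estimation_error"
    )
  }
  invisible(qr_x)
}

# core Zellner FGLS on prepared matrices; kept lean because the bootstrap
# and jackknife call it tens of thousands of times
sur_fgls <- function(X1, y1, X2, y2, iterate = FALSE, max_iter = 50, tol = 1e-8) {
  n <- length(y1)
  b1 <- qr.coef(qr(X1), y1)
  b2 <- qr.coef(qr(X2), y2)
  beta <- c(b1, b2)
  k1 <- ncol(X1)
  for (it in seq_len(if (iterate) max_iter else 1L)) {
    e1 <- y1 - X1 %*% beta[1:k1]
    e2 <- y2 - X2 %*% beta[(k1 + 1):length(beta)]
    S <- crossprod(cbind(e1, e2)) / n
    W <- solve(S)
    A <- rbind(
      cbind(W[1, 1] * crossprod(X1), W[1, 2] * crossprod(X1, X2)),
      cbind(W[2, 1] * crossprod(X2, X1), W[2, 2] * crossprod(X2))
    )
    rhs <- c(
      W[1, 1] * crossprod(X1, y1) + W[1, 2] * crossprod(X1, y2),
      W[2, 1] * crossprod(X2, y1) + W[2, 2] * crossprod(X2, y2)
    )
    # Jacobi equilibration: euro-scale and effect-scale blocks differ by many
    # orders of magnitude, so precondition before solving
    d <- sqrt(diag(A))
    Ad <- A / outer(d, d)
    beta_new <- solve(Ad, rhs / d) / d
    done <- max(abs(beta_new - beta)) < tol
    beta <- drop(beta_new)
    if (done) break
  }
  e1 <- drop(y1 - X1 %*% beta[1:k1])
  e2 <- drop(y2 - X2 %*% beta[(k1 + 1):length(beta)])
  S <- crossprod(cbind(e1, e2)) / n
  vcov_model <- solve(Ad) / outer(d, d)
  # heteroskedasticity-robust sandwich over participants
  U1 <- X1 * (W[1, 1] * e1 + W[1, 2] * e2)
  U2 <- X2 * (W[2, 1] * e1 + W[2, 2] * e2)
  U <- cbind(U1, U2)
  vcov_robust <- vcov_model %*% crossprod(U) %*% vcov_model
  list(beta = beta, k1 = k1, sigma = S, e1 = e1, e2 = e2,
       vcov_model = vcov_model, vcov_robust = vcov_robust, W = W)
}

#' Fit a two-equation SUR system by Zellner feasible GLS
#'
#' Equation-wise ordinary least squares provides residuals, the 2x2
#' cross-equation residual covariance is estimated, and generalized least
#' squares is run on the stacked system. With identical design matrices in
#' both equations the FGLS estimate reduces exactly to equation-wise OLS
#' (Zellner's classical result), which anchors the correctness tests.
#' Estimation is complete-case on the union of model variables.
#'
#' @param data Analysis table holding the model variables (see
#'   [build_analysis_table()] or [sur_spec()]).
#' @param spec A [sur_spec()].
#' @param iterate Iterate FGLS to convergence instead of the standard
#'   one-step estimator (default `FALSE`).
#' @return An object of class `sur_fit`: coefficients per equation, the
#'   residual covariance, model-based and heteroskedasticity-robust
#'   covariance matrices, and the rows used.
#' @export
fit_sur <- function(data, spec, iterate = FALSE) {
  stopifnot(inherits(spec, "sur_spec"))
  mp <- model_parts(data, spec)
  if (mp$n < max(ncol(mp$X1), ncol(mp$X2)) + 2L) {
    stop_trialcea(
      sprintf("only %d complete cases for %d parameters.", mp$n,
              max(ncol(mp$X1), ncol(mp$X2))),
      "trialcea_estimation_error"
    )
  }
  check_rank(mp$X1, "cost")
  check_rank(mp$X2, "effect")
  f <- sur_fgls(mp$X1, mp$y1, mp$X2, mp$y2, iterate = iterate)
  k1 <- f$k1
  coefs <- list(
    cost = setNames(f$beta[1:k1], colnames(mp$X1)),
    effect = setNames(f$beta[(k1 + 1):length(f$beta)], colnames(mp$X2))
  )
  structure(
    list(
      coefficients = coefs, sigma = f$sigma,
      vcov_model = f$vcov_model, vcov_robust = f$vcov_robust,
      n_used = mp$n, spec = spec, model = mp, iterate = iterate,
      residuals = list(cost = f$e1, effect = f$e2)
    ),
    class = "sur_fit"
  )
}

#' @export
print.sur_fit <- function(x, ...) {
  cat(sprintf("Seemingly unrelated regression fit (n = %d)\n", x$n_used))
  cat(sprintf("Effect measure: %s\n", x$spec$effect_name))
  cat(sprintf("Residual correlation (cost, effect): %.3f\n",
              stats::cov2cor(x$sigma)[1, 2]))
  cat("\nCost equation:\n")
  print(round(x$coefficients$cost, 4))
  cat("\nEffect equation:\n")
  print(round(x$coefficients$effect, 6))
  invisible(x)
}

arm_term <- function(fit, equation) {
  nm <- names(fit$coefficients[[equation]])
  hit <- grep("^armIG$", nm)
  if (!length(hit)) {
    stop_trialcea("arm coefficient not found; was `arm` in the model?",
                  "trialcea_estimation_error")
  }
  offset <- if (equation == "cost") 0L else length(fit$coefficients$cost)
  list(index = offset + hit, name = nm[hit])
}

#' Adjusted group means and IG-CG differences (g-computation)
#'
#' Predicts every participant's outcome under `arm = "IG"` and under
#' `arm = "CG"`, averages each counterfactual column, and reports the
#' adjusted means, the difference, its robust standard error and a normal
#' two-sided p-value for both equations. When arm enters linearly without
#' interactions the difference equals the arm coefficient; this identity is
#' asserted at run time.
#'
#' @param fit A [fit_sur()] object.
#' @return A tibble with rows `total_cost` and the effect measure:
#'   `outcome`, `mean_ig`, `mean_cg`, `difference`, `se`, `p_value`, `n`.
#' @export
adjusted_contrast <- function(fit) {
  stopifnot(inherits(fit, "sur_fit"))
  d <- fit$model$data
  rows <- purrr::map(c(cost = "cost", effect = "effect"), function(eq) {
    form <- if (eq == "cost") fit$spec$cost_formula else fit$spec$effect_formula
    beta <- fit$coefficients[[eq]]
    preds <- purrr::map_dbl(c(IG = "IG", CG = "CG"), function(a) {
      dd <- d
      dd$arm <- factor(a, levels = c("CG", "IG"))
      mean(model.matrix(form, dd) %*% beta)
    })
    at <- arm_term(fit, eq)
    diff_gcomp <- preds[["IG"]] - preds[["CG"]]
    stopifnot(abs(diff_gcomp - beta[at$name]) < 1e-9 * max(1, abs(beta[at$name])))
    se <- sqrt(fit$vcov_robust[at$index, at$index])
    tibble::tibble(
      outcome = if (eq == "cost") "total_cost" else fit$spec$effect_name,
      mean_ig = preds[["IG"]], mean_cg = preds[["CG"]],
      difference = diff_gcomp, se = se,
      p_value = 2 * pnorm(-abs(diff_gcomp / se)),
      n = fit$n_used
    )
  })
  dplyr::bind_rows(rows)
}

#' Unadjusted two-group comparison by linear-model F test
#'
#' Regresses the outcome on group and reports the one-way F statistic, its
#' p-value, and the raw mean difference. On two groups the F statistic
#' equals the squared equal-variance two-sample t statistic.
#'
#' @param values_ig,values_cg Outcome values per arm (missing values
#'   dropped).
#' @return One-row tibble: `mean_ig`, `mean_cg`, `difference`, `se`,
#'   `f_statistic`, `p_value`, `n`.
#' @export
unadjusted_comparison <- function(values_ig, values_cg) {
  values_ig <- values_ig[!is.na(values_ig)]
  values_cg <- values_cg[!is.na(values_cg)]
  if (length(values_ig) < 2 || length(values_cg) < 2) {
    stop_trialcea("need >= 2 observations per arm.", "trialcea_estimation_error")
  }
  y <- c(values_ig, values_cg)
  g <- factor(rep(c("IG", "CG"), c(length(values_ig), length(values_cg))),
              levels = c("CG", "IG"))
  if (var(y) < .Machine$double.eps) {
    return(tibble::tibble(
      mean_ig = mean(values_ig), mean_cg = mean(values_cg),
      difference = mean(values_ig) - mean(values_cg), se = 0,
      f_statistic = 0, p_value = 1, n = length(y)
    ))
  }
  # perfect separation: groups differ but have (near-)zero within variance
  if (var(values_ig) + var(values_cg) < .Machine$double.eps) {
    return(tibble::tibble(
      mean_ig = mean(values_ig), mean_cg = mean(values_cg),
      difference = mean(values_ig) - mean(values_cg), se = 0,
      f_statistic = Inf, p_value = 0, n = length(y)
    ))
  }
  fit <- lm(y ~ g)
  an <- stats::anova(fit)
  sm <- summary(fit)$coefficients
  tibble::tibble(
    mean_ig = mean(values_ig), mean_cg = mean(values_cg),
    difference = unname(sm["gIG", "Estimate"]),
    se = unname(sm["gIG", "Std. Error"]),
    f_statistic = an$`F value`[1],
    p_value = an$`Pr(>F)`[1],
    n = length(y)
  )
}

#' @rdname fit_sur
#' @param x A `sur_fit`.
#' @param robust Report robust (sandwich) standard errors (default) or
#'   model-based ones.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.sur_fit <- function(x, robust = TRUE, ...) {
  V <- if (robust) x$vcov_robust else x$vcov_model
  se_all <- sqrt(diag(V))
  k1 <- length(x$coefficients$cost)
  purrr::map_dfr(c("cost", "effect"), function(eq) {
    beta <- x$coefficients[[eq]]
    idx <- if (eq == "cost") seq_len(k1) else k1 + seq_along(beta)
    tibble::tibble(
      equation = eq, term = names(beta), estimate = unname(beta),
      std.error = se_all[idx],
      statistic = unname(beta) / se_all[idx],
      p.value = 2 * pnorm(-abs(unname(beta) / se_all[idx]))
    )
  })
}

#' @rdname fit_sur
#' @exportS3Method generics::glance
glance.sur_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n_used,
    sigma_cost = sqrt(x$sigma[1, 1]),
    sigma_effect = sqrt(x$sigma[2, 2]),
    resid_correlation = stats::cov2cor(x$sigma)[1, 2],
    effect_name = x$spec$effect_name,
    iterated = x$iterate
  )
}
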