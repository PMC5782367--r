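# Longitudinal cohort statistics: early/late period comparison with the
# study's observation-selection rules and a Mann-Whitney U test, a
# random-intercept mixed model over ICU day for every outcome, a +/-3 SD
# residual sensitivity refit, and the zero-crossing-day estimate.

#' Assign study occasions to comparison periods
#'
#' Early period: ICU days 10-20; late period: days 30-40 (closed
#' intervals); anything else is `"neither"`.
#'
#' @param icu_day Integer vector of ICU days.
#' @return Character vector `"early"`, `"late"` or `"neither"`.
#' @export
assign_periods <- function(icu_day) {
  out <- rep("neither", length(icu_day))
  out[icu_day >= 10 & icu_day <= 20] <- "early"
  out[icu_day >= 30 & icu_day <= 40] <- "late"
  out
}

#' Select one observation per patient for the period comparison
#'
#' Repeated measurements would make the two comparison groups
#' non-independent, so: a patient studied in **both** periods contributes
#' only the last (latest-day) measurement; a patient studied **twice
#' within one** period contributes the first. Observations outside both
#' periods never enter the comparison.
#'
#' @param occasions Data frame with at least `patient_id` and `icu_day`
#'   (one row per occasion; extra columns are carried through).
#' @return List: `selected` (the retained rows, with a `period` column)
#'   and `group_sizes` (named vector, early/late counts).
#' @export
select_observations <- function(occasions) {
  d <- occasions
  d$period <- assign_periods(d$icu_day)
  d <- d[d$period != "neither", , drop = FALSE]
  keep <- logical(nrow(d))
  for (pid in unique(d$patient_id)) {
    idx <- which(d$patient_id == pid)
    periods <- unique(d$period[idx])
    if (length(periods) == 2) {
      keep[idx[which.max(d$icu_day[idx])]] <- TRUE
    } else {
      for (p in periods) {
        pidx <- idx[d$period[idx] == p]
        keep[pidx[which.min(d$icu_day[pidx])]] <- TRUE
      }
    }
  }
  sel <- d[keep, , drop = FALSE]
  list(selected = sel,
       group_sizes = c(early = sum(sel$period == "early"),
                       late = sum(sel$period == "late")))
}

#' Mann-Whitney U test
#'
#' Exact tie-aware permutation enumeration when the combined sample size
#' is at most `exact_max_n`; otherwise the tie-corrected normal
#' approximation with continuity correction. The U statistic counts, over
#' all cross-pairs, how often an `x` value exceeds a `y` value (ties
#' count one half).
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param exact `TRUE`/`FALSE` to force a method, or `NULL` (default) to
#'   enumerate exactly when `length(x) + length(y) <= exact_max_n`.
#' @param exact_max_n Size limit for exhaustive enumeration (default 12).
#' @return Object of class `mann_whitney`: `U`, `p_value`, `method`,
#'   `degenerate` (all pooled values tied, in which case `p = 1`).
#' @export
mann_whitney <- function(x, y, exact = NULL, exact_max_n = 12) {
  if (length(x) == 0 || length(y) == 0) {
    lt_stop("both groups must be non-empty", "lt_domain_error")
  }
  m <- length(x); n <- length(y); N <- m + n
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (length(unique(pooled)) == 1) {
    return(structure(list(U = U, p_value = 1, method = "degenerate",
                          degenerate = TRUE), class = "mann_whitney"))
  }
  if (is.null(exact)) exact <- N <= exact_max_n
  mu <- m * n / 2
  if (exact) {
    dev <- abs(U - mu)
    subsets <- combn(N, m)
    Us <- colSums(matrix(r[subsets], nrow = m)) - m * (m + 1) / 2
    p <- mean(abs(Us - mu) >= dev - 1e-12)
    method <- "exact"
  } else {
    tie <- table(r)
    sigma2 <- (m * n / 12) * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    z <- U - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  structure(list(U = U, p_value = p, method = method, degenerate = FALSE),
            class = "mann_whitney")
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("<mann_whitney> U = %g, p = %.4g (%s)\n", x$U, x$p_value, x$method))
  invisible(x)
}

#' Early-vs-late period comparison for one outcome
#'
#' Applies [select_observations()] and compares the early (days 10-20)
#' and late (days 30-40) groups with [mann_whitney()]. Summaries are
#' medians and quartiles, matching the study's descriptive convention.
#'
#' @param occasions Data frame with `patient_id`, `icu_day` and the
#'   outcome column.
#' @param value_col Name of the outcome column.
#' @param ... Passed to [mann_whitney()].
#' @return Object of class `period_comparison`: per-period `median` and
#'   `quartiles`, `group_sizes`, `U`, `p_value`, `selected`.
#' @export
period_comparison <- function(occasions, value_col, ...) {
  sel <- select_observations(occasions)
  s <- sel$selected
  a <- s[[value_col]][s$period == "early"]
  b <- s[[value_col]][s$period == "late"]
  if (length(a) == 0 || length(b) == 0) {
    lt_stop("a comparison period has no observations after selection",
            "lt_domain_error")
  }
  mw <- mann_whitney(a, b, ...)
  summarize <- function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    list(n = length(v), q1 = q[1], median = q[2], q3 = q[3])
  }
  structure(list(early = summarize(a), late = summarize(b),
                 group_sizes = sel$group_sizes,
                 U = mw$U, p_value = mw$p_value, method = mw$method,
                 selected = s),
            class = "period_comparison")
}

#' Random-intercept mixed model of an outcome over ICU day
#'
#' Fits `y_ij = beta0 + beta1 * day_ij + b_i + e_ij`, with a per-patient
#' random intercept `b_i ~ N(0, sigma_b^2)` and residual
#' `e_ij ~ N(0, sigma_e^2)`, by REML via [nlme::lme()]. The slope test
#' defaults to nlme's within-group t (`df_method = "within"`), which is
#' well calibrated at repeated-measures cohorts of a few dozen
#' observations; `df_method = "normal"` gives the large-sample Wald z
#' test. If the
#' mixed fit fails (e.g. an exactly deterministic outcome leaves no
#' residual variance to estimate), the model degrades to ordinary least
#' squares with `sigma_b = 0` and is flagged.
#'
#' @param y Outcome vector (one value per occasion).
#' @param icu_day Continuous time covariate (days since ICU admission).
#' @param patient_id Grouping factor.
#' @param df_method `"within"` (default) or `"normal"`.
#' @return Object of class `cohort_trend`: `beta0`, `beta1`, `se_beta1`,
#'   `p_slope`, `sigma_b`, `sigma_e`, `n_obs`, `n_patients`,
#'   `vcov_fixed`, `residuals` (conditional, i.e. including the
#'   predicted random intercept), `boundary` (`sigma_b` at zero),
#'   `method` (`"lme"` or `"ols"`), and the model frame.
#' @export
fit_random_intercept <- function(y, icu_day, patient_id,
                                 df_method = c("within", "normal")) {
  df_method <- match.arg(df_method)
  ok <- complete.cases(y, icu_day, patient_id)
  d <- data.frame(y = y[ok], day = as.numeric(icu_day[ok]),
                  patient = factor(patient_id[ok]))
  if (nlevels(d$patient) < 2) {
    lt_stop("at least 2 patients are required", "lt_domain_error")
  }
  fit <- tryCatch(
    nlme::lme(y ~ day, random = ~ 1 | patient, data = d, method = "REML",
              control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                         msMaxIter = 200, returnObject = TRUE)),
    error = function(e) NULL)

  if (!is.null(fit)) {
    fe <- nlme::fixef(fit)
    V <- as.matrix(vcov(fit))
    sigma_e <- fit$sigma
    sigma_b <- suppressWarnings(
      as.numeric(nlme::VarCorr(fit)["(Intercept)", "StdDev"]))
    res <- as.numeric(residuals(fit, level = 1))
    p_within <- summary(fit)$tTable["day", "p-value"]
    method <- "lme"
  } else {
    lmfit <- lm(y ~ day, data = d)
    fe <- coef(lmfit)
    V <- vcov(lmfit)
    sigma_e <- summary(lmfit)$sigma
    sigma_b <- 0
    res <- as.numeric(residuals(lmfit))
    tt <- summary(lmfit)$coefficients
    p_within <- if (nrow(tt) >= 2) tt["day", "Pr(>|t|)"] else NA_real_
    method <- "ols"
  }
  se1 <- sqrt(V[2, 2])
  z <- fe[[2]] / se1
  p_slope <- switch(df_method,
                    normal = 2 * pnorm(-abs(z)),
                    within = p_within)
  structure(list(beta0 = unname(fe[[1]]), beta1 = unname(fe[[2]]),
                 se_beta1 = se1, p_slope = unname(p_slope),
                 sigma_b = sigma_b, sigma_e = sigma_e,
                 n_obs = nrow(d), n_patients = nlevels(d$patient),
                 vcov_fixed = V, residuals = res,
                 boundary = sigma_b < 1e-6 * max(sigma_e, 1e-12),
                 method = method, df_method = df_method, data = d),
            class = "cohort_trend")
}

#' @export
print.cohort_trend <- function(x, ...) {
  cat(sprintf("<cohort_trend> slope %.4g / day (SE %.3g, p = %.3g), intercept %.4g; sigma_b %.3g, sigma_e %.3g; %d obs / %d patients%s\n",
              x$beta1, x$se_beta1, x$p_slope, x$beta0, x$sigma_b, x$sigma_e,
              x$n_obs, x$n_patients,
              if (x$method == "ols") " [OLS fallback]" else ""))
  invisible(x)
}

#' Outlier sensitivity refit (+/- 3 SD residual rule)
#'
#' Computes the SD of the fitted model's conditional residuals, removes
#' every patient with any measurement whose residual exceeds 3 SD in
#' magnitude, refits, and reports whether the slope's significance at
#' the 5% level changed.
#'
#' @param fit A [fit_random_intercept()] result.
#' @param sd_multiple Residual cut in SD units (default 3).
#' @return Object of class `sensitivity_result`: `removed_patient_ids`,
#'   `refit` (a `cohort_trend`; the original fit if nothing was removed),
#'   `conclusion_changed`.
#' @export
sensitivity_refit <- function(fit, sd_multiple = 3) {
  stopifnot(inherits(fit, "cohort_trend"))
  sd_r <- sd(fit$residuals)
  bad <- abs(fit$residuals) > sd_multiple * sd_r
  removed <- unique(as.character(fit$data$patient[bad]))
  if (length(removed) == 0) {
    return(structure(list(removed_patient_ids = character(0), refit = fit,
                          conclusion_changed = FALSE),
                     class = "sensitivity_result"))
  }
  keep <- !(as.character(fit$data$patient) %in% removed)
  if (nlevels(droplevels(fit$data$patient[keep])) < 2) {
    lt_stop("outlier removal leaves fewer than 2 patients",
            "lt_domain_error")
  }
  refit <- fit_random_intercept(fit$data$y[keep], fit$data$day[keep],
                                fit$data$patient[keep],
                                df_method = fit$df_method)
  structure(list(removed_patient_ids = removed, refit = refit,
                 conclusion_changed =
                   (fit$p_slope < 0.05) != (refit$p_slope < 0.05)),
            class = "sensitivity_result")
}

#' ICU day at which the fitted mean outcome crosses zero
#'
#' For a fitted trend `beta0 + beta1 * day`, the crossing day is
#' `-beta0 / beta1`; its standard error follows from the first-order
#' delta method on the fixed-effect covariance.
#'
#' @param fit A [fit_random_intercept()] result.
#' @param tol Slope magnitude below which the crossing is reported
#'   undefined (default 1e-10).
#' @return List: `day`, `se`, `undefined`.
#' @export
zero_crossing_day <- function(fit, tol = 1e-10) {
  stopifnot(inherits(fit, "cohort_trend"))
  b0 <- fit$beta0; b1 <- fit$beta1
  if (!is.finite(b1) || abs(b1) < tol) {
    return(list(day = NA_real_, se = NA_real_, undefined = TRUE))
  }
  g <- c(-1 / b1, b0 / b1^2)
  se <- sqrt(drop(t(g) %*% fit$vcov_fixed %*% g))
  list(day = -b0 / b1, se = se, undefined = FALSE)
}
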