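#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with Greenwood variance and 95% confidence
#' intervals on the log(-log S) scale (which keeps the bounds inside
#' [0, 1]).
#'
#' @param data A data frame of one row per subject.
#' @param time,event Columns (tidy-eval) holding follow-up time in years
#'   and the death indicator (logical or 0/1).
#' @param conf_level Confidence level.
#' @return A `km_curve` object; [tidy()] gives the step curve,
#'   [glance()] the subject/event counts and the 5-year mortality, and
#'   [mortality_at()] the mortality at any horizon.
#' @export
#' @examples
#' d <- tibble::tibble(t = c(1, 2, 3), d = c(TRUE, TRUE, FALSE))
#' km <- km_estimate(d, t, d)
#' tidy(km)
km_estimate <- function(data, time, event, conf_level = 0.95) {
  t <- dplyr::pull(data, {{ time }})
  e <- as.integer(dplyr::pull(data, {{ event }}))
  if (!length(t)) abort("no subjects")
  if (any(t <= 0)) abort("follow-up times must be positive")
  fit <- survival::survfit(survival::Surv(t, e) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  structure(list(fit = fit, n = length(t), events = sum(e),
                 conf_level = conf_level),
            class = "km_curve")
}

#' @method tidy km_curve
#' @export
tidy.km_curve <- function(x, ...) {
  f <- x$fit
  tibble::tibble(
    time = f$time,
    n_risk = f$n.risk,
    n_event = f$n.event,
    n_censor = f$n.censor,
    survival = f$surv,
    ci_low = dplyr::coalesce(f$lower, f$surv),
    ci_high = dplyr::coalesce(f$upper, f$surv)
  )
}

#' @method glance km_curve
#' @export
glance.km_curve <- function(x, ...) {
  m <- mortality_at(x, 5)
  tibble::tibble(n = x$n, events = x$events,
                 mortality_5y_pct = m$mortality_pct,
                 ci_low_pct = m$ci_low_pct, ci_high_pct = m$ci_high_pct)
}

#' Mortality at a horizon from a Kaplan-Meier curve
#'
#' @param km A `km_curve`.
#' @param horizon_years Horizon in years (default 5).
#' @return One-row tibble: `mortality_pct`, `ci_low_pct`, `ci_high_pct`
#'   (the CI bounds of `1 - S`, so low/high are swapped relative to the
#'   survival CI).
#' @export
mortality_at <- function(km, horizon_years = 5) {
  s <- summary(km$fit, times = horizon_years, extend = TRUE)
  tibble::tibble(
    mortality_pct = 100 * (1 - s$surv),
    ci_low_pct = 100 * (1 - dplyr::coalesce(s$upper, s$surv)),
    ci_high_pct = 100 * (1 - dplyr::coalesce(s$lower, s$surv))
  )
}

#' Log-rank test
#'
#' @param data A data frame of one row per subject.
#' @param time,event,group Columns (tidy-eval): follow-up years, death
#'   indicator, group label (at least two non-empty groups).
#' @return One-row tibble: `chi2`, `df`, `p_value`, `n_groups`.
#' @export
logrank_test <- function(data, time, event, group) {
  t <- dplyr::pull(data, {{ time }})
  e <- as.integer(dplyr::pull(data, {{ event }}))
  g <- dplyr::pull(data, {{ group }})
  if (anyNA(g)) abort("group labels contain NA")
  if (length(unique(g)) < 2) abort("log-rank needs at least two groups")
  if (sum(e) == 0) {
    warn("no events: log-rank statistic undefined")
    return(tibble::tibble(chi2 = NA_real_, df = length(unique(g)) - 1,
                          p_value = NA_real_,
                          n_groups = length(unique(g))))
  }
  fit <- survival::survdiff(survival::Surv(t, e) ~ g)
  df <- length(fit$n) - 1
  tibble::tibble(chi2 = fit$chisq, df = df,
                 p_value = pchisq(fit$chisq, df, lower.tail = FALSE),
                 n_groups = length(fit$n))
}

#' Cox proportional-hazards fit
#'
#' Maximum partial likelihood with the Efron tie approximation; Wald
#' confidence intervals and p-values.  Refuses constant covariates, too few
#' events, and silently unconverged fits.
#'
#' @param data A data frame of one row per subject with the covariate
#'   columns.
#' @param time,event Columns (tidy-eval): follow-up years and the death
#'   indicator.
#' @param covariates Character vector of covariate column names.
#' @param conf_level Confidence level for the hazard-ratio intervals.
#' @return A `cox_fit` object; [tidy()] gives one row per covariate with
#'   hazard ratio, CI and p-value, [glance()] the fit summary.
#' @export
cox_fit <- function(data, time, event, covariates, conf_level = 0.95) {
  stopifnot(is.character(covariates), length(covariates) >= 1)
  missing_cols <- setdiff(covariates, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing covariate column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  t <- dplyr::pull(data, {{ time }})
  e <- as.integer(dplyr::pull(data, {{ event }}))
  x <- data[covariates]
  keep <- complete.cases(x) & !is.na(t) & !is.na(e)
  x <- x[keep, , drop = FALSE]
  t <- t[keep]
  e <- e[keep]
  const <- vapply(x, function(v) length(unique(v)) < 2, logical(1))
  if (any(const)) {
    abort(paste0("constant covariate(s): ",
                 paste(covariates[const], collapse = ", ")))
  }
  if (sum(e) < length(covariates) + 1) {
    abort("too few events for the number of covariates")
  }
  d <- cbind(data.frame(.time = t, .event = e), x)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = d, ties = "efron",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50))
  if (anyNA(coef(fit))) {
    abort("Cox fit did not converge (singular or separated covariates)")
  }
  structure(list(fit = fit, covariates = covariates,
                 conf_level = conf_level, n = nrow(d), events = sum(e)),
            class = "cox_fit")
}

#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) {
  s <- summary(x$fit, conf.int = x$conf_level)
  z <- qnorm(1 - (1 - x$conf_level) / 2)
  b <- coef(x$fit)
  se <- sqrt(diag(x$fit$var))
  tibble::tibble(
    term = x$covariates,
    estimate = unname(b),
    std_error = unname(se),
    hazard_ratio = unname(exp(b)),
    ci_low = unname(exp(b - z * se)),
    ci_high = unname(exp(b + z * se)),
    p_value = unname(s$coefficients[, "Pr(>|z|)"])
  )
}

#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  f <- x$fit
  tibble::tibble(n = x$n, events = x$events,
                 loglik = f$loglik[2], loglik_null = f$loglik[1],
                 concordance = unname(f$concordance["concordance"]),
                 iter = f$iter)
}

#' CVHR-threshold mortality scan
#'
#' For each threshold `tau`, the Kaplan-Meier 5-year mortality (with CI)
#' of the subgroup of patients whose CVHR duration is at most `tau`.
#' Intended for non-flat patients only; subgroups smaller than `min_n` are
#' suppressed.
#'
#' @param data A data frame of one row per patient.
#' @param cvhr,time,event Columns (tidy-eval): minutes with CVHR,
#'   follow-up years, death indicator.
#' @param thresholds Threshold grid in minutes; default every observed
#'   CVHR value.
#' @param min_n Minimum subgroup size for a reported point.
#' @param horizon_years Mortality horizon.
#' @return A `cvhr_scan` tibble: `threshold_min`, `n`, `events`,
#'   `mortality_pct`, `ci_low_pct`, `ci_high_pct`.
#' @export
threshold_mortality_scan <- function(data, cvhr, time, event,
                                     thresholds = NULL, min_n = 20,
                                     horizon_years = 5) {
  v <- dplyr::pull(data, {{ cvhr }})
  t <- dplyr::pull(data, {{ time }})
  e <- as.integer(dplyr::pull(data, {{ event }}))
  ok <- !is.na(v)
  v <- v[ok]
  t <- t[ok]
  e <- e[ok]
  if (is.null(thresholds)) thresholds <- sort(unique(v))
  rows <- purrr::map(thresholds, function(tau) {
    sel <- v <= tau
    n <- sum(sel)
    if (n < min_n) return(NULL)
    km <- km_estimate(tibble::tibble(t = t[sel], e = e[sel]), t, e)
    m <- mortality_at(km, horizon_years)
    tibble::tibble(threshold_min = tau, n = n, events = sum(e[sel]),
                   mortality_pct = m$mortality_pct,
                   ci_low_pct = m$ci_low_pct, ci_high_pct = m$ci_high_pct)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cvhr_scan", class(out))
  out
}

#' Pearson correlation coefficient
#'
#' @param x,y Numeric vectors; pairs with missing values are dropped.
#'   Requires at least 3 complete pairs and nonzero variance in both.
#' @return The product-moment correlation (scalar), `NA` with a warning
#'   when undefined.
#' @export
pearson_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("zero variance: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}
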