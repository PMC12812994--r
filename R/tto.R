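# Time-to-onset: latency extraction, Weibull maximum likelihood with the
# shape-parameter hazard classification, Kaplan-Meier cumulative incidence
# and the log-rank comparison.

#' Extract time-to-onset records
#'
#' Latency is the number of days from the earliest full-precision therapy
#' start of the tagged drug to the event date. Records with a missing or
#' non-positive latency are dropped and counted (partial-precision dates
#' were already read as missing, so they drop out here without excluding
#' the report from disproportionality counting).
#'
#' @param records An [event_records()] tibble (usually already restricted to
#'   the SOC of interest via [restrict_to_soc()]).
#' @param drugs Drug labels to keep (default: tagged target drugs).
#' @return A tibble `drug, case_id, pt, onset_days` with `onset_days >= 1`;
#'   the number of dropped records is reported via a message.
#' @export
extract_tto <- function(records, drugs = NULL) {
  if (is.null(drugs)) drugs <- sort(unique(records$drug[records$is_target]))
  sub <- filter(records, .data$drug %in% drugs)
  sub <- mutate(sub, onset_days =
                  as.integer(.data$event_date - .data$therapy_start))
  bad <- is.na(sub$onset_days) | sub$onset_days < 1
  if (any(bad)) {
    inform(sprintf("extract_tto: dropped %d record(s) with missing or non-positive latency",
                   sum(bad)))
  }
  sub |>
    filter(!bad) |>
    select("drug", "case_id", "pt", "onset_days")
}

#' Median and interquartile range
#'
#' Type-7 (linear interpolation) quantiles, R's default and the convention
#' used for the onset-time summaries.
#'
#' @param x Numeric vector, `length(x) >= 1`.
#' @return A tibble `median, q1, q3`.
#' @export
median_iqr <- function(x) {
  stopifnot(length(x) >= 1)
  q <- quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  tibble(median = q[1], q1 = q[2], q3 = q[3])
}

weibull_negloglik <- function(par, x) {
  shape <- exp(par[1]); scale <- exp(par[2])
  -sum(stats::dweibull(x, shape = shape, scale = scale, log = TRUE))
}

#' Weibull maximum-likelihood fit with hazard-type classification
#'
#' Fits scale alpha and shape beta by maximising the Weibull log-likelihood
#' (Nelder-Mead on the log-parameters from a method-of-moments start), with
#' 95% confidence intervals from the observed-information normal
#' approximation on `(log alpha, log beta)`, and classifies the hazard via
#' [classify_failure_type()]: a shape below 1 (interval excluding 1) means
#' the event rate falls with time on therapy — the early-failure profile
#' typical of onset latencies under these drugs.
#'
#' @param x Positive numeric vector of onset days; `length(x) >= n_min`.
#' @param n_min Minimum sample size (default 10).
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @return An object of class `weibull_fit`: `scale_alpha`, `shape_beta`,
#'   `alpha_ci`, `beta_ci`, `failure_type`, `n`, `median_iqr`, `loglik`.
#'   `tidy()`, `glance()` and `autoplot()` methods are provided.
#' @export
weibull_mle <- function(x, n_min = 10, conf_level = 0.95) {
  x <- as.numeric(x)
  if (length(x) < n_min) {
    abort(sprintf("weibull_mle needs at least %d observations", n_min))
  }
  if (any(x <= 0)) abort("onset times must be strictly positive")
  if (length(unique(x)) == 1) abort("all onset times identical; shape is unidentifiable")
  # method-of-moments start: CV determines the shape
  cv <- stats::sd(x) / mean(x)
  shape0 <- max(min(cv^(-1.086), 50), 0.05)
  scale0 <- mean(x) / gamma(1 + 1 / shape0)
  start <- c(log(shape0), log(scale0))
  fit <- optim(start, weibull_negloglik, x = x, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  if (fit$convergence != 0) {
    abort(sprintf("weibull_mle failed to converge (optim code %d)",
                  fit$convergence))
  }
  if (weibull_negloglik(fit$par, x) > weibull_negloglik(start, x) + 1e-8) {
    abort("weibull_mle: optimum worse than the method-of-moments start")
  }
  H <- optimHess(fit$par, weibull_negloglik, x = x)
  V <- solve(H)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(pmax(diag(V), 0))
  shape <- exp(fit$par[1]); scale <- exp(fit$par[2])
  beta_ci <- exp(fit$par[1] + c(-1, 1) * z * se[1])
  alpha_ci <- exp(fit$par[2] + c(-1, 1) * z * se[2])
  out <- list(scale_alpha = scale, shape_beta = shape,
              alpha_ci = alpha_ci, beta_ci = beta_ci,
              n = length(x), median_iqr = median_iqr(x),
              loglik = -fit$value)
  out$failure_type <- classify_failure_type(shape, beta_ci)
  class(out) <- "weibull_fit"
  out
}

#' Classify the hazard profile from the Weibull shape parameter
#'
#' Early failure: shape below 1 with the whole interval below 1 (risk
#' decreases over time). Random failure: the interval contains 1 (roughly
#' constant hazard). Wear-out: shape above 1 with the whole interval above
#' 1 (risk increases). An interval endpoint exactly at 1 is classified
#' random — the boundary is treated as compatible with constant hazard.
#'
#' @param shape_beta Point estimate of the shape.
#' @param beta_ci Length-2 numeric, the interval for the shape.
#' @return `"early"`, `"random"` or `"wear-out"`.
#' @export
classify_failure_type <- function(shape_beta, beta_ci) {
  stopifnot(length(beta_ci) == 2, beta_ci[1] <= beta_ci[2])
  if (shape_beta < 1 && beta_ci[2] < 1) return("early")
  if (shape_beta > 1 && beta_ci[1] > 1) return("wear-out")
  "random"
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("<weibull_fit>\n")
  cat(sprintf("  n = %d, median (IQR) = %.0f (%.0f-%.0f) days\n", x$n,
              x$median_iqr$median, x$median_iqr$q1, x$median_iqr$q3))
  cat(sprintf("  scale alpha = %.1f (%.1f-%.1f)\n", x$scale_alpha,
              x$alpha_ci[1], x$alpha_ci[2]))
  cat(sprintf("  shape beta  = %.2f (%.2f-%.2f)  ->  %s failure\n",
              x$shape_beta, x$beta_ci[1], x$beta_ci[2], x$failure_type))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.weibull_fit <- function(x, ...) {
  tibble(term = c("scale_alpha", "shape_beta"),
         estimate = c(x$scale_alpha, x$shape_beta),
         conf.low = c(x$alpha_ci[1], x$beta_ci[1]),
         conf.high = c(x$alpha_ci[2], x$beta_ci[2]))
}

#' @exportS3Method generics::glance
glance.weibull_fit <- function(x, ...) {
  tibble(n = x$n, logLik = x$loglik, failure_type = x$failure_type,
         median = x$median_iqr$median, q1 = x$median_iqr$q1,
         q3 = x$median_iqr$q3)
}

#' Per-drug Weibull time-to-onset table
#'
#' Pools all onset records per drug (all PTs of the analysed SOC together)
#' and fits [weibull_mle()] per drug — the shape of a WSP summary table.
#'
#' @param ttos An [extract_tto()] tibble.
#' @param n_min Minimum records per drug.
#' @return A tibble with one row per drug: `n`, `median`, `q1`, `q3`,
#'   `min`, `max`, `scale_alpha` and its interval, `shape_beta` and its
#'   interval, `failure_type`.
#' @export
tto_summary <- function(ttos, n_min = 10) {
  ttos |>
    group_by(.data$drug) |>
    group_modify(function(df, key) {
      f <- weibull_mle(df$onset_days, n_min = n_min)
      tibble(n = f$n, median = f$median_iqr$median, q1 = f$median_iqr$q1,
             q3 = f$median_iqr$q3,
             min = min(df$onset_days), max = max(df$onset_days),
             scale_alpha = f$scale_alpha, alpha_low = f$alpha_ci[1],
             alpha_high = f$alpha_ci[2], shape_beta = f$shape_beta,
             beta_low = f$beta_ci[1], beta_high = f$beta_ci[2],
             failure_type = f$failure_type)
    }) |>
    ungroup()
}

#' Kaplan-Meier cumulative incidence of onset
#'
#' All spontaneous-report latencies are realised events (no censoring), so
#' the cumulative incidence `1 - S(t)` reduces to the empirical CDF; the
#' curve is still computed through the product-limit estimator for fidelity
#' to survival practice.
#'
#' @param ttos An [extract_tto()] tibble (or any tibble with `drug` and
#'   `onset_days`).
#' @return A tibble `drug, time, n_risk, n_event, surv, cum_incidence`,
#'   monotone non-decreasing in `cum_incidence` and ending at 1 per drug.
#' @export
km_curve <- function(ttos) {
  stopifnot(nrow(ttos) >= 1)
  ttos |>
    group_by(.data$drug) |>
    group_modify(function(df, key) {
      sf <- survival::survfit(survival::Surv(df$onset_days,
                                             rep(1, nrow(df))) ~ 1)
      tibble(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             surv = sf$surv, cum_incidence = 1 - sf$surv)
    }) |>
    ungroup()
}

#' Log-rank comparison of onset distributions across drugs
#'
#' k-sample log-rank test; the statistic is chi-squared with k-1 degrees of
#' freedom under the null of identical onset distributions.
#'
#' @param ttos A tibble with `drug` and `onset_days`, at least two non-empty
#'   groups.
#' @return A tibble `statistic, df, p_value`.
#' @export
log_rank <- function(ttos) {
  groups <- unique(ttos$drug)
  if (length(groups) < 2) abort("log_rank needs at least two non-empty groups")
  sd <- survival::survdiff(survival::Surv(onset_days,
                                          rep(1, nrow(ttos))) ~ drug,
                           data = ttos)
  df <- length(sd$n) - 1
  tibble(statistic = sd$chisq, df = df,
         p_value = pchisq(sd$chisq, df = df, lower.tail = FALSE))
}
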