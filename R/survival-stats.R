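# Survival estimators: the D-index (Cox regression on scaled normal order
# statistics of a risk score), Kaplan-Meier curves, two-group log-rank tests
# and median-split stratification.

# Blom rankits of a score vector, scaled by 1/kappa. Depends on the scores
# only through their ranks (average ranks over ties).
dindex_covariate <- function(scores) {
  n <- length(scores)
  r <- rank(scores, ties.method = "average")
  qnorm((r - 3 / 8) / (n + 1 / 4)) / DINDEX_KAPPA
}

# Fast path for scans: endpoints already prepared, x aligned to prep input
# order (not yet sorted). Returns c(log_hr, se) or c(NA, NA) on degeneracy.
dindex_core <- function(scores, prep) {
  z <- dindex_covariate(scores)
  fit <- cox_newton(z[prep$ord], prep)
  if (!fit$ok) return(c(NA_real_, NA_real_))
  c(fit$coef, fit$se)
}

#' Royston-Sauerbrei D-index of a risk score
#'
#' The D-index estimates the log hazard ratio between two equal-sized
#' prognostic groups defined by a continuous risk score: scores are ranked
#' (average ranks over ties), converted to normal order statistics via Blom's
#' approximation `qnorm((rank - 3/8) / (n + 1/4))`, scaled by
#' `1/kappa` with `kappa = sqrt(8/pi)`, and a univariate Cox model is fitted
#' to the result. The coefficient is the D statistic; `exp(D)` is the hazard
#' ratio of the upper versus lower prognostic half. The statistic depends on
#' the scores only through their ranks.
#'
#' @param scores numeric risk scores (higher = predicted worse outcome).
#' @param time,event survival endpoints as in [fit_cox()].
#' @return object of class `"dindex"`: `log_hr`, `se`, `hr`, `ci95`,
#'   `p_value`, `n`, `n_events`, `kappa`.
#' @export
d_index <- function(scores, time, event) {
  stopifnot(length(scores) == length(time), length(time) == length(event))
  keep <- !(is.na(scores) | is.na(time) | is.na(event))
  scores <- scores[keep]; time <- time[keep]; event <- event[keep]
  if (length(scores) == 0) stop(degenerate_error("no complete observations"))
  fit <- fit_cox(dindex_covariate(scores), time, event)
  structure(
    list(log_hr = fit$coef, se = fit$se, hr = exp(fit$coef),
         ci95 = exp(fit$coef + c(-1, 1) * qnorm(0.975) * fit$se),
         p_value = fit$p, n = fit$n, n_events = fit$n_events,
         kappa = DINDEX_KAPPA),
    class = "dindex"
  )
}

#' @export
print.dindex <- function(x, ...) {
  cat(sprintf("D-index: %.4f (HR %.3f, 95%% CI %.3f-%.3f), p = %.3g, n = %d (%d events)\n",
              x$log_hr, x$hr, x$ci95[1], x$ci95[2], x$p_value, x$n, x$n_events))
  invisible(x)
}

#' @export
coef.dindex <- function(object, ...) c(log_hr = object$log_hr)

#' @export
confint.dindex <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  matrix(object$log_hr + c(-1, 1) * z * object$se, 1,
         dimnames = list("log_hr", c("lo", "hi")))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator wrapped around [survival::survfit()]. The returned
#' object evaluates as a right-continuous step function with `S(0) = 1`.
#'
#' @param time,event survival endpoints.
#' @return object of class `"km_curve"` with components `time`, `surv`,
#'   `n_risk`, `n_event`.
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) >= 1, all(time > 0))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
                 n_event = sf$n.event),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km a `"km_curve"`.
#' @param t times at which to evaluate the survival probability.
#' @return numeric vector of survival probabilities.
#' @export
km_survival <- function(km, t) {
  idx <- findInterval(t, km$time)
  c(1, km$surv)[idx + 1]
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d time points, %d events, final S = %.3f\n",
              length(x$time), sum(x$n_event), x$surv[length(x$surv)]))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, xlab = "time (days)", ylab = "survival probability",
                          ...) {
  plot(stepfun(x$time, c(1, x$surv)), do.points = FALSE, ylim = c(0, 1),
       xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Export a Kaplan-Meier curve as a two-column TSV (time, survival)
#'
#' @param km a `"km_curve"`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_km_curve <- function(km, path) {
  write.table(data.frame(time = km$time, survival = km$surv), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-squared statistic on one degree of freedom, via
#' [survival::survdiff()].
#'
#' @param groups binary group labels (two distinct values required).
#' @param time,event survival endpoints.
#' @return list with `chi2` and `p`.
#' @export
logrank_test <- function(groups, time, event) {
  keep <- !(is.na(groups) | is.na(time) | is.na(event))
  groups <- groups[keep]; time <- time[keep]; event <- event[keep]
  if (length(unique(groups)) != 2)
    stop("log-rank test requires exactly two non-empty groups")
  if (sum(event) < 1) stop(degenerate_error("no events"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
  list(chi2 = unname(sd$chisq),
       p = pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}

#' Median-split stratification
#'
#' Labels each sample `1` ("high") iff its score strictly exceeds the median
#' of the supplied scores. Intended to be applied within each dataset before
#' pooling, so that cross-platform location shifts never leak into the split.
#'
#' @param scores numeric risk scores.
#' @return integer vector of 0/1 labels (1 = high).
#' @export
median_split <- function(scores) {
  stopifnot(length(scores) >= 1)
  labels <- as.integer(scores > median(scores, na.rm = TRUE))
  if (all(labels == 0L))
    warning("all scores at or below the median; no split")
  labels
}
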