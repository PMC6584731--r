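# Single-covariate Cox partial-likelihood fitting with Efron handling of tied
# event times. The risk-set bookkeeping (cox_prep) depends only on the
# endpoints, so a genome-wide scan prepares it once per dataset and reuses it
# for every gene; each Newton iteration is then a handful of cumulative sums.

# Precompute the risk-set structure for a set of endpoints.
# Subjects are sorted by decreasing time so that the risk set at an event time
# is a prefix; events are grouped by distinct event time and the Efron
# correction is unrolled into an expansion index (one entry per event, with
# the fractional down-weight l/d of its tie group).
cox_prep <- function(time, event) {
  stopifnot(length(time) == length(event), all(time > 0),
            all(event %in% c(0, 1)))
  ord <- order(time, decreasing = TRUE)
  t_s <- time[ord]
  e_s <- event[ord] == 1
  idx_e <- which(e_s)
  if (length(idx_e) == 0) {
    return(list(ord = ord, n = length(time), n_events = 0L))
  }
  ut <- unique(t_s[idx_e])                       # distinct event times, decreasing
  grp <- match(t_s[idx_e], ut)                   # tie group of each event
  d <- tabulate(grp, nbins = length(ut))         # tie multiplicities
  m <- findInterval(-ut, -t_s)                   # |risk set| at each event time
  # expansion: for group k, entries l = 0..d_k - 1
  k_exp <- rep.int(seq_along(ut), d)
  frac_exp <- unlist(lapply(d, function(dd) seq_len(dd) - 1), use.names = FALSE) /
    d[k_exp]
  # events are contiguous in idx_e per tie group: segment boundaries allow
  # group sums by differenced cumulative sums instead of rowsum()
  e_ends <- cumsum(d)
  e_starts <- c(1L, head(e_ends, -1) + 1L)
  list(ord = ord, n = length(time), n_events = length(idx_e),
       idx_e = idx_e, grp = grp, m = m, k_exp = k_exp, frac_exp = frac_exp,
       e_starts = e_starts, e_ends = e_ends)
}

# Newton-Raphson with step-halving on a prepared risk-set structure.
# `x` must already be ordered by `prep$ord`. Returns ok = FALSE for
# degenerate inputs (constant covariate, < 2 events, non-convergence,
# non-positive information).
cox_newton <- function(x, prep, tol = 1e-9, max_iter = 50L) {
  fail <- function(reason) list(ok = FALSE, reason = reason)
  if (prep$n_events < 2) return(fail("fewer than 2 events"))
  if (all(x == x[1])) return(fail("constant covariate"))
  x <- x - mean(x)                      # guards exp() overflow, coef unchanged
  idx_e <- prep$idx_e
  k_exp <- prep$k_exp
  frac <- prep$frac_exp
  m <- prep$m
  st0 <- prep$e_starts
  en0 <- prep$e_ends
  sum_xd <- sum(x[idx_e])
  x2 <- x * x
  xe <- x[idx_e]
  x2e <- x2[idx_e]
  seg <- function(v) { cs <- cumsum(v); cs[en0] - c(0, cs)[st0] }

  eval_at <- function(beta) {
    r <- exp(beta * x)
    c0 <- cumsum(r);        c1 <- cumsum(x * r);    c2 <- cumsum(x2 * r)
    s0R <- c0[m];           s1R <- c1[m];           s2R <- c2[m]
    re <- r[idx_e]
    s0D <- seg(re)
    s1D <- seg(xe * re)
    s2D <- seg(x2e * re)
    phi0 <- s0R[k_exp] - frac * s0D[k_exp]
    phi1 <- s1R[k_exp] - frac * s1D[k_exp]
    phi2 <- s2R[k_exp] - frac * s2D[k_exp]
    rat1 <- phi1 / phi0
    list(loglik = beta * sum_xd - sum(log(phi0)),
         U = sum_xd - sum(rat1),
         I = sum(phi2 / phi0 - rat1 * rat1))
  }

  beta <- 0
  st <- eval_at(beta)
  u0 <- st$U; i0 <- st$I
  if (!is.finite(i0) || i0 <= 0) return(fail("non-positive information"))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    step <- st$U / st$I
    if (!is.finite(step)) return(fail("numerical failure"))
    new_beta <- beta + step
    new_st <- eval_at(new_beta)
    halvings <- 0L
    while ((!is.finite(new_st$loglik) || new_st$loglik < st$loglik) &&
           halvings < 30L) {
      step <- step / 2
      new_beta <- beta + step
      new_st <- eval_at(new_beta)
      halvings <- halvings + 1L
    }
    if (!is.finite(new_st$loglik)) return(fail("numerical failure"))
    beta <- new_beta
    st <- new_st
    if (abs(step) < tol) { converged <- TRUE; break }
  }
  if (!converged || !is.finite(st$I) || st$I <= 0)
    return(fail("did not converge"))
  list(ok = TRUE, coef = beta, se = 1 / sqrt(st$I), loglik = st$loglik,
       iter = iter, score_u0 = u0, score_i0 = i0)
}

#' Fit a univariate Cox proportional hazards model
#'
#' Maximizes the Cox partial likelihood for a single covariate, with Efron
#' handling of tied event times, by Newton-Raphson with step-halving
#' (convergence when the coefficient moves by less than `tol`). The standard
#' error comes from the observed information and the p-value is a two-sided
#' Wald test.
#'
#' @param x numeric covariate.
#' @param time,event survival endpoints: follow-up time (> 0) and event
#'   indicator (1 = event, 0 = censored). Pairs with any missing value are
#'   dropped.
#' @param tol,max_iter Newton-Raphson controls.
#' @return object of class `"cox_fit"`: list with `coef`, `se`, `p`, `n`,
#'   `n_events`, `loglik`, `score_chi2` (score test at 0, equal to the
#'   log-rank statistic for a binary covariate without ties), `iter`.
#' @export
fit_cox <- function(x, time, event, tol = 1e-9, max_iter = 50L) {
  stopifnot(length(x) == length(time), length(time) == length(event))
  keep <- !(is.na(x) | is.na(time) | is.na(event))
  x <- x[keep]; time <- time[keep]; event <- event[keep]
  if (sum(event) < 2)
    stop(degenerate_error("fewer than 2 events"))
  if (length(unique(x)) < 2)
    stop(degenerate_error("constant covariate"))
  prep <- cox_prep(time, event)
  fit <- cox_newton(x[prep$ord], prep, tol = tol, max_iter = max_iter)
  if (!fit$ok) stop(degenerate_error(fit$reason))
  z <- fit$coef / fit$se
  structure(
    list(coef = fit$coef, se = fit$se, p = 2 * pnorm(-abs(z)),
         n = length(x), n_events = as.integer(sum(event)),
         loglik = fit$loglik, score_chi2 = fit$score_u0^2 / fit$score_i0,
         iter = fit$iter),
    class = "cox_fit"
  )
}

degenerate_error <- function(msg) {
  structure(
    class = c("metasig_degenerate", "error", "condition"),
    list(message = paste0("degenerate survival input: ", msg), call = sys.call(-1))
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit: coef = %.4f (se %.4f), HR = %.3f, p = %.3g, n = %d (%d events)\n",
              x$coef, x$se, exp(x$coef), x$p, x$n, x$n_events))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) c(coef = object$coef)

#' @export
confint.cox_fit <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  matrix(c(object$coef - z * object$se, object$coef + z * object$se), 1,
         dimnames = list("coef", c("lo", "hi")))
}
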