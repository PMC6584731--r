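# Independent oracles used to freeze expected values: deliberately plain,
# loop-based implementations that share no code with the package internals.

# Efron partial log-likelihood for a single covariate, summing over distinct
# event times directly from the definition.
oracle_efron_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    s0R <- sum(exp(beta * x[R]))
    s0D <- sum(exp(beta * x[D]))
    ll <- ll + sum(beta * x[D])
    for (l in seq_len(d) - 1) ll <- ll - log(s0R - (l / d) * s0D)
  }
  ll
}

oracle_cox_coef <- function(x, time, event, interval = c(-8, 8)) {
  rough <- optimize(function(b) oracle_efron_loglik(b, x, time, event),
                    interval = interval, maximum = TRUE, tol = 1e-10)$maximum
  # refine beyond golden-section precision: root of the numerical derivative
  h <- 1e-5
  dll <- function(b) (oracle_efron_loglik(b + h, x, time, event) -
                        oracle_efron_loglik(b - h, x, time, event)) / (2 * h)
  uniroot(dll, c(rough - 0.05, rough + 0.05), tol = 1e-12)$root
}

# Two-group log-rank chi-squared from observed-minus-expected counts and the
# hypergeometric variance at each distinct event time.
oracle_logrank_chi2 <- function(groups, time, event) {
  g <- as.integer(factor(groups)) - 1L
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# DerSimonian-Laird pooling written as the plain sequence of formulas.
oracle_dl <- function(est, se) {
  w <- 1 / se^2
  mu <- sum(w * est) / sum(w)
  q <- sum(w * (est - mu)^2)
  k <- length(est)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  list(pooled = sum(ws * est) / sum(ws), se = 1 / sqrt(sum(ws)),
       tau2 = tau2, q = q)
}

# Spearman rank correlation from first principles (average ranks, Pearson on
# the ranks by the explicit sum formulas).
oracle_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  num / sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Benjamini-Hochberg step-up by its closed form.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  out <- numeric(n)
  out[o] <- pmin(q_sorted, 1)
  out
}
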