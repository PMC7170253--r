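# Independent oracles, deliberately implemented without the survival
# package so they can cross-check the production code paths.

# Efron partial log-likelihood for a single continuous covariate.
oracle_efron_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (t in unique(sort(time[status == 1]))) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    eta <- x * beta
    sumD <- sum(exp(eta[D]))
    sumR <- sum(exp(eta[R]))
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1L) ll <- ll - log(sumR - (l / d) * sumD)
  }
  ll
}

# Brute-force maximizer of the Efron partial likelihood.
oracle_cox_coef <- function(time, status, x, interval = c(-20, 20)) {
  optimize(function(b) -oracle_efron_loglik(b, time, status, x),
           interval = interval, tol = 1e-12)$minimum
}

# Hand log-rank arithmetic: observed minus expected deaths in group 1
# with the hypergeometric variance, summed over distinct event times.
oracle_logrank <- function(time, status, group) {
  g <- as.integer(factor(group)) - 1L   # 0/1
  O <- 0; E <- 0; V <- 0
  for (t in unique(sort(time[status == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    d <- sum(time == t & status == 1)
    d1 <- sum(time == t & status == 1 & g == 1L)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Closed-form Welch t statistic and two-sided p.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(statistic = t, p = 2 * pt(-abs(t), df))
}

# Closed-form Yates-corrected chi-square on a 2x2 table.
oracle_yates <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((abs(tab - E) - 0.5)^2 / E)
}

# Kaplan-Meier product-limit estimate at each distinct event time
# (single group, for the no-censoring invariant).
oracle_km <- function(time, status) {
  s <- 1
  out <- numeric(0)
  for (t in unique(sort(time[status == 1]))) {
    n <- sum(time >= t)
    d <- sum(time == t & status == 1)
    s <- s * (1 - d / n)
    out[as.character(t)] <- s
  }
  out
}
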