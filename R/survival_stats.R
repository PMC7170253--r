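#' Kaplan-Meier curves and log-rank test for a group split
#'
#' Product-limit survival estimates per group plus the two-sided log-rank
#' chi-square comparing them.
#'
#' @param groups a `group_assignment` from [dichotomize()].
#' @param survival a [survival_table()]; matched to `groups` on
#'   `sample_id`.
#' @return List of class `km_logrank`: `curves` (data.frame with columns
#'   `group`, `time`, `n_risk`, `n_event`, `surv`), `chisq`, `df`, `p`,
#'   `n` per group.
#' @export
km_logrank <- function(groups, survival) {
  stopifnot(inherits(groups, "group_assignment"),
            inherits(survival, "survival_table"))
  d <- merge(as.data.frame(groups)[, c("sample_id", "group")],
             as.data.frame(survival), by = "sample_id")
  if (nrow(d) == 0L)
    pps_stop("pps_empty_cohort_error", "no samples shared by groups and survival")
  tab <- table(d$group)
  if (any(tab == 0L))
    pps_stop("pps_degenerate_group_error", "empty group: %s",
             paste(names(tab)[tab == 0L], collapse = ", "))
  if (sum(d$event) < 1L)
    pps_stop("pps_degenerate_group_error", "no events observed")
  sf <- survfit(Surv(time, event) ~ group, data = d)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- data.frame(group = sub("^group=", "", strata), time = sf$time,
                       n_risk = sf$n.risk, n_event = sf$n.event,
                       surv = sf$surv, stringsAsFactors = FALSE)
  sd_ <- survdiff(Surv(time, event) ~ group, data = d)
  p <- pchisq(sd_$chisq, df = length(sd_$n) - 1L, lower.tail = FALSE)
  structure(list(curves = curves, chisq = unname(sd_$chisq),
                 df = length(sd_$n) - 1L, p = p, n = as.vector(tab)),
            class = "km_logrank")
}

#' Cox fit of survival on a binary high/low group indicator
#'
#' The low group is the reference, so the hazard ratio reads as the
#' relative hazard of the high group.
#'
#' @inheritParams km_logrank
#' @return One-row data.frame of class `cox_group`: `hr`, `ci_low`,
#'   `ci_high`, `p`, `n`; attribute `monotone` flags monotone-likelihood
#'   fits whose CI is unreliable.
#' @export
cox_univariate_group <- function(groups, survival) {
  stopifnot(inherits(groups, "group_assignment"),
            inherits(survival, "survival_table"))
  d <- merge(as.data.frame(groups)[, c("sample_id", "group")],
             as.data.frame(survival), by = "sample_id")
  if (length(unique(d$group)) < 2L)
    pps_stop("pps_degenerate_group_error", "need both groups represented")
  ev <- tapply(d$event, d$group, sum)
  monotone <- any(ev == 0)
  if (monotone)
    pps_warn("pps_monotone_likelihood_warning",
             "a group has no events; CI is unreliable")
  fit <- suppressWarnings(coxph(Surv(time, event) ~ group, data = d,
                                ties = "efron"))
  b <- unname(coef(fit)[1L])
  se <- sqrt(unname(vcov(fit)[1L, 1L]))
  out <- data.frame(hr = exp(b), ci_low = exp(b - 1.959964 * se),
                    ci_high = exp(b + 1.959964 * se),
                    p = 2 * pnorm(-abs(b / se)), n = nrow(d))
  attr(out, "monotone") <- monotone
  class(out) <- c("cox_group", "data.frame")
  out
}

# Wald p-values per covariate from a coxph fit
wald_p <- function(fit) {
  b <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  setNames(2 * pnorm(-abs(b / se)), names(b))
}

cox_report_row <- function(fit) {
  b <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  data.frame(covariate = names(b), hr = exp(unname(b)),
             ci_low = exp(unname(b) - 1.959964 * se),
             ci_high = exp(unname(b) + 1.959964 * se),
             p = unname(2 * pnorm(-abs(b / se))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multivariate Cox with backward elimination on Wald p-values
#'
#' Fits survival on all supplied covariate columns, then repeatedly
#' removes the covariate with the largest Wald p >= `removal_alpha` and
#' refits, until every remaining covariate has p < `removal_alpha` (the
#' stepwise "backward Wald" procedure; the 0.10 default is the usual
#' removal probability). The full step history is reported.
#'
#' @param covariates data.frame of numeric covariate columns (categorical
#'   covariates pre-encoded; ordinal codings such as 1/2/3 subtype levels
#'   are supplied by the caller), rows aligned with `survival`.
#' @param survival a [survival_table()].
#' @param removal_alpha removal threshold; default 0.10.
#' @return List of class `cox_backward`: `final` (data.frame hr/ci/p per
#'   retained covariate, or NULL if all removed), `steps` (list of
#'   per-step reports), `removed` (character, removal order), `n`.
#' @export
cox_backward_wald <- function(covariates, survival, removal_alpha = 0.10) {
  stopifnot(inherits(survival, "survival_table"))
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 1L)
    pps_stop("pps_invalid_parameter_error", "need at least one covariate")
  if (nrow(covariates) != nrow(survival))
    pps_stop("pps_format_error", "covariates rows must match survival rows")
  d <- cbind(data.frame(time = survival$time, event = survival$event),
             covariates)
  d <- d[complete.cases(d), , drop = FALSE]
  vars <- colnames(covariates)
  steps <- list()
  removed <- character(0)
  while (length(vars) > 0L) {
    fml <- stats::reformulate(vars, response = "Surv(time, event)")
    fit <- tryCatch(
      suppressWarnings(coxph(fml, data = d, ties = "efron")),
      error = function(e)
        pps_stop("pps_fit_error", "Cox fit failed at step %d: %s",
                 length(steps) + 1L, conditionMessage(e)))
    steps[[length(steps) + 1L]] <- cox_report_row(fit)
    p <- wald_p(fit)
    worst <- which.max(p)
    if (p[worst] < removal_alpha) break
    # coefficient name may differ from column name for factors; match by prefix
    drop_var <- vars[which.max(vapply(vars, function(v)
      max(p[startsWith(names(p), v)], -Inf), 0))]
    removed <- c(removed, drop_var)
    vars <- setdiff(vars, drop_var)
  }
  structure(list(final = if (length(vars)) steps[[length(steps)]] else NULL,
                 steps = steps, removed = removed, n = nrow(d)),
            class = "cox_backward")
}

#' Filter covariates by univariate significance before a multivariate fit
#'
#' The usual entry rule: only covariates significant in univariate Cox
#' (p < `alpha`) are carried into backward elimination.
#'
#' @inheritParams cox_backward_wald
#' @param alpha univariate inclusion threshold; default 0.05.
#' @return Character vector of covariate names passing the filter.
#' @export
filter_univariate_significant <- function(covariates, survival, alpha = 0.05) {
  covariates <- as.data.frame(covariates)
  p <- vapply(colnames(covariates), function(v) {
    r <- fit_univariate_cox(covariates[[v]], survival, gene_id = v)
    if (r$degenerate) NA_real_ else r$p
  }, 0)
  sel <- names(p)[!is.na(p) & p < alpha]
  pps_log("filter_univariate_significant: %d / %d covariates at p < %g",
          length(sel), ncol(covariates), alpha)
  sel
}

#' Welch or paired two-group t-test
#'
#' Unpaired comparisons use Welch's t (no equal-variance assumption);
#' paired designs (e.g. tumor vs matched normal) use the paired t-test.
#'
#' @param x,y numeric vectors; equal length required when `paired`.
#' @param paired logical.
#' @return List: `statistic`, `p`, `df`, `degenerate` (TRUE when the
#'   paired differences have zero variance).
#' @export
two_group_tests <- function(x, y, paired = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    pps_stop("pps_sample_size_error", "need >= 2 observations per group")
  if (paired && length(x) != length(y))
    pps_stop("pps_format_error", "paired test needs equal-length vectors")
  if (paired && sd(x - y) <= 1e-10 * max(abs(x - y), 1))
    return(list(statistic = NA_real_, p = NA_real_, df = NA_real_,
                degenerate = TRUE))
  if (!paired && sd(x) == 0 && sd(y) == 0)
    return(list(statistic = if (mean(x) == mean(y)) 0 else NA_real_,
                p = if (mean(x) == mean(y)) 1 else NA_real_,
                df = NA_real_, degenerate = TRUE))
  tt <- t.test(x, y, paired = paired, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Yates-corrected chi-square test on a 2x2 table
#'
#' Statistic `sum((|O - E| - 0.5)^2 / E)` with 1 degree of freedom.
#'
#' @param table 2x2 matrix of non-negative integer counts with all
#'   margins positive.
#' @return List: `statistic`, `df`, `p`.
#' @export
chisq_yates <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L))
    pps_stop("pps_invalid_parameter_error", "need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    pps_stop("pps_invalid_parameter_error", "counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    pps_stop("pps_undefined_test_error", "zero margin; test undefined")
  ct <- suppressWarnings(chisq.test(table, correct = TRUE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Write Kaplan-Meier curves as a delimited step-function table
#' @param km a `km_logrank` result.
#' @param path output path.
#' @export
write_km_curves <- function(km, path) {
  write.table(km$curves, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
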