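#' Univariate Cox proportional-hazards fit for one gene
#'
#' Fits survival on a single continuous covariate (log expression) by
#' partial likelihood with the Efron approximation for tied event times,
#' and reports the hazard ratio per unit covariate with its Wald 95% CI
#' and p-value. A constant covariate or fewer than two events cannot be
#' fit and yields a degenerate result rather than an error, so genome
#' scans keep going.
#'
#' @param expression numeric vector, one value per sample.
#' @param survival a [survival_table()]; rows aligned with `expression`.
#' @param gene_id label carried into the result.
#' @return One-row data.frame: `gene_id`, `coef`, `hr`, `ci_low`,
#'   `ci_high`, `p`, `n`, `degenerate`.
#' @export
fit_univariate_cox <- function(expression, survival, gene_id = "gene") {
  stopifnot(inherits(survival, "survival_table"))
  if (length(expression) != nrow(survival))
    pps_stop("pps_format_error", "expression length != survival rows")
  ok <- is.finite(expression) & is.finite(survival$time)
  x <- expression[ok]
  tm <- survival$time[ok]
  ev <- survival$event[ok]
  degenerate <- data.frame(gene_id = gene_id, coef = NA_real_, hr = NA_real_,
                           ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                           n = length(x), degenerate = TRUE,
                           stringsAsFactors = FALSE)
  if (length(x) < 2L || sum(ev) < 2L || sd(x) == 0) return(degenerate)
  fit <- tryCatch(
    coxph(Surv(tm, ev) ~ x, ties = "efron"),
    error = function(e) NULL, warning = function(w) {
      # monotone-likelihood / non-convergence warnings: refit quietly,
      # flag as degenerate if the coefficient ran away
      suppressWarnings(coxph(Surv(tm, ev) ~ x, ties = "efron"))
    })
  if (is.null(fit) || !is.finite(coef(fit)) || abs(coef(fit)) > 50)
    return(degenerate)
  b <- unname(coef(fit))
  se <- sqrt(unname(vcov(fit)[1L, 1L]))
  z <- b / se
  data.frame(gene_id = gene_id, coef = b, hr = exp(b),
             ci_low = exp(b - 1.959964 * se), ci_high = exp(b + 1.959964 * se),
             p = 2 * pnorm(-abs(z)), n = length(x), degenerate = FALSE,
             stringsAsFactors = FALSE)
}

#' Per-gene univariate Cox screen of an expression matrix
#'
#' Runs [fit_univariate_cox()] for every gene against the cohort's
#' survival, after intersecting the two inputs on sample id. Expression
#' is expected on a log scale.
#'
#' @param expr an [expr_matrix()] on a log scale.
#' @param survival a [survival_table()].
#' @return data.frame of class `cox_screen`, one row per gene (degenerate
#'   genes flagged, not dropped).
#' @export
screen_genes <- function(expr, survival) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!expr$unit %in% c("log_cpm", "log_rsem", "array_log"))
    pps_warn("pps_unit_warning",
             "screen_genes expects log-scale expression, got '%s'", expr$unit)
  m <- match_samples(expr, survival)
  res <- do.call(rbind, lapply(seq_len(nrow(m$expr$values)), function(i)
    fit_univariate_cox(m$expr$values[i, ], m$surv,
                       gene_id = gene_ids(m$expr)[i])))
  ndeg <- sum(res$degenerate)
  if (ndeg > 0)
    pps_log("screen_genes: %d / %d genes degenerate (excluded from ranking)",
            ndeg, nrow(res))
  class(res) <- c("cox_screen", "data.frame")
  res
}

#' Rank genes by Cox p-value and folded hazard ratio
#'
#' Two ranks are assigned to every non-degenerate gene: `p_rank`
#' ascending in the Wald p-value (rank 1 = smallest p) and `hr_rank`
#' descending in the folded hazard ratio `max(HR, 1/HR)` (rank 1 =
#' strongest effect in either direction — folding makes protective and
#' adverse effects of equal magnitude rank equally). Their sum,
#' `ranksum`, orders the output ascending: the smaller the ranksum, the
#' higher the priority. Ties get average ranks, which keeps the result
#' invariant under permutation of the input.
#'
#' @param results a `cox_screen` data.frame from [screen_genes()], or any
#'   data.frame with columns `gene_id`, `hr`, `p`, `degenerate`.
#' @return data.frame of class `rank_table` sorted by `ranksum`
#'   ascending, with columns of the input plus `folded_hr`, `p_rank`,
#'   `hr_rank`, `ranksum`.
#' @export
rank_genes <- function(results) {
  results <- results[!results$degenerate, , drop = FALSE]
  if (nrow(results) == 0L)
    pps_stop("pps_empty_table_error", "no non-degenerate genes to rank")
  results$folded_hr <- pmax(results$hr, 1 / results$hr)
  results$p_rank <- rank(results$p, ties.method = "average")
  results$hr_rank <- rank(-results$folded_hr, ties.method = "average")
  results$ranksum <- results$p_rank + results$hr_rank
  out <- results[order(results$ranksum, results$p, results$gene_id), ,
                 drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rank_table", "data.frame")
  out
}

#' Write a rank table as delimited text
#' @param x a `rank_table`.
#' @param path output path.
#' @export
write_rank_table <- function(x, path) {
  cols <- c("gene_id", "hr", "ci_low", "ci_high", "p",
            "p_rank", "hr_rank", "ranksum")
  write.table(as.data.frame(x)[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @importFrom stats coef pnorm vcov
NULL
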