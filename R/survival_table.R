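#' Per-sample time-to-event table
#'
#' @param sample_ids character vector of unique sample ids.
#' @param time non-negative event/censoring times.
#' @param event 0/1 indicator, 1 = event (death) observed.
#' @param time_unit `"days"` or `"months"`.
#' @param covariates optional data.frame of clinical covariates, one row
#'   per sample (categorical covariates should be pre-encoded as numeric
#'   by the caller where ordinal coding is intended).
#' @return A data.frame of class `survival_table` with columns
#'   `sample_id`, `time`, `event`, any covariates, and attribute
#'   `time_unit`.
#' @export
survival_table <- function(sample_ids, time, event,
                           time_unit = c("months", "days"),
                           covariates = NULL) {
  time_unit <- match.arg(time_unit)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    pps_stop("pps_format_error", "duplicate sample id(s) in survival table")
  if (length(time) != length(sample_ids) || length(event) != length(sample_ids))
    pps_stop("pps_format_error", "time/event length must match sample_ids")
  if (any(!is.finite(time)) || any(time < 0))
    pps_stop("pps_format_error", "times must be finite and non-negative")
  if (!all(event %in% c(0, 1)))
    pps_stop("pps_format_error", "event must be 0 (censored) or 1 (event)")
  df <- data.frame(sample_id = sample_ids, time = as.numeric(time),
                   event = as.integer(event), stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    if (nrow(covariates) != nrow(df))
      pps_stop("pps_format_error", "covariates must have one row per sample")
    df <- cbind(df, covariates)
  }
  attr(df, "time_unit") <- time_unit
  class(df) <- c("survival_table", "data.frame")
  df
}

#' Read a delimited survival table
#'
#' Requires columns `sample_id`, `time`, `event`; any further columns are
#' kept as covariates.
#'
#' @param path file path.
#' @param time_unit unit of the `time` column.
#' @param delimiter field separator, default tab.
#' @return A [survival_table()].
#' @export
read_survival <- function(path, time_unit = c("months", "days"),
                          delimiter = "\t") {
  time_unit <- match.arg(time_unit)
  df <- read.delim(path, sep = delimiter, stringsAsFactors = FALSE,
                   check.names = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    pps_stop("pps_format_error", "survival table %s lacks column(s): %s",
             path, paste(miss, collapse = ", "))
  extra <- df[, setdiff(colnames(df), need), drop = FALSE]
  survival_table(df$sample_id, df$time, df$event, time_unit,
                 covariates = if (ncol(extra)) extra else NULL)
}

#' Write a survival table as delimited text
#' @param x a [survival_table()].
#' @param path output path.
#' @param delimiter field separator, default tab.
#' @export
write_survival <- function(x, path, delimiter = "\t") {
  write.table(as.data.frame(x), path, sep = delimiter, quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Apply the survival exclusion and day-to-month conversion rules
#'
#' Samples with a recorded time of exactly 0 are excluded (they carry no
#' follow-up information and break log-time based machinery). Times in
#' days are optionally converted to months by division by 30 for
#' Kaplan-Meier display consistency; Cox regression is scale-invariant
#' in time so either unit gives identical fits.
#'
#' @param table a [survival_table()].
#' @param to_months convert day-scale times to months (time / 30)?
#' @return A `survival_table` with zero-time rows removed.
#' @export
prepare_survival <- function(table, to_months = FALSE) {
  stopifnot(inherits(table, "survival_table"))
  zero <- table$time == 0
  if (any(zero))
    pps_log("prepare_survival: excluded %d sample(s) with survival value 0",
            sum(zero))
  out <- table[!zero, , drop = FALSE]
  if (nrow(out) == 0L)
    pps_stop("pps_empty_cohort_error", "no samples left after zero-time exclusion")
  unit <- attr(table, "time_unit")
  if (to_months) {
    if (unit == "days") {
      out$time <- out$time / 30
      unit <- "months"
    } # already months: no-op
  }
  attr(out, "time_unit") <- unit
  class(out) <- c("survival_table", "data.frame")
  out
}

# Intersect an expression matrix and a survival table on sample ids.
# Partial clinical coverage is the norm in public cohorts, so this is
# silent apart from a logged count.
match_samples <- function(expr, surv) {
  common <- intersect(sample_ids(expr), surv$sample_id)
  if (length(common) == 0L)
    pps_stop("pps_empty_cohort_error",
             "no overlapping samples between expression and survival data")
  dropped <- (ncol(expr$values) - length(common)) +
    (nrow(surv) - length(common))
  if (dropped > 0)
    pps_log("match_samples: %d samples in common (%d without a match dropped)",
            length(common), dropped)
  surv2 <- surv[match(common, surv$sample_id), , drop = FALSE]
  attr(surv2, "time_unit") <- attr(surv, "time_unit")
  class(surv2) <- c("survival_table", "data.frame")
  list(expr = expr_matrix(expr$values[, common, drop = FALSE], expr$unit),
       surv = surv2)
}
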