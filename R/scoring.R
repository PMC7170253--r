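#' Compute a signed-sum signature score per sample
#'
#' For a sign signature the score of sample s is the sum of the log
#' expression of the +1 genes minus the sum of the -1 genes; for a
#' coefficient signature it is the weighted sum. Signature genes missing
#' from the matrix are dropped with a logged list rather than imputed
#' (on an array without one of the genes the score is simply computed
#' from the remaining terms); a minimum-coverage guard refuses scores
#' based on too few genes.
#'
#' @param expr a log-scale [expr_matrix()].
#' @param signature a [pps_signature()].
#' @param min_coverage minimum fraction of signature genes that must be
#'   present; default 0.5.
#' @return data.frame of class `score_vector` with columns `sample_id`,
#'   `score`; attributes `signature_name` and `genes_used`.
#' @export
compute_score <- function(expr, signature, min_coverage = 0.5) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(signature, "pps_signature"))
  if (!expr$unit %in% c("log_cpm", "log_rsem", "array_log"))
    pps_warn("pps_unit_warning",
             "scores are defined on log expression; matrix unit is '%s'",
             expr$unit)
  e <- signature$entries
  present <- e$gene %in% gene_ids(expr)
  if (!any(present))
    pps_stop("pps_coverage_error",
             "none of the %d signature genes present in the matrix", nrow(e))
  if (mean(present) < min_coverage)
    pps_stop("pps_coverage_error",
             "only %d / %d signature genes present (< %g coverage)",
             sum(present), nrow(e), min_coverage)
  if (any(!present))
    pps_log("compute_score: %d signature gene(s) absent, dropped: %s",
            sum(!present), paste(e$gene[!present], collapse = ", "))
  used <- e[present, , drop = FALSE]
  score <- as.vector(crossprod(expr$values[used$gene, , drop = FALSE],
                               used$weight))
  out <- data.frame(sample_id = sample_ids(expr), score = score,
                    stringsAsFactors = FALSE)
  attr(out, "signature_name") <- signature$name
  attr(out, "genes_used") <- used$gene
  class(out) <- c("score_vector", "data.frame")
  out
}

#' Split samples into high/low groups at a cut-off
#'
#' The default rule is the cohort median: samples with score strictly
#' above the median are "high", the rest "low", so exact-median samples
#' land in the low group (the placement is logged and can be flipped
#' with `ties_high`). A fixed numeric cut-off can be supplied instead
#' (e.g. a transferred threshold from another platform).
#'
#' @param scores a `score_vector` from [compute_score()], or a numeric
#'   vector with names as sample ids.
#' @param cutoff `"median"` or a numeric value.
#' @param ties_high put samples exactly at the cut-off in the high group?
#'   Default FALSE.
#' @return data.frame of class `group_assignment` with columns
#'   `sample_id`, `score`, `group` (factor low/high); attributes `cutoff`
#'   and `cutoff_rule`.
#' @export
dichotomize <- function(scores, cutoff = "median", ties_high = FALSE) {
  if (is.numeric(scores) && !is.data.frame(scores))
    scores <- data.frame(sample_id = names(scores) %||%
                           as.character(seq_along(scores)),
                         score = as.numeric(scores), stringsAsFactors = FALSE)
  if (nrow(scores) < 2L)
    pps_stop("pps_invalid_parameter_error", "need >= 2 samples to dichotomize")
  rule <- if (identical(cutoff, "median")) "median" else "value"
  cut <- if (rule == "median") median(scores$score) else as.numeric(cutoff)
  hi <- if (ties_high) scores$score >= cut else scores$score > cut
  if (all(hi) || !any(hi))
    pps_stop("pps_degenerate_split_error",
             "cut-off %g leaves one group empty (all scores %s)", cut,
             if (all(hi)) "above" else "at or below")
  out <- data.frame(sample_id = scores$sample_id, score = scores$score,
                    group = factor(ifelse(hi, "high", "low"),
                                   levels = c("low", "high")),
                    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cut
  attr(out, "cutoff_rule") <- rule
  class(out) <- c("group_assignment", "data.frame")
  out
}
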