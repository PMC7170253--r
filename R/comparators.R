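#' Specification of a previously published comparator signature
#'
#' Two modes are supported. `weighted`: the published per-gene
#' coefficients multiply log expression and the score is their sum
#' (Chen-style and Yan-style signatures). `binary_cutoff`: each gene is
#' called present (1) or absent (0) against a per-gene expression
#' cut-off, the calls are weighted and summed, and a fixed decision
#' threshold splits high from low risk (Shi-style signatures); cut-offs
#' determined on one platform are carried to another via
#' [transfer_cutoffs()].
#'
#' @param name signature name.
#' @param genes character vector of gene symbols.
#' @param mode `"weighted"` or `"binary_cutoff"`.
#' @param coefficients per-gene coefficients (weighted mode) or
#'   indicator weights (binary mode).
#' @param reference_cutoffs,reference_medians per-gene values from the
#'   reference platform (binary mode; medians must be positive).
#' @param threshold decision threshold on the binary risk score.
#' @return List of class `comparator_spec`.
#' @export
comparator_spec <- function(name, genes, mode = c("weighted", "binary_cutoff"),
                            coefficients, reference_cutoffs = NULL,
                            reference_medians = NULL, threshold = NA_real_) {
  mode <- match.arg(mode)
  genes <- as.character(genes)
  if (anyDuplicated(genes))
    pps_stop("pps_format_error", "duplicate genes in comparator spec")
  if (length(coefficients) != length(genes))
    pps_stop("pps_format_error", "one coefficient per gene required")
  if (mode == "binary_cutoff") {
    if (is.null(reference_cutoffs) || is.null(reference_medians) ||
        length(reference_cutoffs) != length(genes) ||
        length(reference_medians) != length(genes))
      pps_stop("pps_format_error",
               "binary_cutoff mode needs reference cut-offs and medians per gene")
    if (any(reference_medians <= 0))
      pps_stop("pps_transfer_error",
               "binary_cutoff mode requires positive reference medians")
  }
  structure(list(name = name, genes = genes, mode = mode,
                 coefficients = setNames(as.numeric(coefficients), genes),
                 reference_cutoffs = if (!is.null(reference_cutoffs))
                   setNames(as.numeric(reference_cutoffs), genes),
                 reference_medians = if (!is.null(reference_medians))
                   setNames(as.numeric(reference_medians), genes),
                 threshold = threshold),
            class = "comparator_spec")
}

#' Coefficient-weighted comparator score
#'
#' `score(s) = sum over genes of coefficient_g * expr[g, s]`. Genes
#' absent from the platform are dropped from the sum and logged — the
#' standard accommodation when one signature gene has no probe on the
#' target array.
#'
#' @param expr a log-scale [expr_matrix()].
#' @param spec a `weighted` [comparator_spec()].
#' @return A `score_vector` (see [compute_score()]); dichotomize with
#'   [dichotomize()].
#' @export
weighted_score <- function(expr, spec) {
  stopifnot(inherits(spec, "comparator_spec"))
  if (spec$mode != "weighted")
    pps_stop("pps_invalid_parameter_error", "spec '%s' is not weighted mode",
             spec$name)
  sig <- pps_signature(spec$genes, spec$coefficients, name = spec$name)
  compute_score(expr, sig, min_coverage = 0)
}

#' Transfer per-gene expression cut-offs across platforms
#'
#' A cut-off defined on a reference platform is scaled to a target
#' platform through the ratio of medians: the per-gene coefficient is
#' `reference_cutoff / reference_median`, and the target cut-off is
#' `coefficient * target_median`. Exact only insofar as the two
#' platforms' expression scales are proportional, so treat the result as
#' an approximation.
#'
#' @param spec a `binary_cutoff` [comparator_spec()].
#' @param target_medians named per-gene medians on the target platform
#'   (must be positive).
#' @return Named numeric vector of target cut-offs.
#' @export
transfer_cutoffs <- function(spec, target_medians) {
  stopifnot(inherits(spec, "comparator_spec"))
  if (spec$mode != "binary_cutoff")
    pps_stop("pps_invalid_parameter_error", "spec '%s' is not binary_cutoff mode",
             spec$name)
  miss <- setdiff(spec$genes, names(target_medians))
  if (length(miss))
    pps_stop("pps_transfer_error", "no target median for gene(s): %s",
             paste(miss, collapse = ", "))
  tm <- target_medians[spec$genes]
  bad <- spec$genes[tm <= 0]
  if (length(bad))
    pps_stop("pps_transfer_error", "non-positive target median for: %s",
             paste(bad, collapse = ", "))
  coefficient <- spec$reference_cutoffs / spec$reference_medians
  coefficient * tm
}

#' Binary present/absent risk score with a fixed decision threshold
#'
#' Each gene is scored 1 when its expression exceeds its cut-off and 0
#' otherwise; the weighted sum of the indicators is compared with
#' `threshold` to assign high/low risk.
#'
#' @param expr an [expr_matrix()].
#' @param cutoffs named per-gene cut-offs on the matrix's scale.
#' @param weights named per-gene weights over the same genes.
#' @param threshold decision threshold; default 1.709.
#' @return A `group_assignment` whose `score` column is the binary risk
#'   score.
#' @export
binary_risk_score <- function(expr, cutoffs, weights, threshold = 1.709) {
  stopifnot(inherits(expr, "expr_matrix"))
  genes <- names(cutoffs)
  if (!setequal(genes, names(weights)))
    pps_stop("pps_format_error", "cutoffs and weights must cover the same genes")
  present <- intersect(genes, gene_ids(expr))
  if (length(present) == 0L)
    pps_stop("pps_coverage_error", "no cut-off gene present in the matrix")
  if (length(present) < length(genes))
    pps_log("binary_risk_score: %d gene(s) absent, dropped",
            length(genes) - length(present))
  ind <- (expr$values[present, , drop = FALSE] > cutoffs[present]) * 1
  risk <- as.vector(crossprod(ind, weights[present]))
  out <- data.frame(sample_id = sample_ids(expr), score = risk,
                    group = factor(ifelse(risk > threshold, "high", "low"),
                                   levels = c("low", "high")),
                    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- threshold
  attr(out, "cutoff_rule") <- "value"
  class(out) <- c("group_assignment", "data.frame")
  out
}
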