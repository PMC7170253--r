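#' Cell line x compound drug-response (AUC) table
#'
#' Area-under-curve cytotoxicity values, lower = more sensitive; missing
#' entries allowed (not every line is screened against every compound).
#'
#' @param auc numeric matrix, cell lines in rows, drugs in columns, with
#'   dimnames; NAs allowed.
#' @param n_concentrations optional integer vector, per-drug number of
#'   tested concentrations.
#' @return List of class `drug_response_table`.
#' @export
drug_response_table <- function(auc, n_concentrations = NULL) {
  if (!is.matrix(auc) || is.null(rownames(auc)) || is.null(colnames(auc)))
    pps_stop("pps_format_error", "auc must be a matrix with line/drug dimnames")
  if (any(!is.finite(auc) & !is.na(auc)))
    pps_stop("pps_format_error", "AUC values must be finite where present")
  if (!is.null(n_concentrations) && length(n_concentrations) != ncol(auc))
    pps_stop("pps_format_error", "n_concentrations must have one entry per drug")
  structure(list(auc = auc,
                 n_concentrations = if (!is.null(n_concentrations))
                   setNames(as.integer(n_concentrations), colnames(auc))),
            class = "drug_response_table")
}

#' Read a delimited cell line x drug AUC matrix
#' @param path file path; first column cell line ids, header drug ids.
#' @param delimiter field separator, default tab.
#' @return A [drug_response_table()].
#' @export
read_drug_response <- function(path, delimiter = "\t") {
  df <- read.delim(path, sep = delimiter, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  drug_response_table(m)
}

#' Filter drugs by screening coverage and assay design
#'
#' Keeps drugs screened against at least `min_lines` cell lines
#' (non-missing AUC) and, when per-drug concentration metadata is
#' available and `required_concentrations` is set, only drugs assayed at
#' exactly that many concentrations.
#'
#' @param table a [drug_response_table()].
#' @param min_lines minimum non-missing lines per drug; default 10.
#' @param required_concentrations exact concentration count to require,
#'   or NULL to skip that filter; default 16 when metadata is present.
#' @return A filtered `drug_response_table`.
#' @export
filter_drugs <- function(table, min_lines = 10L, required_concentrations = 16L) {
  stopifnot(inherits(table, "drug_response_table"))
  keep <- colSums(!is.na(table$auc)) >= min_lines
  if (!is.null(table$n_concentrations) && !is.null(required_concentrations))
    keep <- keep & table$n_concentrations == required_concentrations
  pps_log("filter_drugs: kept %d / %d drugs", sum(keep), length(keep))
  if (!any(keep)) {
    pps_warn("pps_empty_screen_warning", "no drug passed the filters")
    return(structure(list(auc = table$auc[, keep, drop = FALSE],
                          n_concentrations = table$n_concentrations[keep]),
                     class = "drug_response_table"))
  }
  drug_response_table(table$auc[, keep, drop = FALSE],
                      table$n_concentrations[keep])
}

#' Pearson correlation of a signature score with per-drug AUC
#'
#' For each drug, the score is correlated with AUC over the cell lines
#' that have both values, after removing `exclusions` (outlier lines).
#' Drugs with fewer than 3 usable points or zero AUC variance are
#' skipped with a reason.
#'
#' @param scores a `score_vector` over cell lines (sample ids = line
#'   ids), or a named numeric vector.
#' @param table a [drug_response_table()].
#' @param exclusions character vector of cell line ids to drop.
#' @return data.frame of class `drug_screen`: `drug_id`, `r`, `p`, `n`,
#'   `skipped`, `reason`.
#' @export
correlate_score_auc <- function(scores, table, exclusions = character(0)) {
  stopifnot(inherits(table, "drug_response_table"))
  if (is.data.frame(scores))
    scores <- setNames(scores$score, scores$sample_id)
  if (length(exclusions))
    pps_log("correlate_score_auc: excluding %d line(s): %s",
            length(exclusions), paste(exclusions, collapse = ", "))
  lines <- setdiff(intersect(names(scores), rownames(table$auc)), exclusions)
  if (length(lines) < 3L)
    pps_stop("pps_empty_cohort_error",
             "fewer than 3 cell lines shared by scores and AUC table")
  res <- lapply(colnames(table$auc), function(d) {
    a <- table$auc[lines, d]
    ok <- !is.na(a)
    if (sum(ok) < 3L)
      return(data.frame(drug_id = d, r = NA_real_, p = NA_real_, n = sum(ok),
                        skipped = TRUE, reason = "fewer than 3 points",
                        stringsAsFactors = FALSE))
    if (sd(a[ok]) == 0 || sd(scores[lines][ok]) == 0)
      return(data.frame(drug_id = d, r = NA_real_, p = NA_real_, n = sum(ok),
                        skipped = TRUE, reason = "zero variance",
                        stringsAsFactors = FALSE))
    ct <- cor.test(scores[lines][ok], a[ok], method = "pearson")
    data.frame(drug_id = d, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), skipped = FALSE, reason = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("drug_screen", "data.frame")
  out
}

#' Label significantly correlated drugs by the group they target
#'
#' Under the default `"auc_sensitivity"` convention, lower AUC means
#' greater cytotoxicity, so a drug whose AUC correlates negatively with
#' the score is preferentially effective on high-score lines. The
#' `"literal"` convention inverts the reading (positive correlation =>
#' effective on the high-score group), matching the alternative verbal
#' convention found in parts of the literature; both are provided
#' because published descriptions disagree.
#'
#' @param correlations a `drug_screen` from [correlate_score_auc()].
#' @param alpha significance threshold; default 0.05 (nominal, no
#'   multiplicity correction).
#' @param convention `"auc_sensitivity"` (default) or `"literal"`.
#' @param adjust p-adjustment method passed to [stats::p.adjust()];
#'   default `"none"`, `"BH"` available.
#' @return The input with columns `p_adj` and `target` ("high", "low" or
#'   NA), sorted by p ascending.
#' @export
classify_targets <- function(correlations, alpha = 0.05,
                             convention = c("auc_sensitivity", "literal"),
                             adjust = "none") {
  convention <- match.arg(convention)
  stopifnot(inherits(correlations, "drug_screen"))
  out <- correlations
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  sig <- !out$skipped & !is.na(out$p_adj) & out$p_adj < alpha
  neg_target <- if (convention == "auc_sensitivity") "high" else "low"
  pos_target <- if (convention == "auc_sensitivity") "low" else "high"
  out$target <- NA_character_
  out$target[sig & out$r < 0] <- neg_target
  out$target[sig & out$r > 0] <- pos_target
  out <- out[order(out$skipped, out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("drug_screen", "data.frame")
  out
}
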