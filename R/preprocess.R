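#' Counts-per-million normalization
#'
#' CPM of gene g in sample s is `count[g, s] / total[s] * 1e6`, where the
#' total is the sample's full column sum. Apply before any gene filtering
#' if the totals should reflect the whole library.
#'
#' @param counts an [expr_matrix()] with unit `"counts"`.
#' @return An `expr_matrix` with unit `"cpm"`; every column sums to 1e6.
#' @export
compute_cpm <- function(counts) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (counts$unit != "counts")
    pps_stop("pps_unit_error", "compute_cpm needs counts, got unit '%s'", counts$unit)
  tot <- colSums(counts$values)
  zero <- names(tot)[tot <= 0]
  if (length(zero))
    pps_stop("pps_degenerate_sample_error",
             "sample(s) with zero total count: %s", paste(zero, collapse = ", "))
  vals <- sweep(counts$values, 2L, tot, "/") * 1e6
  expr_matrix(vals, "cpm")
}

#' Log-transform a linear-scale expression matrix
#'
#' Computes `log_base(value + pseudocount)`. The default pseudocount is
#' 0.001 and the default base is 2, applied uniformly so scores stay
#' comparable across cohorts.
#'
#' @param expr an [expr_matrix()] on a linear scale (`"cpm"` or a
#'   RSEM-like matrix read with unit `"cpm"`).
#' @param pseudocount positive offset added before the log; default 0.001.
#' @param base log base, 2 or `exp(1)`; default 2.
#' @param out_unit unit tag of the result, default `"log_cpm"`.
#' @return An `expr_matrix` on log scale.
#' @export
log_transform <- function(expr, pseudocount = 0.001, base = 2,
                          out_unit = c("log_cpm", "log_rsem", "array_log")) {
  stopifnot(inherits(expr, "expr_matrix"))
  out_unit <- match.arg(out_unit)
  if (expr$unit %in% c("log_cpm", "log_rsem", "array_log"))
    pps_stop("pps_unit_error", "matrix already on log scale ('%s')", expr$unit)
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    pps_stop("pps_domain_error", "pseudocount must be positive")
  if (any(expr$values < 0, na.rm = TRUE))
    pps_stop("pps_domain_error", "negative values cannot be log-transformed")
  expr_matrix(log(expr$values + pseudocount, base = base), out_unit)
}

#' Drop genes that are zero in most samples
#'
#' A gene is removed when its fraction of zero-count samples is strictly
#' greater than `max_zero_fraction` ("more than 85%" at the default), a
#' standard guard against genes too sparse to carry survival signal.
#' Idempotent: re-filtering the result removes nothing further.
#'
#' @param counts an [expr_matrix()] with unit `"counts"`.
#' @param max_zero_fraction maximum tolerated zero fraction; default 0.85.
#' @return A filtered `expr_matrix`; removed gene ids are attached as
#'   attribute `"removed"` and logged.
#' @export
filter_zero_genes <- function(counts, max_zero_fraction = 0.85) {
  stopifnot(inherits(counts, "expr_matrix"))
  if (counts$unit != "counts")
    pps_stop("pps_unit_error", "filter_zero_genes needs counts, got '%s'", counts$unit)
  zf <- rowMeans(counts$values == 0)
  drop <- zf > max_zero_fraction
  pps_log("filter_zero_genes: removed %d / %d genes (zero fraction > %g)",
          sum(drop), length(drop), max_zero_fraction)
  if (all(drop)) {
    pps_warn("pps_empty_result_warning", "all genes removed by zero filter")
    kept <- counts$values[!drop, , drop = FALSE]
    return(structure(list(values = kept, unit = "counts",
                          removed = gene_ids(counts)[drop]),
                     class = "expr_matrix"))
  }
  out <- expr_matrix(counts$values[!drop, , drop = FALSE], "counts")
  out$removed <- gene_ids(counts)[drop]
  out
}

#' Collapse probes to gene symbols by averaging
#'
#' Microarray platforms carry several probesets per gene; each gene's row
#' becomes the arithmetic mean of its probes' rows, on whatever scale the
#' matrix is stored (no rescaling). Probes with no mapping are dropped
#' and logged.
#'
#' @param expr an [expr_matrix()] keyed by probe id.
#' @param probe_to_gene named character vector mapping probe id to gene
#'   symbol (names = probe ids), or a two-column data.frame (probe, gene).
#' @return An `expr_matrix` with one row per gene symbol; sample order
#'   unchanged.
#' @export
collapse_probes <- function(expr, probe_to_gene) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (is.data.frame(probe_to_gene))
    probe_to_gene <- setNames(as.character(probe_to_gene[[2L]]),
                              as.character(probe_to_gene[[1L]]))
  probe_to_gene <- probe_to_gene[!is.na(probe_to_gene) & nzchar(probe_to_gene)]
  if (length(probe_to_gene) == 0L)
    pps_stop("pps_mapping_error", "empty probe-to-gene mapping")
  probes <- gene_ids(expr)
  mapped <- probes %in% names(probe_to_gene)
  if (sum(mapped) == 0L)
    pps_stop("pps_mapping_error", "no probe in the matrix has a mapping")
  pps_log("collapse_probes: %d / %d probes unmapped, dropped",
          sum(!mapped), length(probes))
  sub <- expr$values[mapped, , drop = FALSE]
  genes <- probe_to_gene[probes[mapped]]
  # rowsum sums rows by group; divide by group size for the mean
  summed <- rowsum(sub, group = genes, reorder = FALSE)
  n <- as.vector(table(genes)[rownames(summed)])
  expr_matrix(summed / n, expr$unit)
}

#' Read a two-column probe-to-gene annotation file
#'
#' @param path delimited text, first column probe id, second gene symbol.
#' @param delimiter field separator, default tab.
#' @param header whether the file has a header row.
#' @return Named character vector, names = probe ids.
#' @export
read_probe_map <- function(path, delimiter = "\t", header = TRUE) {
  df <- read.delim(path, sep = delimiter, header = header,
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L)
    pps_stop("pps_mapping_error", "probe map needs two columns: %s", path)
  setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}
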