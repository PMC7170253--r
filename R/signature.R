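#' Gene signature with signs or coefficients
#'
#' A signature is an ordered list of gene symbols, each carrying either a
#' sign (+1 = adverse, expression added to the score; -1 = favorable,
#' subtracted) or a real coefficient (for weighted comparator
#' signatures).
#'
#' @param genes character vector of unique gene symbols.
#' @param weights numeric vector of signs (+1/-1) or coefficients.
#' @param name signature name.
#' @param provenance optional list of discovery parameters (k,
#'   min_cohorts, alpha, ...).
#' @return A list of class `pps_signature` with an `entries` data.frame
#'   (`gene`, `weight`).
#' @export
pps_signature <- function(genes, weights, name = "signature", provenance = list()) {
  genes <- as.character(genes)
  if (anyDuplicated(genes))
    pps_stop("pps_format_error", "duplicate gene symbols in signature")
  if (length(weights) != length(genes))
    pps_stop("pps_format_error", "one weight per gene required")
  structure(list(entries = data.frame(gene = genes,
                                      weight = as.numeric(weights),
                                      stringsAsFactors = FALSE),
                 name = name, provenance = provenance),
            class = "pps_signature")
}

#' @export
print.pps_signature <- function(x, ...) {
  e <- x$entries
  cat(sprintf("signature '%s': %d genes (%d positive, %d negative)\n",
              x$name, nrow(e), sum(e$weight > 0), sum(e$weight < 0)))
  invisible(x)
}

#' The bundled 20-gene pancreatic cancer prognostic signature (PPS20)
#'
#' Eleven genes associated with shorter overall survival enter with sign
#' +1 and nine genes associated with longer survival with sign -1; the
#' score is the signed sum of their log expression:
#' ARNTL2 - KANK1 + MAP4K4 + LDHA + SLC20A1 + TRIO - ZNF557 + EPS8 -
#' CBX7 + RAB7A - POLR3H + STX16 - PITPNA + TFG - CADPS2 + ERRFI1 +
#' GSK3B - NDUFB2 - C2orf42 - MIA3.
#'
#' @return A [pps_signature()] with 20 entries, loaded from the shipped
#'   fixture.
#' @export
pps20_signature <- function() {
  path <- system.file("extdata", "pps20_signature.tsv", package = "pps20",
                      mustWork = TRUE)
  read_signature(path, name = "PPS20")
}

#' Read / write signatures as two-column delimited text
#'
#' Format: comment lines starting with `#` (provenance), then a header
#' `gene<TAB>weight` and one row per gene.
#'
#' @param path file path.
#' @param name signature name; defaults to the file base name.
#' @return A [pps_signature()].
#' @export
read_signature <- function(path, name = NULL) {
  if (!file.exists(path))
    pps_stop("pps_format_error", "signature file not found: %s", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("gene", "weight") %in% colnames(df)))
    pps_stop("pps_format_error", "signature file needs columns gene, weight")
  pps_signature(df$gene, df$weight,
            name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_signature
#' @param x a [pps_signature()].
#' @export
write_signature <- function(x, path) {
  stopifnot(inherits(x, "pps_signature"))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(x$provenance))
    writeLines(sprintf("# %s: %s", names(x$provenance),
                       vapply(x$provenance, function(v)
                         paste(format(v), collapse = ","), "")), con)
  writeLines("gene\tweight", con)
  writeLines(sprintf("%s\t%g", x$entries$gene, x$entries$weight), con)
  invisible(path)
}

#' Top-K genes of a rank table
#'
#' Returns the first `k` genes by ranksum. Average-rank ties can straddle
#' the cut; all genes tied with the k-th ranksum are included and any
#' overage is logged.
#'
#' @param rank_table a `rank_table` from [rank_genes()].
#' @param k number of genes, default 500.
#' @return Character vector of gene ids.
#' @export
top_k <- function(rank_table, k = 500L) {
  stopifnot(inherits(rank_table, "rank_table"))
  if (k >= nrow(rank_table)) {
    if (k > nrow(rank_table))
      pps_warn("pps_parameter_warning",
               "k = %d exceeds table size %d; returning all genes",
               k, nrow(rank_table))
    return(rank_table$gene_id)
  }
  cut <- rank_table$ranksum[k]
  sel <- rank_table$gene_id[rank_table$ranksum <= cut]
  if (length(sel) > k)
    pps_log("top_k: boundary tie at ranksum %g, returning %d genes for k = %d",
            cut, length(sel), k)
  sel
}

#' Genes present in at least `min_cohorts` of several top-K sets
#'
#' @param sets list of character vectors (per-cohort top-K gene sets).
#' @param min_cohorts minimum number of sets a gene must appear in;
#'   default 2.
#' @return Character vector (possibly empty).
#' @export
intersect_cohorts <- function(sets, min_cohorts = 2L) {
  if (min_cohorts < 1L || min_cohorts > length(sets))
    pps_stop("pps_invalid_parameter_error",
             "min_cohorts must be in 1..%d, got %d", length(sets), min_cohorts)
  counts <- table(unlist(lapply(sets, unique)))
  sort(names(counts)[counts >= min_cohorts])
}

#' Retest candidate genes in a tuning cohort and assemble a signature
#'
#' Each candidate is refit by univariate Cox in the tuning cohort; genes
#' with Wald p < `alpha` are retained with sign +1 when the tuning HR is
#' above 1 (shorter survival) and -1 when below. When discovery-cohort
#' hazard directions are supplied, genes whose tuning direction
#' contradicts discovery are excluded by default (a signature with
#' internally contradictory directions is uninterpretable); set
#' `drop_sign_flips = FALSE` to keep them with the tuning sign.
#'
#' @param candidates character vector of candidate genes.
#' @param tuning_expr log-scale [expr_matrix()] of the tuning cohort.
#' @param tuning_survival [survival_table()] of the tuning cohort.
#' @param alpha retention threshold on the tuning p-value; default 0.05.
#' @param discovery_signs optional named vector of +1/-1 consensus
#'   discovery directions per candidate.
#' @param drop_sign_flips exclude genes whose tuning sign contradicts
#'   `discovery_signs`? Default TRUE.
#' @param name name of the resulting signature.
#' @return A [pps_signature()]; zero retained genes gives an empty signature
#'   with a warning, not an error.
#' @export
retest <- function(candidates, tuning_expr, tuning_survival, alpha = 0.05,
                   discovery_signs = NULL, drop_sign_flips = TRUE,
                   name = "discovered") {
  if (length(candidates) == 0L)
    pps_stop("pps_invalid_parameter_error", "no candidate genes supplied")
  present <- intersect(candidates, gene_ids(tuning_expr))
  if (length(present) < length(candidates))
    pps_log("retest: %d candidate(s) absent from the tuning cohort",
            length(candidates) - length(present))
  sub <- expr_matrix(tuning_expr$values[present, , drop = FALSE],
                     tuning_expr$unit)
  res <- screen_genes(sub, tuning_survival)
  keep <- !res$degenerate & res$p < alpha
  res <- res[keep, , drop = FALSE]
  signs <- ifelse(res$hr > 1, 1L, -1L)
  if (!is.null(discovery_signs) && nrow(res)) {
    disc <- discovery_signs[res$gene_id]
    flip <- !is.na(disc) & disc != signs
    if (any(flip)) {
      pps_log("retest: %d gene(s) flip direction vs discovery: %s",
              sum(flip), paste(res$gene_id[flip], collapse = ", "))
      if (drop_sign_flips) {
        res <- res[!flip, , drop = FALSE]
        signs <- signs[!flip]
      }
    }
  }
  if (nrow(res) == 0L)
    pps_warn("pps_empty_signature_warning",
             "no candidate passed the tuning retest at alpha = %g", alpha)
  ord <- order(res$p)
  pps_signature(res$gene_id[ord], signs[ord], name = name,
            provenance = list(alpha = alpha, n_candidates = length(candidates),
                              tuning_n = ncol(tuning_expr$values)))
}
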