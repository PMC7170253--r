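#' Expression matrix with an explicit unit tag
#'
#' A thin container for a genes x samples numeric matrix plus the scale
#' ("unit") its values are on. Downstream operations check the unit so
#' that, e.g., CPM normalization is only applied to raw counts and
#' signature scores are only computed on a log scale.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param unit one of `"counts"`, `"cpm"`, `"log_cpm"`, `"log_rsem"`,
#'   `"array_log"`.
#' @return An object of class `expr_matrix`: a list with elements
#'   `values` and `unit`.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' em <- expr_matrix(m, "counts")
#' gene_ids(em)
#' @export
expr_matrix <- function(values, unit = c("counts", "cpm", "log_cpm",
                                         "log_rsem", "array_log")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    pps_stop("pps_format_error", "values must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    pps_stop("pps_format_error", "empty expression matrix (%d genes x %d samples)",
             nrow(values), ncol(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    pps_stop("pps_format_error", "expression matrix needs gene rownames and sample colnames")
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    pps_stop("pps_format_error", "duplicate sample id(s): %s",
             paste(unique(dup), collapse = ", "))
  dupg <- rownames(values)[duplicated(rownames(values))]
  if (length(dupg))
    pps_stop("pps_format_error", "duplicate gene id(s): %s",
             paste(unique(head(dupg, 5)), collapse = ", "))
  if (unit == "counts") {
    v <- values[is.finite(values)]
    if (any(v < 0) || any(v != round(v)))
      pps_stop("pps_format_error", "counts unit requires non-negative integral values")
  }
  structure(list(values = values, unit = unit), class = "expr_matrix")
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expr_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' Read a delimited gene x sample expression matrix
#'
#' Expects gene/probe ids in the first column and sample ids in the header
#' row, the common layout of GEO series-matrix exports and TCGA/ICGC
#' flat files. Leading metadata lines (series-matrix preamble) can be
#' skipped with `skip`.
#'
#' @param path file path.
#' @param unit unit tag to attach (see [expr_matrix()]).
#' @param delimiter field separator, default tab.
#' @param skip number of leading lines to skip before the header.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, unit, delimiter = "\t", skip = 0L) {
  if (!file.exists(path))
    pps_stop("pps_format_error", "file not found: %s", path)
  df <- read.delim(path, sep = delimiter, skip = skip, header = TRUE,
                   check.names = FALSE, stringsAsFactors = FALSE,
                   quote = "\"", comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L)
    pps_stop("pps_format_error", "empty or single-column matrix in %s", path)
  ids <- as.character(df[[1L]])
  samp <- colnames(df)[-1L]
  dup <- samp[duplicated(samp)]
  if (length(dup))
    pps_stop("pps_format_error", "duplicate sample id(s) in header of %s: %s",
             path, paste(unique(dup), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    # locate the offending cells for the error message
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2L,
                                              as.numeric))) &
                   !is.na(as.matrix(df[, -1L, drop = FALSE])), arr.ind = TRUE)
    loc <- if (nrow(bad)) sprintf(" first at row %d, column %s",
                                  bad[1L, 1L], samp[bad[1L, 2L]]) else ""
    pps_stop("pps_format_error", "non-numeric cells in %s;%s", path, loc)
  }
  storage.mode(vals) <- "double"
  dimnames(vals) <- list(ids, samp)
  expr_matrix(vals, unit)
}

#' Write an expression matrix as delimited text
#'
#' @param x an [expr_matrix()].
#' @param path output file path.
#' @param delimiter field separator, default tab.
#' @param id_column name for the first (gene id) column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, delimiter = "\t", id_column = "gene_id") {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene_id = gene_ids(x), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write.table(df, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}
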