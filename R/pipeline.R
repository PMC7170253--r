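#' Pipeline configuration
#'
#' Collects cohort file paths by role and every tunable threshold of the
#' discovery/validation workflow, with the canonical defaults: top-K =
#' 500, intersection across >= 2 discovery cohorts, tuning retest alpha =
#' 0.05, zero-count filter at 85%, pseudocount 0.001, log base 2,
#' backward-Wald removal alpha 0.10, drug screen >= 10 lines, binary
#' risk threshold 1.709.
#'
#' @param discovery,tuning,validation lists of cohorts; each cohort is a
#'   list with elements `expr` (path or [expr_matrix()]), `surv` (path or
#'   [survival_table()]), `unit` (unit tag of the expression file) and
#'   optionally `time_unit`.
#' @param k,min_cohorts,retest_alpha,zero_fraction,pseudocount,log_base,
#'   removal_alpha,min_lines,shi_threshold thresholds as above.
#' @param seed integer seed echoed into outputs.
#' @param out_dir directory for materialized intermediates (rank tables,
#'   candidate sets, signature, reports).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(discovery = list(), tuning = NULL,
                            validation = list(), k = 500L, min_cohorts = 2L,
                            retest_alpha = 0.05, zero_fraction = 0.85,
                            pseudocount = 0.001, log_base = 2,
                            removal_alpha = 0.10, min_lines = 10L,
                            shi_threshold = 1.709, seed = 1L,
                            out_dir = tempfile("pps20_run_")) {
  cfg <- list(discovery = discovery, tuning = tuning, validation = validation,
              k = as.integer(k), min_cohorts = as.integer(min_cohorts),
              retest_alpha = retest_alpha, zero_fraction = zero_fraction,
              pseudocount = pseudocount, log_base = log_base,
              removal_alpha = removal_alpha, min_lines = as.integer(min_lines),
              shi_threshold = shi_threshold, seed = as.integer(seed),
              out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

# Load one cohort entry: accepts in-memory objects or file paths, applies
# the count-cohort preprocessing (zero filter -> CPM -> log) when the
# input is raw counts; log-scale inputs pass through.
load_cohort <- function(entry, cfg) {
  expr <- entry$expr
  if (is.character(expr))
    expr <- read_expression(expr, unit = entry$unit %||% "counts")
  surv <- entry$surv
  if (is.character(surv))
    surv <- read_survival(surv, time_unit = entry$time_unit %||% "months")
  surv <- prepare_survival(surv)
  if (expr$unit == "counts") {
    expr <- filter_zero_genes(expr, cfg$zero_fraction)
    expr <- log_transform(compute_cpm(expr), pseudocount = cfg$pseudocount,
                          base = cfg$log_base)
  } else if (expr$unit == "cpm") {
    expr <- log_transform(expr, pseudocount = cfg$pseudocount,
                          base = cfg$log_base)
  }
  list(expr = expr, surv = surv)
}

#' Run signature discovery: screen, rank, intersect, retest
#'
#' Per discovery cohort: univariate Cox screen of every gene, ranksum
#' ranking, top-K selection. Genes in the top K of at least
#' `min_cohorts` cohorts become candidates and are retested in the
#' tuning cohort; those significant there form the signature, signed by
#' their tuning hazard direction (discovery-direction flips excluded).
#' Every intermediate is written under `config$out_dir` so the candidate
#' counts can be audited.
#'
#' @param config a [pipeline_config()] with >= `min_cohorts` discovery
#'   cohorts and one tuning cohort.
#' @return List of class `discovery_result`: `signature`, `rank_tables`
#'   (per cohort), `top_sets`, `candidates`.
#' @export
run_discover <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(config$discovery) < config$min_cohorts)
    pps_stop("pps_invalid_config_error",
             "need >= min_cohorts (%d) discovery cohorts, got %d",
             config$min_cohorts, length(config$discovery))
  if (is.null(config$tuning))
    pps_stop("pps_invalid_config_error", "a tuning cohort is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  names_d <- names(config$discovery) %||%
    paste0("discovery", seq_along(config$discovery))
  rank_tables <- list()
  top_sets <- list()
  sign_votes <- list()
  for (i in seq_along(config$discovery)) {
    co <- load_cohort(config$discovery[[i]], config)
    rt <- rank_genes(screen_genes(co$expr, co$surv))
    rank_tables[[names_d[i]]] <- rt
    write_rank_table(rt, file.path(config$out_dir,
                                   paste0("rank_", names_d[i], ".tsv")))
    top_sets[[names_d[i]]] <- top_k(rt, config$k)
    sign_votes[[i]] <- setNames(ifelse(rt$hr > 1, 1L, -1L), rt$gene_id)
  }
  candidates <- intersect_cohorts(top_sets, config$min_cohorts)
  writeLines(candidates, file.path(config$out_dir, "candidates.txt"))
  pps_log("run_discover: %d candidate genes in >= %d of %d top-%d sets",
          length(candidates), config$min_cohorts, length(top_sets), config$k)
  # consensus discovery direction: majority vote among cohorts ranking the gene
  votes <- sapply(candidates, function(g) {
    v <- unlist(lapply(sign_votes, function(s) s[g]))
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_integer_ else sign(sum(v))
  })
  tuning <- load_cohort(config$tuning, config)
  sig <- retest(candidates, tuning$expr, tuning$surv,
                alpha = config$retest_alpha,
                discovery_signs = votes[votes != 0],
                name = "discovered")
  sig$provenance <- c(sig$provenance,
                      list(k = config$k, min_cohorts = config$min_cohorts,
                           seed = config$seed))
  write_signature(sig, file.path(config$out_dir, "signature.tsv"))
  structure(list(signature = sig, rank_tables = rank_tables,
                 top_sets = top_sets, candidates = candidates),
            class = "discovery_result")
}

#' Evaluate a signature on validation cohorts
#'
#' Per cohort: compute the score, split at the cohort median, and report
#' Kaplan-Meier/log-rank and the group Cox hazard ratio; optionally a
#' multivariate backward-Wald fit with supplied covariate columns.
#'
#' @param config a [pipeline_config()] with validation cohorts.
#' @param signature a [pps_signature()].
#' @param covariates optional character vector naming survival-table
#'   covariate columns to include in a multivariate fit.
#' @return Named list per cohort: `scores`, `groups`, `km`
#'   (`km_logrank`), `cox` (`cox_group`) and optionally `mva`.
#' @export
run_evaluate <- function(config, signature, covariates = NULL) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(signature, "pps_signature"))
  if (length(config$validation) == 0L) {
    pps_warn("pps_empty_validation_warning", "no validation cohorts configured")
    return(list())
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  names_v <- names(config$validation) %||%
    paste0("validation", seq_along(config$validation))
  out <- list()
  for (i in seq_along(config$validation)) {
    co <- load_cohort(config$validation[[i]], config)
    m <- match_samples(co$expr, co$surv)
    scores <- compute_score(m$expr, signature)
    groups <- dichotomize(scores)
    km <- km_logrank(groups, m$surv)
    cox <- cox_univariate_group(groups, m$surv)
    res <- list(scores = scores, groups = groups, km = km, cox = cox)
    if (!is.null(covariates)) {
      cov_df <- as.data.frame(m$surv)[, intersect(covariates, colnames(m$surv)),
                                      drop = FALSE]
      cov_df$score_group <- as.integer(groups$group == "high")
      res$mva <- cox_backward_wald(cov_df, m$surv, config$removal_alpha)
    }
    write_km_curves(km, file.path(config$out_dir,
                                  paste0("km_", names_v[i], ".tsv")))
    out[[names_v[i]]] <- res
  }
  out
}
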