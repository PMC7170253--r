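#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the ingredients the pipeline needs from a real
#' bulk RNA-seq survival cohort: negative-binomial counts with
#' sample-to-sample library-size variation, a small set of "planted"
#' genes whose (standardized log-CPM) expression multiplicatively scales
#' the death hazard, exponential event times under that proportional
#' hazard, and independent uniform right-censoring tuned toward a target
#' censoring rate.
#'
#' Defaults describe a mid-sized pancreatic-cancer-like cohort: 1000
#' genes, 200 patients, 10 adverse + 10 favorable planted genes at
#' |beta| = 1 per SD of log expression, a baseline hazard of 0.04 per
#' month (median survival around 17 months under the null), and 35%
#' censoring.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param n_planted_adverse,n_planted_favorable numbers of planted genes
#'   with hazard-increasing (+) and hazard-decreasing (-) effects.
#' @param beta_magnitude |log-hazard| per unit standardized log-CPM.
#' @param baseline_hazard events per month for a sample at the planted
#'   genes' mean expression.
#' @param censor_rate_target desired fraction of censored samples, in
#'   `[0, 1)`.
#' @param nb_dispersion negative-binomial dispersion (1/size); 0.15 is a
#'   typical bulk RNA-seq value.
#' @param library_size_range pair of positive totals; per-sample library
#'   sizes are drawn log-normally centred inside this range and clamped
#'   to it.
#' @param seed integer RNG seed; identical configs give bit-identical
#'   cohorts.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 1000L, n_samples = 200L,
                             n_planted_adverse = 10L,
                             n_planted_favorable = 10L,
                             beta_magnitude = 1.0,
                             baseline_hazard = 0.04,
                             censor_rate_target = 0.35,
                             nb_dispersion = 0.15,
                             library_size_range = c(2e5, 2e6),
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              n_planted_adverse = as.integer(n_planted_adverse),
              n_planted_favorable = as.integer(n_planted_favorable),
              beta_magnitude = beta_magnitude,
              baseline_hazard = baseline_hazard,
              censor_rate_target = censor_rate_target,
              nb_dispersion = nb_dispersion,
              library_size_range = as.numeric(library_size_range),
              seed = as.integer(seed))
  if (cfg$n_genes < 1L || cfg$n_samples < 1L)
    pps_stop("pps_invalid_config_error", "need at least one gene and one sample")
  if (cfg$n_planted_adverse < 0L || cfg$n_planted_favorable < 0L)
    pps_stop("pps_invalid_config_error", "planted gene counts must be non-negative")
  if (cfg$n_planted_adverse + cfg$n_planted_favorable > cfg$n_genes)
    pps_stop("pps_invalid_config_error",
             "planted genes (%d) exceed n_genes (%d)",
             cfg$n_planted_adverse + cfg$n_planted_favorable, cfg$n_genes)
  if (cfg$censor_rate_target < 0 || cfg$censor_rate_target >= 1)
    pps_stop("pps_invalid_config_error", "censor_rate_target must be in [0, 1)")
  if (cfg$baseline_hazard <= 0 || cfg$nb_dispersion <= 0)
    pps_stop("pps_invalid_config_error",
             "baseline_hazard and nb_dispersion must be positive")
  if (length(cfg$library_size_range) != 2L ||
      any(cfg$library_size_range <= 0) ||
      diff(cfg$library_size_range) < 0)
    pps_stop("pps_invalid_config_error",
             "library_size_range must be an increasing pair of positive numbers")
  class(cfg) <- "synthetic_config"
  cfg
}

# Uniform-censoring cap solved so that the expected censored fraction,
# given the realized event times, matches the target: with C ~ U(0, M),
# P(censor sample i) = P(C < t_i) = min(t_i, M) / M.
solve_censor_cap <- function(event_times, target) {
  if (target <= 0) return(Inf)
  f <- function(M) mean(pmin(event_times, M) / M) - target
  # f decreases from 1 - target (M -> 0) towards -target (M -> Inf)
  hi <- max(event_times) * 2
  while (f(hi) > 0 && hi < max(event_times) * 1e8) hi <- hi * 10
  if (f(hi) > 0) return(hi)
  uniroot(f, lower = min(event_times) * 1e-6, upper = hi,
          tol = 1e-8)$root
}

#' Generate one synthetic survival cohort
#'
#' @param config a [synthetic_config()].
#' @param seed optional seed overriding `config$seed` (used by
#'   [generate_multi_cohorts()] to vary samples while keeping the planted
#'   gene identities fixed).
#' @return A list with elements `expr` (counts [expr_matrix()]), `surv`
#'   (a [survival_table()] in months) and `truth` (planted gene table,
#'   config, seed).
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  n_planted <- config$n_planted_adverse + config$n_planted_favorable
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  samples <- sprintf("S%03d", seq_len(config$n_samples))
  # Planted gene identities depend only on config$seed so that cohorts
  # generated with per-cohort sample seeds share the same truth.
  planted <- with_seed(config$seed, {
    idx <- sample.int(config$n_genes, n_planted)
    sign <- rep(c(1L, -1L),
                c(config$n_planted_adverse, config$n_planted_favorable))
    # per-gene relative abundance on a log-normal scale (sdlog ~ 1.2 gives
    # the usual several-orders-of-magnitude spread of bulk expression)
    abund <- rlnorm(config$n_genes, meanlog = 0, sdlog = 1.2)
    list(idx = idx, sign = sign, abund = abund / sum(abund))
  })
  with_seed(seed, {
    lsr <- log(config$library_size_range)
    libsize <- exp(pmin(pmax(rnorm(config$n_samples, mean = mean(lsr),
                                   sd = diff(lsr) / 4), lsr[1]), lsr[2]))
    mu <- outer(planted$abund, libsize)   # expected counts
    counts <- matrix(rnbinom(length(mu), mu = mu,
                             size = 1 / config$nb_dispersion),
                     nrow = config$n_genes,
                     dimnames = list(genes, samples))
    expr <- expr_matrix(counts, "counts")
    # hazard acts on standardized log-CPM of the planted genes
    logcpm <- suppressMessages(
      log_transform(compute_cpm(expr))$values)
    lp <- numeric(config$n_samples)
    beta <- numeric(0)
    if (n_planted > 0L) {
      z <- logcpm[planted$idx, , drop = FALSE]
      zsd <- apply(z, 1L, sd)
      zsd[zsd == 0] <- 1        # constant planted gene carries no signal
      z <- (z - rowMeans(z)) / zsd
      beta <- planted$sign * config$beta_magnitude
      lp <- as.vector(crossprod(z, beta))
    }
    hazard <- config$baseline_hazard * exp(lp)
    t_event <- rexp(config$n_samples, rate = hazard)
    cap <- solve_censor_cap(t_event, config$censor_rate_target)
    t_cens <- if (is.finite(cap)) runif(config$n_samples, 0, cap)
              else rep(Inf, config$n_samples)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    truth <- list(
      planted_genes = if (n_planted > 0L)
        data.frame(gene_id = genes[planted$idx], sign = planted$sign,
                   beta = beta, stringsAsFactors = FALSE)
      else data.frame(gene_id = character(0), sign = integer(0),
                      beta = numeric(0)),
      seed = as.integer(seed), config = config)
    class(truth) <- "synthetic_truth"
    list(expr = expr,
         surv = survival_table(samples, time, event, "months"),
         truth = truth)
  })
}

#' Generate several cohorts sharing the same planted genes
#'
#' Discovery designs need independent cohorts that agree on which genes
#' are prognostic; planted identities and signs come from
#' `config$seed` while per-cohort sampling uses `cohort_seeds`.
#'
#' @param config a [synthetic_config()].
#' @param n_cohorts number of cohorts, >= 1.
#' @param cohort_seeds integer vector of length `n_cohorts`.
#' @return List of cohort lists as returned by [generate_cohort()].
#' @export
generate_multi_cohorts <- function(config, n_cohorts,
                                   cohort_seeds = config$seed + seq_len(n_cohorts)) {
  stopifnot(inherits(config, "synthetic_config"))
  if (n_cohorts < 1L)
    pps_stop("pps_invalid_config_error", "n_cohorts must be >= 1")
  if (length(cohort_seeds) != n_cohorts)
    pps_stop("pps_invalid_config_error",
             "cohort_seeds must have length n_cohorts (%d)", n_cohorts)
  lapply(cohort_seeds, function(s) generate_cohort(config, seed = s))
}

#' Generate a synthetic cell-line expression + drug-response panel
#'
#' Per-line log-scale expression is drawn for every signature gene (plus
#' background genes); each line's signature score is computed, and for
#' drugs named in `effect_map` the area-under-curve response is
#' `intercept + slope * score + N(0, noise_sd)`. All other drugs' AUC is
#' independent of the score. A fraction of (line, drug) cells is set
#' missing, mirroring incomplete screens.
#'
#' @param signature a [pps_signature()] object.
#' @param n_lines number of cell lines (>= 3; correlation is undefined
#'   below 3 points).
#' @param n_drugs number of compounds.
#' @param effect_map data.frame with columns `drug_id`, `slope` (AUC
#'   units per score unit); may be empty for a pure null panel.
#' @param noise_sd Gaussian noise SD on AUC; default 0.5.
#' @param seed RNG seed.
#' @param missing_fraction fraction of AUC cells set to NA; default 0.1.
#' @param auc_intercept mean AUC of an average line; default 12 (AUC
#'   scale of 16-point concentration curves).
#' @return List with `expr` ([expr_matrix()], unit `"array_log"`),
#'   `auc` (a [drug_response_table()]) and `truth`.
#' @export
generate_cellline_panel <- function(signature, n_lines, n_drugs,
                                    effect_map = data.frame(drug_id = character(0),
                                                            slope = numeric(0)),
                                    noise_sd = 0.5, seed = 1L,
                                    missing_fraction = 0.1,
                                    auc_intercept = 12) {
  stopifnot(inherits(signature, "pps_signature"))
  if (n_lines < 3L)
    pps_stop("pps_too_few_lines_error",
             "need >= 3 cell lines for correlation, got %d", n_lines)
  drugs <- sprintf("D%03d", seq_len(n_drugs))
  if (!all(effect_map$drug_id %in% drugs))
    pps_stop("pps_invalid_config_error",
             "effect_map names drugs outside the generated panel")
  with_seed(seed, {
    lines <- sprintf("CL%02d", seq_len(n_lines))
    genes <- c(signature$entries$gene,
               sprintf("BG%03d", seq_len(50L)))
    vals <- matrix(rnorm(length(genes) * n_lines, mean = 5, sd = 1),
                   nrow = length(genes), dimnames = list(genes, lines))
    expr <- expr_matrix(vals, "array_log")
    score <- suppressMessages(compute_score(expr, signature))$score
    auc <- matrix(rnorm(n_lines * n_drugs, mean = auc_intercept, sd = 1),
                  nrow = n_lines, dimnames = list(lines, drugs))
    for (i in seq_len(nrow(effect_map))) {
      d <- effect_map$drug_id[i]
      auc[, d] <- auc_intercept + effect_map$slope[i] * score +
        rnorm(n_lines, sd = noise_sd)
    }
    if (missing_fraction > 0) {
      nmiss <- floor(missing_fraction * length(auc))
      # never blank effect-map drugs below 3 observations
      auc[sample(which(!is.na(auc)), nmiss)] <- NA
      for (d in effect_map$drug_id)
        if (sum(!is.na(auc[, d])) < 3L) auc[, d] <- auc_intercept +
            effect_map$slope[match(d, effect_map$drug_id)] * score
    }
    truth <- list(effect_map = effect_map, seed = as.integer(seed),
                  score = setNames(score, lines))
    class(truth) <- "synthetic_truth"
    list(expr = expr,
         auc = drug_response_table(auc, n_concentrations = rep(16L, n_drugs)),
         truth = truth)
  })
}

#' Write a synthetic cohort to disk in pipeline-ready formats
#'
#' Counts and survival go to the same delimited formats the readers
#' consume; the planted-gene truth goes to a JSON sidecar.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix, default `"cohort"`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, paste0(prefix, "_counts.tsv")),
    survival = file.path(dir, paste0(prefix, "_survival.tsv")),
    truth = file.path(dir, paste0(prefix, "_truth.json")))
  write_expression(cohort$expr, paths[["counts"]])
  write_survival(cohort$surv, paths[["survival"]])
  truth <- cohort$truth
  jsonlite::write_json(
    list(planted_genes = truth$planted_genes, seed = truth$seed,
         config = unclass(truth$config)),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
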