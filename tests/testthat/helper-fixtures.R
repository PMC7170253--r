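# Small in-code fixtures shared across test files.

make_expr <- function(values, unit = "log_cpm") {
  if (is.null(dimnames(values)))
    dimnames(values) <- list(sprintf("g%d", seq_len(nrow(values))),
                             sprintf("s%d", seq_len(ncol(values))))
  expr_matrix(values, unit)
}

make_surv <- function(time, event, ids = sprintf("s%d", seq_along(time)),
                      unit = "months", covariates = NULL) {
  survival_table(ids, time, event, unit, covariates = covariates)
}

# A deterministic small cohort with a strong single prognostic gene:
# gene g1 doubles the hazard per unit, the rest are noise.
tiny_cohort <- function(n = 60, seed = 42) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    x <- matrix(rnorm(5 * n), nrow = 5,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:n)))
    haz <- 0.05 * exp(0.9 * x[1, ])
    t_ev <- rexp(n, haz)
    t_c <- runif(n, 0, quantile(t_ev, 0.9))
    list(expr = expr_matrix(x, "log_cpm"),
         surv = make_surv(pmin(t_ev, t_c), as.integer(t_ev <= t_c),
                          ids = paste0("s", 1:n)))
  })
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
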