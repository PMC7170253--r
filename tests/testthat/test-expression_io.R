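test_that("read_expression round-trips a written matrix and preserves order", {
  m <- matrix(c(1.5, 0, 3, 2, 4.25, 7), nrow = 3,
              dimnames = list(c("TP53", "KRAS", "MYC"), c("a", "b")))
  em <- expr_matrix(m, "cpm")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(em, path)
  back <- read_expression(path, unit = "cpm")
  expect_equal(back$values, em$values)
  expect_identical(gene_ids(back), c("TP53", "KRAS", "MYC"))
  expect_identical(back$unit, "cpm")
})

test_that("read_expression rejects duplicate sample headers and empty files", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts1", "g1\t1\t2"), path)
  expect_error(read_expression(path, unit = "counts"),
               class = "pps_format_error")
  err <- tryCatch(read_expression(path, unit = "counts"), error = identity)
  expect_match(conditionMessage(err), "s1")
  writeLines("gene", path)
  expect_error(read_expression(path, unit = "counts"),
               class = "pps_format_error")
})

test_that("expr_matrix enforces unit and uniqueness invariants", {
  m <- matrix(c(1, -2, 3, 4), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(expr_matrix(m, "counts"), class = "pps_format_error") # negative
  m2 <- abs(m)
  rownames(m2) <- c("g1", "g1")
  expect_error(expr_matrix(m2, "counts"), class = "pps_format_error") # dup gene
})

test_that("compute_cpm matches per-column division and sums to 1e6", {
  m <- matrix(c(2, 2, 0, 6, 1, 3, 5, 10, 15, 1, 2, 3, 0, 0, 9), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  cpm <- compute_cpm(expr_matrix(m, "counts"))
  # independent per-column oracle
  expect_equal(cpm$values, apply(m, 2, function(col) col / sum(col) * 1e6),
               tolerance = 0)
  expect_equal(unname(colSums(cpm$values)), rep(1e6, 3), tolerance = 1e-6)
  # the printed two-gene example: counts (2, 2) -> (500000, 500000)
  two <- compute_cpm(make_expr(matrix(c(2, 2), 2, 1,
                                      dimnames = list(c("a", "b"), "s")),
                               "counts"))
  expect_equal(unname(two$values[, 1]), c(5e5, 5e5))
  expect_error(compute_cpm(make_expr(matrix(0, 2, 1,
                                            dimnames = list(c("a", "b"), "sX")),
                                     "counts")),
               class = "pps_degenerate_sample_error")
})

test_that("log_transform applies log2(x + 0.001) by default", {
  m <- make_expr(matrix(c(1.999, 0, 7.999, 1), 2, 2), "cpm")
  lg <- log_transform(m)
  expect_equal(lg$values[1, 1], 1)                  # log2(2)
  expect_equal(lg$values[2, 1], log2(0.001))        # zero input
  expect_equal(lg$values[1, 2], 3)                  # log2(8)
  expect_identical(lg$unit, "log_cpm")
  expect_error(log_transform(make_expr(matrix(-1, 1, 1), "cpm")),
               class = "pps_domain_error")
  expect_error(log_transform(lg), class = "pps_unit_error")
})

test_that("filter_zero_genes removes strictly above the threshold and is idempotent", {
  n <- 20
  m <- rbind(
    g_removed = c(rep(0, 18), 5, 5),   # 90% zeros -> out
    g_boundary = c(rep(0, 17), 1, 2, 3), # exactly 85% -> kept
    g_dense = seq_len(n))
  colnames(m) <- paste0("s", 1:n)
  f <- quiet(filter_zero_genes(expr_matrix(m, "counts")))
  expect_identical(gene_ids(f), c("g_boundary", "g_dense"))
  expect_identical(f$removed, "g_removed")
  f2 <- quiet(filter_zero_genes(f))
  expect_equal(f2$values, f$values)
  expect_length(f2$removed, 0)
})

test_that("collapse_probes averages probe rows and preserves samples", {
  m <- matrix(c(2, 4, 10, 1, 3, 20), nrow = 3,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  map <- c(p1 = "GENEA", p2 = "GENEA", p3 = "GENEB")
  out <- quiet(collapse_probes(expr_matrix(m, "array_log"), map))
  expect_equal(out$values["GENEA", ], c(s1 = 3, s2 = 2))   # mean(2,4), mean(1,3)
  expect_equal(out$values["GENEB", ], c(s1 = 10, s2 = 20)) # single probe
  expect_identical(sample_ids(out), c("s1", "s2"))
  # 3-probe mean against direct recomputation
  m3 <- matrix(rnorm(9), 3, dimnames = list(paste0("q", 1:3), paste0("s", 1:3)))
  out3 <- quiet(collapse_probes(expr_matrix(m3, "array_log"),
                                c(q1 = "G", q2 = "G", q3 = "G")))
  expect_equal(unname(out3$values["G", ]), unname(colMeans(m3)))
  expect_error(collapse_probes(expr_matrix(m, "array_log"), character(0)),
               class = "pps_mapping_error")
})

test_that("prepare_survival drops zero times and converts days to months", {
  st <- make_surv(c(90, 0, 45), c(1, 1, 0), unit = "days")
  out <- quiet(prepare_survival(st, to_months = TRUE))
  expect_equal(out$time, c(3, 1.5))
  expect_identical(attr(out, "time_unit"), "months")
  # months-in, conversion off: unchanged
  st2 <- make_surv(c(5, 10), c(1, 0))
  expect_equal(prepare_survival(st2)$time, c(5, 10))
  expect_error(quiet(prepare_survival(make_surv(0, 1))),
               class = "pps_empty_cohort_error")
})
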