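mk_groups <- function(ids, groups, scores = seq_along(ids)) {
  out <- data.frame(sample_id = ids, score = scores,
                    group = factor(groups, levels = c("low", "high")),
                    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- 0; attr(out, "cutoff_rule") <- "median"
  class(out) <- c("group_assignment", "data.frame")
  out
}

test_that("km_logrank matches the hand-computed log-rank oracle", {
  # 8-sample worked fixture, two groups of 4
  time <- c(3, 5, 7, 9, 2, 4, 6, 12)
  event <- c(1, 1, 0, 1, 1, 1, 1, 0)
  grp <- rep(c("low", "high"), each = 4)
  ids <- paste0("s", 1:8)
  km <- km_logrank(mk_groups(ids, grp), make_surv(time, event, ids = ids))
  oracle <- oracle_logrank(time, event, grp)
  expect_equal(km$chisq, oracle$chisq, tolerance = 1e-8)
  expect_equal(km$p, oracle$p, tolerance = 1e-8)
})

test_that("identical groups give statistic 0 and p 1", {
  time <- rep(c(2, 4, 6, 8), 2)
  event <- rep(c(1, 1, 0, 1), 2)
  ids <- paste0("s", 1:8)
  km <- km_logrank(mk_groups(ids, rep(c("low", "high"), each = 4)),
                   make_surv(time, event, ids = ids))
  expect_equal(km$chisq, 0, tolerance = 1e-12)
  expect_equal(km$p, 1, tolerance = 1e-12)
})

test_that("KM estimates are valid step functions; no censoring = empirical survival", {
  time <- c(1, 3, 3, 7, 9, 11)
  ids <- paste0("s", 1:6)
  km <- km_logrank(mk_groups(ids, c("low", "low", "low", "high", "high", "high")),
                   make_surv(time, rep(1, 6), ids = ids))
  for (g in c("low", "high")) {
    cv <- km$curves[km$curves$group == g, ]
    expect_true(all(diff(cv$surv) <= 1e-12))
    expect_true(all(cv$surv >= 0 & cv$surv <= 1))
  }
  emp <- oracle_km(time[1:3], rep(1, 3))
  low <- km$curves[km$curves$group == "low", ]
  expect_equal(setNames(low$surv, low$time), emp)
})

test_that("cox_univariate_group reports the high-vs-low hazard ratio", {
  time <- c(2, 4, 4, 5, 7, 8, 9, 9, 11, 13)
  event <- c(1, 1, 1, 0, 1, 1, 0, 1, 1, 1)
  grp <- c("high", "high", "low", "high", "low",
           "high", "low", "high", "low", "low")
  ids <- paste0("s", 1:10)
  r <- cox_univariate_group(mk_groups(ids, grp),
                            make_surv(time, event, ids = ids))
  b <- oracle_cox_coef(time, event, as.integer(grp == "high"))
  expect_equal(log(r$hr), b, tolerance = 1e-6)
  # label swap inverts the HR
  swapped <- ifelse(grp == "high", "low", "high")
  r2 <- cox_univariate_group(mk_groups(ids, swapped),
                             make_surv(time, event, ids = ids))
  expect_equal(r$hr, 1 / r2$hr, tolerance = 1e-8)
  # identical survival in both groups -> HR = 1 by symmetry
  t2 <- rep(c(1, 2, 3, 4), 2); e2 <- rep(1, 8)
  r3 <- cox_univariate_group(mk_groups(ids[1:8], rep(c("low", "high"), each = 4)),
                             make_surv(t2, e2, ids = ids[1:8]))
  expect_equal(log(r3$hr), 0, tolerance = 1e-8)
  expect_gt(r3$p, 0.99)
})

test_that("cox_backward_wald removes noise covariates and keeps the signal", {
  set.seed(123)
  n <- 250
  true_x <- rnorm(n)
  noise1 <- rnorm(n); noise2 <- rnorm(n)
  t_ev <- rexp(n, rate = 0.1 * exp(0.9 * true_x))
  t_c <- runif(n, 0, quantile(t_ev, 0.8))
  sv <- make_surv(pmin(t_ev, t_c), as.integer(t_ev <= t_c),
                  ids = sprintf("s%03d", 1:n))
  covs <- data.frame(true_x = true_x, noise1 = noise1, noise2 = noise2)
  rep_ <- cox_backward_wald(covs, sv)
  expect_identical(rep_$final$covariate, "true_x")
  expect_setequal(rep_$removed, c("noise1", "noise2"))
  # step history strictly decreases in covariate count
  expect_equal(vapply(rep_$steps, nrow, 0L),
               seq(3L, by = -1L, length.out = length(rep_$steps)))
  # removal order follows descending initial Wald p on independent covariates
  p1 <- setNames(rep_$steps[[1]]$p, rep_$steps[[1]]$covariate)
  expect_identical(rep_$removed[1],
                   names(which.max(p1[c("noise1", "noise2")])))
  # removal_alpha = 1 removes nothing beyond a boundary step
  rep_all <- cox_backward_wald(covs, sv, removal_alpha = 1.0000001)
  expect_equal(nrow(rep_all$final), 3)
  expect_length(rep_all$removed, 0)
})

test_that("filter_univariate_significant screens covariates for the MVA", {
  set.seed(19)
  n <- 200
  x <- rnorm(n)
  t_ev <- rexp(n, 0.1 * exp(x))
  sv <- make_surv(t_ev, rep(1L, n), ids = sprintf("s%03d", 1:n))
  sel <- quiet(filter_univariate_significant(
    data.frame(x = x, junk = rnorm(n)), sv))
  expect_true("x" %in% sel)
  expect_false("junk" %in% sel)
})

test_that("two_group_tests matches the closed-form Welch oracle", {
  x <- c(4.1, 5.2, 3.3, 6.8, 5.5, 4.9)
  y <- c(7.2, 8.1, 6.9, 9.3)
  r <- two_group_tests(x, y)
  o <- oracle_welch(x, y)
  expect_equal(r$statistic, o$statistic, tolerance = 1e-10)
  expect_equal(r$p, o$p, tolerance = 1e-10)
  # identical groups: t = 0, p = 1
  r0 <- two_group_tests(x, x)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  # paired with constant difference: degenerate
  rp <- two_group_tests(x, x + 2, paired = TRUE)
  expect_true(rp$degenerate)
  # paired matches t.test on differences
  y2 <- x + c(0.5, -0.2, 0.9, 0.1, -0.4, 0.6)
  rp2 <- two_group_tests(x, y2, paired = TRUE)
  expect_equal(rp2$p, t.test(x - y2)$p.value, tolerance = 1e-12)
  expect_error(two_group_tests(1, y), class = "pps_sample_size_error")
  expect_error(two_group_tests(x[1:3], y, paired = TRUE),
               class = "pps_format_error")
})

test_that("chisq_yates matches the closed-form corrected statistic", {
  flat <- matrix(c(5, 5, 5, 5), 2)
  r <- chisq_yates(flat)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  tab <- matrix(c(10, 20, 10, 5), 2)    # [[10,10],[20,5]] in row form
  r2 <- chisq_yates(tab)
  expect_equal(r2$statistic, oracle_yates(tab), tolerance = 1e-12)
  expect_equal(r2$df, 1)
  # transpose invariance
  expect_equal(chisq_yates(t(tab))$statistic, r2$statistic)
  expect_error(chisq_yates(matrix(c(0, 0, 3, 4), 2)),
               class = "pps_undefined_test_error")
  expect_error(chisq_yates(matrix(1, 3, 3)),
               class = "pps_invalid_parameter_error")
})
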