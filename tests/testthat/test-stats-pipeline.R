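test_that("summary t-test reproduces published p-values from group tables", {
  # control vs disease tortuosity
  r <- t_test_from_summary(c(70.80, 4.05, 53), c(72.43, 3.58, 58), "pooled")
  expect_equal(r$p_two_sided, 0.0266, tolerance = 0.0015 / 0.0266)
  expect_equal(r$df, 109)
  # stage-3 tortuosity vs control
  r <- t_test_from_summary(c(74.91, 3.42, 12), c(70.80, 4.05, 53), "pooled")
  expect_equal(r$p_two_sided, 0.0018, tolerance = 0.0010 / 0.0018)
})

test_that("summary t-test symmetry, degeneracy and Welch df", {
  a <- c(10, 2, 20); b <- c(12, 3, 25)
  expect_equal(t_test_from_summary(a, b)$p_two_sided,
               t_test_from_summary(b, a)$p_two_sided)
  same <- t_test_from_summary(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_two_sided, 1)
  expect_equal(t_test_from_summary(c(1, 0, 5), c(1, 0, 5))$p_two_sided, 1)
  expect_equal(t_test_from_summary(c(1, 0, 5), c(2, 0, 5))$p_two_sided, 0)
  w <- t_test_from_summary(a, b, "welch")
  expect_lt(w$df, a[3] + b[3] - 2)
  # cross-check against t.test on raw data with matching summaries
  set.seed(9)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  mine <- t_test_from_summary(c(mean(x), sd(x), 20), c(mean(y), sd(y), 25),
                              "welch")
  ref <- t.test(x, y)
  expect_equal(mine$p_two_sided, ref$p.value, tolerance = 1e-10)
})

test_that("normality gate levels match simulation under H0 and exponential", {
  n_par <- 0; n_nonpar <- 0
  for (s in 1:100) {
    set.seed(s)
    if (normality_gate(rnorm(50), rnorm(50)) == "parametric")
      n_par <- n_par + 1
    if (normality_gate(rexp(50), rexp(50)) == "nonparametric")
      n_nonpar <- n_nonpar + 1
  }
  expect_gte(n_par, 90)
  expect_gte(n_nonpar, 95)
  # degenerate inputs
  expect_equal(normality_gate(rep(1, 10), rnorm(10)), "nonparametric")
  expect_equal(normality_gate(c(1, 2), rnorm(10)), "nonparametric")
})

test_that("exact Mann-Whitney p equals full enumeration", {
  expect_equal(rank_test(c(1, 2, 3), c(4, 5, 6))$p_two_sided, 0.1)
  set.seed(11)
  for (i in 1:6) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    x <- rnorm(nx); y <- rnorm(ny, 0.8)
    expect_equal(rank_test(x, y)$p_two_sided, mw_enumeration_p(x, y),
                 tolerance = 1e-12, label = sprintf("sizes %d/%d", nx, ny))
  }
})

test_that("multi-group tests handle ties and degenerate inputs", {
  same <- multi_group_test(list(rep(1, 5), rep(1, 5), rep(1, 5)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_two_sided, 1)
  set.seed(2)
  gs <- list(rnorm(20), rnorm(20), rnorm(20, 2))
  a <- multi_group_test(gs, gate = "anova")
  expect_lt(a$p_two_sided, 0.01)
  k <- multi_group_test(gs, gate = "kruskal")
  expect_lt(k$p_two_sided, 0.01)
})

test_that("chi-square (no continuity correction) matches closed form", {
  r <- chi_square_2x2(matrix(c(11, 13, 19, 30), 2))
  expect_equal(r$p_two_sided, 0.5648, tolerance = 0.0005 / 0.5648)
  flat <- chi_square_2x2(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_two_sided, 1)
  diagt <- matrix(c(5, 0, 0, 5), 2)
  r2 <- chi_square_2x2(diagt)
  expect_equal(r2$statistic, 10)
  expect_equal(r2$statistic, chi2_closed_form(diagt))
  expect_equal(r2$p_two_sided, 0.00157, tolerance = 1e-2)
  set.seed(3)
  for (i in 1:5) {
    tb <- matrix(rpois(4, 20) + 1, 2)
    expect_equal(chi_square_2x2(tb)$statistic, chi2_closed_form(tb))
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("ordinal fit recovers a known coefficient at n = 2000", {
  beta_true <- log(1.75)
  co <- make_ordinal_cohort(beta_true, c(-1, 1), 2000, seed = 11)
  fit <- fit_ordinal_logistic(co, "x1")
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[["x1"]] - beta_true), 0.10)
  expect_true(fit$ci_lower[["x1"]] < 1.75 && 1.75 < fit$ci_upper[["x1"]])
  # log-likelihood never decreased across Newton iterations
  expect_true(all(diff(fit$log_lik_trace) >= -1e-9))
  # thresholds strictly increasing, CI brackets the aOR
  expect_true(all(diff(fit$zeta) > 0))
  expect_true(fit$ci_lower[["x1"]] < fit$aor[["x1"]])
  expect_true(fit$aor[["x1"]] < fit$ci_upper[["x1"]])
})

test_that("ordinal fit agrees with the reference polr implementation", {
  skip_if_not_installed("MASS")
  co <- make_ordinal_cohort(c(0.6, -0.4), c(-0.5, 0.8), 800, seed = 13)
  fit <- fit_ordinal_logistic(co, c("x1", "x2"))
  ref <- MASS::polr(factor(stage, ordered = TRUE) ~ x1 + x2, data = co,
                    Hess = TRUE)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(unname(fit$zeta), unname(ref$zeta), tolerance = 1e-4)
  se_ref <- sqrt(diag(vcov(ref)))[1:2]
  expect_equal(unname(fit$se), unname(se_ref), tolerance = 1e-3)
})

test_that("two-level ordinal fit collapses to binary logistic regression", {
  set.seed(17)
  x <- rnorm(300)
  y <- rbinom(300, 1, plogis(0.8 * x - 0.2)) + 1L
  fit <- fit_ordinal_logistic(data.frame(x1 = x, stage = y), "x1")
  ref <- glm(I(y == 2) ~ x, family = binomial())
  expect_equal(fit$coefficients[["x1"]], unname(coef(ref)[2]),
               tolerance = 1e-5)
  expect_equal(fit$zeta, -unname(coef(ref)[1]), tolerance = 1e-5)
})

test_that("the cohort battery finds the published group differences", {
  co <- make_cohort(seed = 42)
  out <- run_table_battery(co)
  # control-vs-disease tortuosity contrast present and two-sided
  pw <- out$pairwise
  expect_true(all(pw$p >= 0 & pw$p <= 1))
  vt_cf <- pw[pw$metric == "vt" & pw$group_a == "control" &
                pw$group_b == "fevr", ]
  expect_equal(nrow(vt_cf), 1L)
  # the ordinal fit used only disease stages
  expect_false(is.null(out$ordinal))
  expect_equal(out$ordinal$n_levels, 3L)
  expect_equal(out$ordinal$n, 58L)
  expect_equal(unname(out$pct_increase),
               unname(100 * out$ordinal$coefficients))
  # width is the dominant stage predictor in this design
  expect_lt(out$ordinal$p_wald[["vw_um"]], 0.05)
})

test_that("battery on a single group yields no comparisons", {
  co <- make_cohort(seed = 1)
  co <- co[co$stage == 0, ]
  co$stage <- 0
  out <- run_table_battery(co[, ])
  expect_null(out$ordinal)
})

test_that("battery p-values are calibrated under a null cohort", {
  # all groups drawn from one distribution: ~5% of pairwise contrasts
  # significant across seeds
  set.seed(5)
  ps <- c()
  for (s in 1:30) {
    def <- cohort_spec()
    def$groups$vt_mean <- 70; def$groups$vt_sd <- 4
    def$groups$vw_mean <- 64; def$groups$vw_sd <- 3
    def$groups$vd_mean <- 5; def$groups$vd_sd <- 1
    out <- run_table_battery(make_cohort(def, seed = 9000 + s))
    ps <- c(ps, out$pairwise$p)
  }
  expect_equal(mean(ps < 0.05), 0.05, tolerance = 0.5)
  expect_gt(mean(ps), 0.3)   # roughly uniform p-values
})
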