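# Statistical battery: summary-statistics t-tests, normality-gated
# two-group and multi-group comparisons, chi-square, and a proportional-
# odds (cumulative logit) ordinal regression of disease stage on the
# vascular metrics with demographic covariates.

.test_result <- function(test_name, statistic, df, p) {
  structure(list(test_name = test_name, statistic = statistic,
                 df = df, p_two_sided = p), class = "peridisc_test")
}

#' @export
print.peridisc_test <- function(x, ...) {
  cat(sprintf("<%s: statistic %.4g, df %s, p = %.4g>\n", x$test_name,
              x$statistic, paste(signif(x$df, 4), collapse = ","),
              x$p_two_sided))
  invisible(x)
}

#' Two-sample t-test from group summaries
#'
#' Unpaired t-test computed from (mean, sd, n) per group, as needed to
#' reproduce published comparisons from summary tables. The pooled variant
#' is the classical Student test with `df = n_a + n_b - 2`; Welch is
#' available by flag.
#'
#' @param a,b lists or vectors with `mean`, `sd`, `n`.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A test result with `statistic`, `df`, `p_two_sided`.
#' @export
t_test_from_summary <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- as.list(a); b <- as.list(b)
  names(a)[1:3] <- names(b)[1:3] <- c("mean", "sd", "n")
  stopifnot(a$n >= 2, b$n >= 2)
  if (a$sd == 0 && b$sd == 0) {
    p <- if (a$mean == b$mean) 1 else 0
    return(.test_result(paste0(variant, "_t"),
                        if (p == 1) 0 else Inf, a$n + b$n - 2, p))
  }
  if (variant == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- (a$mean - b$mean) / se
  .test_result(paste0(variant, "_t"), t, df, 2 * pt(-abs(t), df))
}

#' Choose parametric vs nonparametric two-group testing
#'
#' Both samples must pass a Shapiro-Wilk normality test for the parametric
#' branch; `alpha` is split across the two samples (Bonferroni) so the
#' overall level of the joint normality decision stays near `alpha`.
#' Degenerate samples (n < 3 or near-constant) fall back to nonparametric.
#'
#' @param x,y numeric samples.
#' @param alpha overall level of the normality decision.
#' @return `"parametric"` or `"nonparametric"`.
#' @export
normality_gate <- function(x, y, alpha = 0.05) {
  ok <- function(v) {
    if (length(v) < 3 || length(unique(v)) < 3) return(FALSE)
    stats::shapiro.test(v)$p.value > alpha / 2
  }
  if (ok(x) && ok(y)) "parametric" else "nonparametric"
}

#' Wilcoxon-Mann-Whitney two-sample test
#'
#' Exact when both groups have at most `exact_max` observations and there
#' are no ties; otherwise the normal approximation with tie correction (no
#' continuity correction).
#'
#' @param x,y numeric samples.
#' @param exact_max largest per-group size for the exact distribution.
#' @return A test result (W statistic, p).
#' @export
rank_test <- function(x, y, exact_max = 8) {
  if (length(unique(c(x, y))) == 1L)
    return(.test_result("wilcoxon_mw", length(x) * length(y) / 2, NA_real_, 1))
  use_exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = FALSE))
  .test_result("wilcoxon_mw", unname(wt$statistic), NA_real_, wt$p.value)
}

#' Two-group comparison with the normality gate
#'
#' Unpaired t-test when both samples look Gaussian, otherwise
#' Wilcoxon-Mann-Whitney.
#'
#' @param x,y numeric samples.
#' @param alpha normality-test level.
#' @param variant t-test flavor when parametric, see [t_test_from_summary].
#' @return A test result.
#' @export
two_group_test <- function(x, y, alpha = 0.05, variant = "pooled") {
  if (normality_gate(x, y, alpha) == "parametric") {
    t_test_from_summary(list(mean = mean(x), sd = sd(x), n = length(x)),
                        list(mean = mean(y), sd = sd(y), n = length(y)),
                        variant = variant)
  } else {
    rank_test(x, y)
  }
}

#' Multi-group comparison (one-way ANOVA or Kruskal-Wallis)
#'
#' One-way ANOVA (equal-variance F test) when every group passes the
#' normality check, Kruskal-Wallis otherwise, mirroring the two-group gate.
#'
#' @param groups list of numeric vectors (>= 3 groups).
#' @param gate `"auto"`, `"anova"` or `"kruskal"`.
#' @return A test result.
#' @export
multi_group_test <- function(groups, gate = c("auto", "anova", "kruskal")) {
  gate <- match.arg(gate)
  stopifnot(length(groups) >= 3)
  vals <- unlist(groups)
  if (length(unique(vals)) == 1L)
    return(.test_result("kruskal_wallis", 0, length(groups) - 1, 1))
  if (gate == "auto") {
    normal <- all(vapply(groups, function(g)
      length(g) >= 3 && length(unique(g)) >= 3 &&
        stats::shapiro.test(g)$p.value > 0.05, logical(1)))
    gate <- if (normal) "anova" else "kruskal"
  }
  f <- factor(rep(seq_along(groups), lengths(groups)))
  if (gate == "anova") {
    ow <- stats::oneway.test(vals ~ f, var.equal = TRUE)
    .test_result("anova", unname(ow$statistic), unname(ow$parameter),
                 ow$p.value)
  } else {
    kw <- stats::kruskal.test(vals, f)
    .test_result("kruskal_wallis", unname(kw$statistic),
                 unname(kw$parameter), kw$p.value)
  }
}

#' Pearson chi-square test on a 2x2 table (no continuity correction)
#'
#' @param table 2x2 matrix of counts.
#' @return A test result (`statistic` is the Pearson chi-square, df = 1).
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi-square undefined: zero margin")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  .test_result("chi_square", unname(ct$statistic), 1, ct$p.value)
}

# ---- proportional-odds (cumulative logit) regression ---------------------

# Parameterization: P(Y <= k | x) = plogis(theta_k - x beta), theta
# unconstrained but kept increasing by step-halving on the likelihood.
.polr_loglik <- function(par, X, y, K) {
  theta <- par[seq_len(K - 1L)]
  beta <- par[-seq_len(K - 1L)]
  eta <- as.numeric(X %*% beta)
  th <- c(-Inf, theta, Inf)
  pk <- plogis(th[y + 1L] - eta) - plogis(th[y] - eta)
  if (any(pk <= 0) || is.unsorted(theta, strictly = TRUE)) return(-Inf)
  sum(log(pk))
}

.polr_gradient <- function(par, X, y, K) {
  p <- ncol(X)
  theta <- par[seq_len(K - 1L)]
  beta <- par[-seq_len(K - 1L)]
  eta <- as.numeric(X %*% beta)
  th <- c(-Inf, theta, Inf)
  a <- th[y + 1L] - eta          # upper cut
  b <- th[y] - eta               # lower cut
  pk <- plogis(a) - plogis(b)
  fa <- dlogis(a); fb <- dlogis(b)
  fa[!is.finite(a)] <- 0; fb[!is.finite(b)] <- 0
  g_theta <- numeric(K - 1L)
  for (k in seq_len(K - 1L)) {
    up <- y == k          # theta_k is the upper cut for level k
    lo <- y == k + 1L     # ... and the lower cut for level k+1
    g_theta[k] <- sum(fa[up] / pk[up]) - sum(fb[lo] / pk[lo])
  }
  w <- -(fa - fb) / pk
  g_beta <- as.numeric(crossprod(X, w))
  c(g_theta, g_beta)
}

#' Fit a proportional-odds ordinal regression
#'
#' Maximum-likelihood cumulative-logit fit,
#' `P(Y <= k | x) = plogis(theta_k - x'beta)`, by Newton iteration with
#' step-halving (the log-likelihood never decreases across iterations).
#' The Hessian is the Jacobian of the analytic gradient (central
#' differences); standard errors come from the inverse observed
#' information. A positive coefficient means higher odds of a more severe
#' stage; `exp(beta)` is the adjusted odds ratio per unit covariate.
#'
#' @param records data.frame containing `outcome_col` and the covariates.
#' @param covariates character vector of covariate column names.
#' @param outcome_col name of the ordinal outcome column; its values are
#'   coerced to consecutive integers `1..K` by rank.
#' @param max_iter,tol Newton iteration cap and gradient-norm tolerance.
#' @return An object of class `ordinal_fit`: `coefficients` (beta), `zeta`
#'   (thresholds), `se`, `aor`, `ci_lower`, `ci_upper`, `p_wald`,
#'   `log_lik`, `log_lik_trace`, `converged`, `n`.
#' @export
fit_ordinal_logistic <- function(records, covariates,
                                 outcome_col = "stage",
                                 max_iter = 100L, tol = 1e-6) {
  df <- records[, c(outcome_col, covariates)]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  yraw <- df[[outcome_col]]
  lev <- sort(unique(yraw))
  K <- length(lev)
  if (K < 2L) stop("need at least 2 outcome levels")
  y <- match(yraw, lev)
  X <- matrix(0, nrow(df), length(covariates),
              dimnames = list(NULL, covariates))
  for (j in seq_along(covariates)) {
    v <- df[[covariates[j]]]
    if (!is.numeric(v)) v <- as.numeric(factor(v)) - 1
    X[, j] <- v
  }
  if (qr(cbind(1, X))$rank < ncol(X) + 1L)
    stop("design matrix is rank deficient")
  p <- ncol(X)

  # start: thresholds from marginal cumulative logits, beta = 0
  cumfrac <- cumsum(tabulate(y, K))[seq_len(K - 1L)] / length(y)
  par <- c(stats::qlogis(pmin(pmax(cumfrac, 1e-3), 1 - 1e-3)), rep(0, p))
  ll <- .polr_loglik(par, X, y, K)
  trace <- ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- .polr_gradient(par, X, y, K)
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    Hn <- .jacobian(function(q) .polr_gradient(q, X, y, K), par)
    Hn <- (Hn + t(Hn)) / 2
    step <- tryCatch(solve(Hn, g), error = function(e) NULL)
    if (is.null(step)) step <- g / sqrt(sum(g^2))  # fall back to gradient
    alpha <- 1
    repeat {
      cand <- par - alpha * step
      llc <- .polr_loglik(cand, X, y, K)
      if (llc >= ll || alpha < 1e-10) break
      alpha <- alpha / 2
    }
    if (llc < ll) break                  # no uphill step found
    par <- cand; ll <- llc
    trace <- c(trace, ll)
  }

  H <- .jacobian(function(q) .polr_gradient(q, X, y, K), par)
  H <- (H + t(H)) / 2
  info <- -H                             # observed information
  vc <- tryCatch(solve(info), error = function(e)
    matrix(NA_real_, length(par), length(par)))
  se_all <- sqrt(pmax(diag(vc), 0))
  bi <- K - 1L + seq_len(p)
  beta <- par[bi]
  se <- se_all[bi]
  z <- beta / se
  structure(list(
    coefficients = setNames(beta, covariates),
    zeta = par[seq_len(K - 1L)],
    se = setNames(se, covariates),
    aor = setNames(exp(beta), covariates),
    ci_lower = setNames(exp(beta - 1.96 * se), covariates),
    ci_upper = setNames(exp(beta + 1.96 * se), covariates),
    p_wald = setNames(2 * stats::pnorm(-abs(z)), covariates),
    log_lik = ll, log_lik_trace = trace,
    converged = converged, n = nrow(X), n_levels = K,
    vcov = vc), class = "ordinal_fit")
}

# central-difference Jacobian of a vector-valued function
.jacobian <- function(f, x, h = 1e-5) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    hp <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + hp
    xm <- x; xm[j] <- xm[j] - hp
    J[, j] <- (f(xp) - f(xm)) / (2 * hp)
  }
  J
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf("Proportional-odds fit (n = %d, %d levels, %s)\n", x$n,
              x$n_levels, if (x$converged) "converged" else "NOT converged"))
  tab <- data.frame(beta = x$coefficients, se = x$se, aOR = x$aor,
                    ci_low = x$ci_lower, ci_high = x$ci_upper, p = x$p_wald)
  print(round(tab, 4))
  invisible(x)
}

#' Run the full per-cohort statistical battery
#'
#' For each vascular metric: control-vs-disease two-group comparison, all
#' pairwise stage comparisons, and the overall multi-group test (all with
#' the normality gate); plus a sex chi-square and the proportional-odds
#' regression of stage (disease eyes only, control excluded) on the three
#' metrics adjusted for sex, age, gestational age and birth weight. Also
#' reports `100 * beta`, the per-unit percent increase in the odds of a
#' more severe stage on the log-odds scale (`exp(beta) = aOR`).
#'
#' @param records data.frame of per-eye records as from [make_cohort].
#' @param metrics character vector of metric columns.
#' @param alpha normality-gate level.
#' @return List with `pairwise` (data.frame: metric, group_a, group_b,
#'   test, statistic, p), `overall` (per-metric multi-group test),
#'   `sex_table` + `sex_test`, and `ordinal` ([fit_ordinal_logistic] result
#'   or NULL when fewer than 3 disease stages are present).
#' @export
run_table_battery <- function(records, metrics = c("vt", "vw_um", "vd_pct"),
                              alpha = 0.05) {
  stages <- sort(unique(records$stage))
  grp_label <- function(s) if (s == 0) "control" else paste0("stage", s)
  pull <- function(metric, s) records[[metric]][records$stage == s]

  pairwise <- NULL
  overall <- NULL
  for (m in metrics) {
    # control vs all disease eyes pooled
    if (0 %in% stages && any(stages > 0)) {
      x <- records[[m]][records$stage == 0]
      y <- records[[m]][records$stage > 0]
      tr <- two_group_test(x, y, alpha)
      pairwise <- rbind(pairwise, data.frame(
        metric = m, group_a = "control", group_b = "fevr",
        test = tr$test_name, statistic = tr$statistic, p = tr$p_two_sided))
    }
    if (length(stages) >= 2) {
      cmb <- utils::combn(stages, 2)
      for (j in seq_len(ncol(cmb))) {
        s1 <- cmb[1, j]; s2 <- cmb[2, j]
        tr <- two_group_test(pull(m, s1), pull(m, s2), alpha)
        pairwise <- rbind(pairwise, data.frame(
          metric = m, group_a = grp_label(s1), group_b = grp_label(s2),
          test = tr$test_name, statistic = tr$statistic, p = tr$p_two_sided))
      }
    }
    if (length(stages) >= 3) {
      gr <- lapply(stages, function(s) pull(m, s))
      tr <- multi_group_test(gr)
      overall <- rbind(overall, data.frame(
        metric = m, test = tr$test_name, statistic = tr$statistic,
        p = tr$p_two_sided))
    }
  }

  sex_test <- NULL; sex_table <- NULL
  if ("sex" %in% names(records) && 0 %in% stages && any(stages > 0)) {
    sex_table <- table(factor(records$sex),
                       factor(ifelse(records$stage == 0, "control", "fevr")))
    if (all(dim(sex_table) == 2))
      sex_test <- tryCatch(chi_square_2x2(sex_table), error = function(e) NULL)
  }

  ordinal <- NULL
  dis <- records[records$stage > 0, , drop = FALSE]
  if (length(unique(dis$stage)) >= 3) {
    covs <- intersect(c(metrics, "sex", "age_days", "ga_days", "bw_g"),
                      names(dis))
    ordinal <- fit_ordinal_logistic(dis, covs)
  }
  list(pairwise = pairwise, overall = overall,
       sex_table = sex_table, sex_test = sex_test,
       ordinal = ordinal,
       pct_increase = if (!is.null(ordinal)) 100 * ordinal$coefficients)
}
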