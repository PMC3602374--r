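make_tc <- function(shift = c(0, 0, 0), n = 6, seed = 1, sd = 1) {
  set.seed(seed)
  time_course(
    c(0, 48, 96, 120),
    c(list(rnorm(n, 10, sd)),
      lapply(shift, function(s) rnorm(n, 10 + s, sd)))
  )
}

test_that("overwhelming shifts are detected and null groups are not", {
  res <- anova_dunnett(make_tc(shift = c(10, 0, 0), seed = 2))
  cmp <- res$comparisons
  expect_true(cmp$significant[cmp$timepoint_h == 48])
  expect_lt(cmp$p_adj[cmp$timepoint_h == 48], 1e-6)
  expect_false(cmp$significant[cmp$timepoint_h == 96])
})

test_that("Dunnett-adjusted p-values exceed their unadjusted counterparts", {
  for (seed in 1:10) {
    tc <- make_tc(shift = c(0.5, 1, 1.5), seed = seed)
    res <- anova_dunnett(tc)
    p_unadj <- 2 * stats::pt(abs(res$comparisons$t), res$df_error,
                             lower.tail = FALSE)
    expect_true(all(res$comparisons$p_adj >= p_unadj - 1e-6))
    # ... but never worse than Bonferroni
    expect_true(all(res$comparisons$p_adj <=
                      pmin(3 * p_unadj, 1) + 1e-6))
  }
})

test_that("adjusted p-values agree with multcomp's Dunnett procedure", {
  skip_if_not_installed("multcomp")
  tc <- make_tc(shift = c(1.2, 2, 0.3), seed = 4)
  res <- anova_dunnett(tc)
  d <- data.frame(
    value = unlist(tc$values),
    grp = factor(rep(tc$timepoints_h, lengths(tc$values)))
  )
  gl <- multcomp::glht(stats::aov(value ~ grp, data = d),
                       linfct = multcomp::mcp(grp = "Dunnett"))
  p_mc <- summary(gl, test = multcomp::adjusted("single-step"))$test$pvalues
  expect_equal(res$comparisons$p_adj, as.numeric(p_mc), tolerance = 2e-3)
})

test_that("unequal group sizes are handled with exact correlations", {
  set.seed(9)
  tc <- time_course(c(0, 48, 96),
                    list(rnorm(6, 10), rnorm(5, 11), rnorm(6, 10.2)))
  res <- anova_dunnett(tc)
  expect_equal(nrow(res$comparisons), 2)
  expect_true(all(res$comparisons$p_adj >= 0 & res$comparisons$p_adj <= 1))
})

test_that("degenerate designs are rejected", {
  expect_error(
    anova_dunnett(time_course(c(0, 48), list(c(1, 1), c(2, 2)))),
    "degenerate variance"
  )
  expect_error(
    anova_dunnett(time_course(c(48, 96), list(rnorm(5), rnorm(5)))),
    "control"
  )
})

test_that("family-wise false-positive rate is near alpha under the null", {
  # all groups identical; significance of the max |t| against the
  # multivariate-t critical value is what anova_dunnett thresholds, so
  # first verify the equivalence on a handful of datasets, then
  # calibrate the rate with the fast max-|t| route
  n <- 6; k <- 3; df <- 4 * n - 4
  lam <- sqrt(n / (n + n))
  R <- outer(rep(lam, k), rep(lam, k)); diag(R) <- 1
  qcrit <- uniroot(function(q) {
    set.seed(20231)
    as.numeric(mvtnorm::pmvt(lower = rep(-q, k), upper = rep(q, k),
                             df = df, corr = R,
                             algorithm = mvtnorm::GenzBretz(abseps = 1e-6,
                                                            maxpts = 1e6))) -
      0.95
  }, c(1, 6), tol = 1e-7)$root

  max_t <- function(seed) {
    set.seed(seed)
    vals <- matrix(rnorm(4 * n, 10, 1), nrow = n)
    m <- colMeans(vals)
    s2 <- sum(apply(vals, 2, function(v) sum((v - mean(v))^2))) / df
    max(abs(m[-1] - m[1]) / sqrt(s2 * 2 / n))
  }

  for (seed in 1:25) {
    set.seed(seed)
    tc <- time_course(c(0, 48, 96, 120),
                      lapply(1:4, function(i) rnorm(n, 10, 1)))
    res <- anova_dunnett(tc)
    expect_equal(any(res$comparisons$significant), max_t(seed) > qcrit,
                 info = paste("seed", seed))
  }

  fwer <- mean(vapply(1:2000, function(s) max_t(s) > qcrit, logical(1)))
  expect_lt(abs(fwer - 0.05), 0.01)
})

test_that("quadratic fits recover exact polynomials with zero-width bands", {
  t <- c(0, 48, 96, 120)
  tc <- time_course(t, lapply(t, function(x) rep(2 + 0.5 * x - 0.002 * x^2, 3)))
  fit <- fit_poly2(tc)
  expect_equal(unname(fit$coefficients), c(2, 0.5, -0.002), tolerance = 1e-9)
  expect_equal(max(fit$band$upr - fit$band$lwr), 0, tolerance = 1e-7)
})

test_that("linear data give a quadratic coefficient near zero", {
  t <- c(0, 48, 96, 120)
  set.seed(3)
  tc <- time_course(t, lapply(t, function(x) 2 + 0.1 * x + rnorm(6, 0, 0.5)))
  fit <- fit_poly2(tc)
  ci <- stats::confint(fit$lm)["I(time_h^2)", ]
  expect_true(ci[1] <= 0 && 0 <= ci[2])
})

test_that("logistic fits recover an exact induction curve", {
  t <- seq(0, 120, 12)
  truth <- 690 / (1 + exp(-0.1 * (t - 24)))
  tc <- time_course(t, lapply(truth, function(v) rep(v, 3)))
  fit <- fit_logistic(tc)
  expect_true(fit$identifiable)
  expect_lt(abs(fit$A - 690) / 690, 1e-3)
  expect_lt(abs(fit$k - 0.1) / 0.1, 1e-3)
  expect_lt(abs(fit$t0 - 24) / 24, 1e-3)
})

test_that("flat series are flagged non-identifiable", {
  t <- c(0, 48, 96, 120)
  tc <- time_course(t, lapply(t, function(x) rep(5, 4)))
  fit <- fit_logistic(tc)
  expect_false(fit$identifiable)
})

test_that("noisy logistic plateaus are recovered within 5% median error", {
  t <- c(0, 24, 48, 72, 96, 120)
  truth <- 690 / (1 + exp(-0.1 * (t - 24)))
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    tc <- time_course(t, lapply(truth, function(v) v + rnorm(5, 0, 0.05 * 690)))
    abs(fit_logistic(tc)$A - 690) / 690
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})
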