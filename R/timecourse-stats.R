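#' Replicate time course container
#'
#' Holds replicate measurements of one quantity for one strain at a set
#' of timepoints (conventionally 0, 48, 96 and 120 h of a treatment,
#' with 5-6 replicate cultures).  Timepoint 0 is the pre-treatment
#' control against which Dunnett comparisons are made.
#'
#' @param timepoints_h Timepoints in h (at least 2).
#' @param values List of numeric vectors, one per timepoint (replicate
#'   measurements; group sizes may differ).
#' @param quantity,strain,units Optional metadata.
#' @return A `time_course` object.
#' @export
#' @examples
#' time_course(c(0, 48), list(c(1, 1.2, 0.9), c(2.1, 1.8, 2.2)))
time_course <- function(timepoints_h, values, quantity = NA, strain = NA,
                        units = NA) {
  if (length(timepoints_h) < 2) stop_data("need at least 2 timepoints")
  if (length(values) != length(timepoints_h)) {
    stop_data("one replicate vector per timepoint required")
  }
  structure(
    list(
      timepoints_h = timepoints_h,
      values = lapply(values, as.numeric),
      quantity = quantity, strain = strain, units = units
    ),
    class = "time_course"
  )
}

tc_long <- function(tc) {
  data.frame(
    time_h = rep(tc$timepoints_h, lengths(tc$values)),
    value = unlist(tc$values, use.names = FALSE)
  )
}

#' One-way ANOVA with Dunnett comparisons against the control
#'
#' One-way ANOVA across timepoints followed by Dunnett's many-to-one
#' procedure comparing each later timepoint to the timepoint-0 control,
#' two-sided, using the pooled within-group variance.  Adjusted p-values
#' are computed from the equicorrelated multivariate-t distribution of
#' the maximum absolute contrast statistic (exact unequal-n
#' correlations are used when group sizes differ), so the family-wise
#' error rate is controlled at `alpha` by construction.
#'
#' @param tc A [time_course()] whose timepoints include 0.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A `dunnett_result` list: `anova_F`, `anova_p`, `df_error`,
#'   and `comparisons`, a data frame with columns `timepoint_h`,
#'   `diff` (mean difference vs control), `t`, `p_adj`, `significant`.
#' @export
#' @examples
#' tc <- time_course(c(0, 48, 96), list(rnorm(6), rnorm(6) + 3, rnorm(6)))
#' anova_dunnett(tc)
anova_dunnett <- function(tc, alpha = 0.05) {
  stopifnot(inherits(tc, "time_course"))
  if (!0 %in% tc$timepoints_h) {
    stop_data("Dunnett comparison requires the timepoint-0 control")
  }
  n <- lengths(tc$values)
  if (length(n) < 2 || any(n < 2)) {
    stop_data("need >= 2 groups with >= 2 replicates each")
  }
  d <- tc_long(tc)
  d$grp <- factor(d$time_h)
  means <- tapply(d$value, d$grp, mean)
  ss_within <- sum(tapply(d$value, d$grp, function(v) sum((v - mean(v))^2)))
  df_err <- nrow(d) - nlevels(d$grp)
  if (ss_within <= 0) stop_data("degenerate variance: no within-group spread")
  s2 <- ss_within / df_err

  av <- stats::anova(stats::lm(value ~ grp, data = d))
  ctrl <- as.character(0)
  trt <- setdiff(levels(d$grp), ctrl)
  n_by <- tapply(d$value, d$grp, length)
  n0 <- n_by[[ctrl]]

  tstat <- vapply(trt, function(g) {
    (means[[g]] - means[[ctrl]]) / sqrt(s2 * (1 / n_by[[g]] + 1 / n0))
  }, numeric(1))
  diffs <- vapply(trt, function(g) means[[g]] - means[[ctrl]], numeric(1))

  # correlation of the contrast statistics sharing the control mean:
  # rho_ij = lambda_i * lambda_j with lambda_i = sqrt(n_i / (n_i + n0))
  lam <- sqrt(n_by[trt] / (n_by[trt] + n0))
  R <- outer(lam, lam)
  diag(R) <- 1

  k <- length(trt)
  p_adj <- vapply(seq_len(k), function(i) {
    q <- abs(tstat[i])
    pr <- with_seed(20231, mvtnorm::pmvt(
      lower = rep(-q, k), upper = rep(q, k), df = df_err, corr = R,
      algorithm = mvtnorm::GenzBretz(abseps = 1e-5, maxpts = 100000)
    ))
    min(max(1 - as.numeric(pr), 0), 1)
  }, numeric(1))

  structure(
    list(
      anova_F = av$`F value`[1], anova_p = av$`Pr(>F)`[1],
      df_error = df_err, alpha = alpha,
      comparisons = data.frame(
        timepoint_h = as.numeric(trt),
        diff = unname(diffs), t = unname(tstat),
        p_adj = p_adj, significant = p_adj < alpha
      )
    ),
    class = "dunnett_result"
  )
}

#' @export
print.dunnett_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3f, p = %.4g (error df = %d)\n",
              x$anova_F, x$anova_p, x$df_error))
  cat(sprintf("Dunnett comparisons vs t = 0 (two-sided, alpha = %g):\n",
              x$alpha))
  print(x$comparisons, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Quadratic time-course fit with a 95% confidence band
#'
#' OLS fit of a second-order polynomial in time to the replicate
#' measurements, with a pointwise 95% confidence band from the fit
#' covariance.
#'
#' @param tc A [time_course()] with at least 4 (for replicate-weighted
#'   data, 4 groups of) distinct timepoints... at minimum the design
#'   matrix must have full rank.
#' @param band_times_h Times at which to evaluate the fitted curve and
#'   band (defaults to a fine grid over the observed range).
#' @return A `poly2_fit` list: `coefficients` (intercept, linear,
#'   quadratic), `band` (data frame `time_h`, `fit`, `lwr`, `upr`),
#'   `r_squared`.
#' @export
fit_poly2 <- function(tc, band_times_h = NULL) {
  stopifnot(inherits(tc, "time_course"))
  d <- tc_long(tc)
  if (length(unique(d$time_h)) < 3) {
    stop_data("rank deficiency: need >= 3 distinct timepoints for a quadratic")
  }
  fit <- stats::lm(value ~ time_h + I(time_h^2), data = d)
  if (any(is.na(stats::coef(fit)))) stop_data("rank-deficient quadratic fit")
  if (is.null(band_times_h)) {
    band_times_h <- seq(min(d$time_h), max(d$time_h), length.out = 101)
  }
  pr <- stats::predict(fit, newdata = data.frame(time_h = band_times_h),
                       interval = "confidence", level = 0.95)
  structure(
    list(
      coefficients = stats::coef(fit),
      band = data.frame(time_h = band_times_h, fit = pr[, "fit"],
                        lwr = pr[, "lwr"], upr = pr[, "upr"]),
      r_squared = {
        tss <- sum((d$value - mean(d$value))^2)
        if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
      },
      lm = fit
    ),
    class = "poly2_fit"
  )
}

#' Logistic time-course fit
#'
#' Least-squares fit of a logistic growth function
#' `y(t) = A / (1 + exp(-k (t - t0)))` with the lower asymptote fixed
#' at 0 (appropriate for an induction that starts near zero, such as
#' IsiA accumulation); `A` estimates the plateau.
#'
#' @param tc A [time_course()] with at least 4 timepoints whose means
#'   are non-decreasing on average.
#' @return A `logistic_fit` list: `A`, `k`, `t0`, their standard
#'   errors, `rss`, `converged`, `identifiable` (FALSE when the fitted
#'   rate is indistinguishable from flat data).
#' @export
fit_logistic <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  d <- tc_long(tc)
  if (length(unique(d$time_h)) < 4) stop_data("need >= 4 distinct timepoints")
  means <- tapply(d$value, d$time_h, mean)
  tpts <- as.numeric(names(means))
  A0 <- max(means)
  rng <- diff(range(means))
  if (rng <= 0 || A0 <= 0) {
    return(structure(
      list(A = unname(mean(d$value)), k = 0, t0 = NA_real_,
           A_se = NA_real_, k_se = NA_real_, t0_se = NA_real_,
           rss = sum((d$value - mean(d$value))^2),
           converged = FALSE, identifiable = FALSE),
      class = "logistic_fit"
    ))
  }
  t0_0 <- tpts[which.min(abs(means - A0 / 2))]
  k0 <- 4 / max(diff(range(tpts)) / 4, 1e-6) # quarter-range rise time
  fit <- tryCatch(
    minpack.lm::nlsLM(
      value ~ A / (1 + exp(-k * (time_h - t0))),
      data = d,
      start = list(A = A0, k = k0, t0 = t0_0),
      lower = c(A = 0, k = 0, t0 = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-10,
                                           ftol = 1e-10)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(
      list(A = NA_real_, k = NA_real_, t0 = NA_real_,
           A_se = NA_real_, k_se = NA_real_, t0_se = NA_real_,
           rss = NA_real_, converged = FALSE, identifiable = FALSE),
      class = "logistic_fit"
    ))
  }
  cf <- summary(fit)$coefficients
  kfit <- cf["k", "Estimate"]
  # k so small that the curve is effectively linear/flat over the
  # observed window -> plateau not identifiable
  identifiable <- kfit * diff(range(tpts)) > 0.1
  structure(
    list(
      A = cf["A", "Estimate"], k = kfit, t0 = cf["t0", "Estimate"],
      A_se = cf["A", "Std. Error"], k_se = cf["k", "Std. Error"],
      t0_se = cf["t0", "Std. Error"],
      rss = sum(stats::residuals(fit)^2),
      converged = fit$convInfo$isConv,
      identifiable = identifiable
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic fit: plateau A = %.4g  k = %.4g h-1  t0 = %.4g h%s\n",
    x$A, x$k, x$t0,
    if (isTRUE(x$identifiable)) "" else "  [plateau not identifiable]"
  ))
  invisible(x)
}
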