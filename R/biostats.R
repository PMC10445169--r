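#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided exact p-value defined by the conventional minimum-likelihood
#' rule: the sum of probabilities of all tables (at fixed margins) whose
#' point hypergeometric probability does not exceed the observed table's.
#'
#' @param x 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(x) {
  validate_contingency_2x2(x)
  stats::fisher.test(x)$p.value
}

#' Power of a two-sample two-sided t-test (noncentral t)
#'
#' Exact power for equal group sizes: `P(|T| > t_crit)` where `T` follows a
#' noncentral t distribution with `2n - 2` degrees of freedom and
#' noncentrality `d * sqrt(n/2)`, and `t_crit` is the central two-sided
#' `alpha` critical value. Matches dedicated power software at very small
#' group sizes because no normal approximation is used.
#'
#' @param d Cohen's d effect size (standardized mean difference).
#' @param n_per_group Samples per group (>= 2).
#' @param alpha Type I error rate (default 0.05).
#' @param sides 2 (default) for a two-tailed test, 1 for one-tailed.
#' @return Power in `[0, 1]`.
#' @export
power_two_sample_t <- function(d, n_per_group, alpha = 0.05, sides = 2) {
  stopifnot(n_per_group >= 2, alpha > 0, alpha < 1, d >= 0, sides %in% c(1, 2))
  df <- 2 * n_per_group - 2
  ncp <- d * sqrt(n_per_group / 2)
  if (sides == 2) {
    tcrit <- stats::qt(1 - alpha / 2, df)
    stats::pt(tcrit, df, ncp, lower.tail = FALSE) + stats::pt(-tcrit, df, ncp)
  } else {
    tcrit <- stats::qt(1 - alpha, df)
    stats::pt(tcrit, df, ncp, lower.tail = FALSE)
  }
}

#' Power of a one-way ANOVA (noncentral F)
#'
#' Exact power `P(F > F_crit)` under a noncentral F distribution with
#' `(k - 1, N - k)` degrees of freedom and noncentrality `lambda = f^2 * N`,
#' where `f` is Cohen's f.
#'
#' @param f Cohen's f effect size.
#' @param k Number of groups (>= 2).
#' @param n_total Total sample size (>= k + 1).
#' @param alpha Type I error rate (default 0.05).
#' @return Power in `[0, 1]`.
#' @export
power_one_way_anova <- function(f, k, n_total, alpha = 0.05) {
  stopifnot(k >= 2, n_total >= k + 1, alpha > 0, alpha < 1, f >= 0)
  df1 <- k - 1
  df2 <- n_total - k
  lambda <- f^2 * n_total
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Minimal total sample size reaching a target one-way ANOVA power
#'
#' Reports the smallest `N` at which [power_one_way_anova()] meets `power`,
#' without asserting that any particular published N is minimal.
#'
#' @inheritParams power_one_way_anova
#' @param power Target power (default 0.80).
#' @param n_max Search ceiling (default 10000).
#' @return Integer total sample size.
#' @export
anova_min_total_n <- function(f, k, power = 0.80, alpha = 0.05, n_max = 10000L) {
  for (n in seq(k + 1L, n_max)) {
    if (power_one_way_anova(f, k, n, alpha) >= power) return(n)
  }
  stop("target power not reached by n_total = ", n_max)
}

#' Relative fold change by the 2^-ddCt method
#'
#' `fold = 2^-[(Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control)]`: the treated target gene's cycle
#' threshold is normalized to the reference gene, referenced to the control
#' condition, and converted from cycles to fold expression.
#'
#' @param ct_target_treated,ct_ref_treated Ct of target and reference gene in
#'   the treated condition.
#' @param ct_target_control,ct_ref_control Ct of target and reference gene in
#'   the control condition.
#' @return Fold change (1 = no change; > 1 = higher in treated).
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  stopifnot(is.finite(ct_target_treated), is.finite(ct_ref_treated),
            is.finite(ct_target_control), is.finite(ct_ref_control))
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Fit a four-parameter log-logistic dose-response curve and estimate IC50
#'
#' Least-squares fit of
#' `viability = bottom + (top - bottom) / (1 + (dose/ic50)^hill)`,
#' with starting values taken from the data extremes and the dose closest to
#' the half-maximal response. The IC50 is the dose at half-maximal inhibition
#' between the fitted plateaus (the `ic50` parameter itself). If viability
#' does not decrease with dose the IC50 is undefined and returned as `NA`
#' with a warning.
#'
#' @param dose Positive dose vector (replicates allowed; micromolar in the
#'   assays this mirrors).
#' @param viability Viability as fraction of vehicle control, same length.
#' @return List with `ic50`, `top`, `bottom`, `hill`, `r_squared`, and the
#'   `fit` object.
#' @export
fit_ic50 <- function(dose, viability) {
  stopifnot(length(dose) == length(viability), all(dose > 0),
            all(is.finite(viability)))
  if (length(unique(dose)) < 4) stop("need >= 4 distinct doses")
  mean_by_dose <- tapply(viability, dose, mean)
  doses_sorted <- as.numeric(names(mean_by_dose))
  if (diff(range(mean_by_dose)) < 1e-8 ||
      stats::cor(log(dose), viability) >= 0) {
    warning("viability does not decrease with dose; IC50 undefined")
    return(list(ic50 = NA_real_, top = NA_real_, bottom = NA_real_,
                hill = NA_real_, r_squared = NA_real_, fit = NULL))
  }
  top0 <- max(mean_by_dose)
  bot0 <- min(mean_by_dose)
  half <- (top0 + bot0) / 2
  ic50_0 <- doses_sorted[which.min(abs(mean_by_dose - half))]
  df <- data.frame(dose = dose, viability = viability)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      viability ~ bottom + (top - bottom) / (1 + (dose / ic50)^hill),
      data = df,
      start = list(top = top0, bottom = bot0, ic50 = ic50_0, hill = 1),
      lower = c(top = -Inf, bottom = -Inf, ic50 = min(dose) / 100, hill = 0.1),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("IC50 fit failed to converge: ",
                             conditionMessage(e)))
  est <- stats::coef(fit)
  resid <- stats::resid(fit)
  r2 <- 1 - sum(resid^2) / sum((viability - mean(viability))^2)
  list(ic50 = unname(est["ic50"]), top = unname(est["top"]),
       bottom = unname(est["bottom"]), hill = unname(est["hill"]),
       r_squared = r2, fit = fit)
}

#' Squared Pearson correlation
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return R-squared in `[0, 1]`.
#' @export
correlation_r2 <- function(x, y) {
  pearson(x, y)^2
}
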