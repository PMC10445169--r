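test_that("Fisher exact matches published value and exhaustive enumeration", {
  stage <- matrix(c(4, 5, 5, 5), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(stage), 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2)), 34 / 70,
               tolerance = 1e-7)
  set.seed(71)
  for (rep in 1:15) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab), fisher_enum(tab), tolerance = 1e-7)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("Fisher p is invariant under row swap, column swap and transpose", {
  set.seed(72)
  for (rep in 1:10) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_2x2(tab)
    expect_equal(fisher_exact_2x2(tab[2:1, ]), p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[, 2:1]), p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(t(tab)), p, tolerance = 1e-12)
  }
})

test_that("noncentral-t power: null gives alpha, reported design exceeds 95%", {
  expect_equal(power_two_sample_t(0, 10), 0.05, tolerance = 1e-10)
  expect_gte(power_two_sample_t(9.6, 2), 0.95)
})

test_that("noncentral-t power matches a large Monte-Carlo t-test simulation", {
  set.seed(73)
  n <- 2; d <- 9.6; reps <- 1e6
  g1 <- matrix(stats::rnorm(n * reps, d), n)
  g2 <- matrix(stats::rnorm(n * reps, 0), n)
  m1 <- colMeans(g1); m2 <- colMeans(g2)
  v1 <- (g1[1, ] - m1)^2 + (g1[2, ] - m1)^2  # n-1 = 1 denominators
  v2 <- (g2[1, ] - m2)^2 + (g2[2, ] - m2)^2
  sp <- sqrt((v1 + v2) / (2 * n - 2))
  tstat <- (m1 - m2) / (sp * sqrt(2 / n))
  mc <- mean(abs(tstat) > stats::qt(0.975, 2 * n - 2))
  expect_equal(power_two_sample_t(d, n), mc, tolerance = 0.005)
})

test_that("noncentral-F power: null gives alpha, reported design exceeds 80%", {
  expect_equal(power_one_way_anova(0, 3, 24), 0.05, tolerance = 1e-10)
  expect_gte(power_one_way_anova(0.7, 3, 24), 0.80)
})

test_that("noncentral-F power matches a Monte-Carlo one-way ANOVA simulation", {
  set.seed(74)
  k <- 3; n <- 8; N <- k * n; f <- 0.7; reps <- 1e5
  # group means with Cohen's f: sd of means / sigma = f
  mus <- c(-1, 0, 1) * f * sqrt(3 / 2)  # population sd of these three is f
  x <- array(stats::rnorm(N * reps, rep(rep(mus, each = n), reps)),
             dim = c(n, k, reps))
  gm <- apply(x, c(2, 3), mean)          # k x reps group means
  grand <- colMeans(gm)
  ssb <- n * colSums(sweep(gm, 2, grand)^2)
  ssw <- apply(x, 3, function(m) sum(sweep(m, 2, colMeans(m))^2))
  fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  mc <- mean(fstat > stats::qf(0.95, k - 1, N - k))
  expect_equal(power_one_way_anova(f, k, N), mc, tolerance = 0.01)
})

test_that("both power functions are monotone in effect size and sample size", {
  d_grid <- seq(0, 3, by = 0.5)
  expect_true(all(diff(vapply(d_grid, power_two_sample_t,
                              0, n_per_group = 5)) >= 0))
  n_grid <- 2:12
  expect_true(all(diff(vapply(n_grid, function(n)
    power_two_sample_t(1, n), 0)) >= 0))
  f_grid <- seq(0, 1.5, by = 0.25)
  expect_true(all(diff(vapply(f_grid, power_one_way_anova,
                              0, k = 3, n_total = 24)) >= 0))
  N_grid <- seq(6, 60, by = 6)
  expect_true(all(diff(vapply(N_grid, function(N)
    power_one_way_anova(0.5, 3, N), 0)) >= 0))
})

test_that("minimal ANOVA n reports the first size reaching target power", {
  n_min <- anova_min_total_n(0.7, 3, power = 0.80)
  expect_gte(power_one_way_anova(0.7, 3, n_min), 0.80)
  expect_lt(power_one_way_anova(0.7, 3, n_min - 1), 0.80)
})

test_that("ddCt fold change follows the 2^-ddCt arithmetic", {
  expect_equal(ddct_fold_change(20, 15, 24, 16), 8)
  expect_equal(ddct_fold_change(20, 18, 22, 20), 1)  # ddCt = 0
  expect_equal(ddct_fold_change(21, 18, 22, 20), 0.5)  # ddCt = +1
})

test_that("IC50 recovery on noiseless and noisy 4PL curves", {
  clean <- simulate_dose_response(ic50 = 50, top = 1, bottom = 0.05,
                                  hill = 1.3)
  fit <- fit_ic50(clean$dose, clean$viability)
  expect_lt(abs(fit$ic50 - 50) / 50, 0.01)
  expect_gt(fit$r_squared, 0.999)

  noisy <- simulate_dose_response(ic50 = 50, top = 1, bottom = 0.05,
                                  hill = 1.3, noise_sd = 0.05, seed = 75)
  fitn <- fit_ic50(noisy$dose, noisy$viability)
  expect_lt(abs(fitn$ic50 - 50) / 50, 0.10)
})

test_that("IC50 fit is scale-equivariant in dose and flags flat curves", {
  clean <- simulate_dose_response(ic50 = 40, top = 1, bottom = 0, hill = 1.5)
  f1 <- fit_ic50(clean$dose, clean$viability)
  f2 <- fit_ic50(clean$dose * 10, clean$viability)
  expect_equal(f2$ic50 / f1$ic50, 10, tolerance = 1e-3)

  flat <- simulate_dose_response(ic50 = 50, top = 1, bottom = 1, hill = 1)
  expect_warning(ff <- fit_ic50(flat$dose, flat$viability), "undefined")
  expect_true(is.na(ff$ic50))
})

test_that("correlation r-squared matches its definition", {
  x <- c(1, 2, 3)
  expect_equal(correlation_r2(x, 2 * x + 1), 1.0)
  expect_equal(correlation_r2(x, c(1, 2, 4)), (3 / sqrt(2 * 14 / 3))^2,
               tolerance = 1e-12)
  # orthogonal deviations: y deviations perpendicular to x deviations
  expect_equal(correlation_r2(c(1, 2, 3), c(1, 3, 1) * c(1, -2, 1) + 5), 0)
  expect_error(correlation_r2(c(1, 1, 1), x), "constant")
})
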