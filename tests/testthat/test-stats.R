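# Cohort statistics: paired t, ICC(A,1), Shapiro-Wilk screen, the
# linear mixed model and the summary table.

test_that("paired_t matches the closed form and stats::t.test on random inputs", {
  r <- paired_t(c(3, 4, 5), c(2, 2, 2))          # diffs {1,2,3}
  expect_equal(r$mean_diff, 2)
  expect_equal(r$sd_diff, 1)
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p, 0.0741799, tolerance = 1e-6)

  set.seed(37)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    a <- stats::rnorm(n, 1); b <- stats::rnorm(n)
    got <- paired_t(a, b)
    oracle <- stats::t.test(a, b, paired = TRUE)
    expect_equal(got$t, unname(oracle$statistic), tolerance = 1e-12)
    expect_equal(got$p, oracle$p.value, tolerance = 1e-12)
    expect_equal(got$df, unname(oracle$parameter))
    # and the closed form identity
    expect_equal(got$t, got$mean_diff / (got$sd_diff / sqrt(got$n)),
                 tolerance = 1e-12)
  }
  z <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_true(z$degenerate)
  expect_equal(z$t, 0); expect_equal(z$p, 1)
  expect_error(paired_t(1:3, 1:4), "unequal")
})

test_that("the summary-statistic paired t reuses the formula and flags the reference row", {
  r <- paired_t_from_summary(10.88, 4.55, 33)
  expect_equal(r$t, 10.88 / (4.55 / sqrt(33)), tolerance = 1e-12)
  expect_lt(r$p, 0.001)
  r2 <- paired_t_from_summary(2, 1, 3)
  expect_equal(r2$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_error(paired_t_from_summary(1, 0, 10), "positive")
})

# independent oracle: two-way ANOVA mean squares by explicit sums of squares
icc_bruteforce <- function(M) {
  n <- nrow(M); k <- ncol(M)
  gm <- mean(M)
  row_m <- rowMeans(M); col_m <- colMeans(M)
  SSR <- k * sum((row_m - gm)^2)
  SSC <- n * sum((col_m - gm)^2)
  SSE <- sum((M - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + gm)^2)
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1); MSE <- SSE / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

test_that("ICC(A,1) equals the brute-force ANOVA computation to 1e-9", {
  M0 <- cbind(1:6, c(1.1, 2.2, 2.9, 4.3, 5.1, 5.8))
  expect_equal(icc_agreement(M0)$icc, icc_bruteforce(M0), tolerance = 1e-9)

  set.seed(43)
  for (i in 1:8) {
    n <- sample(5:10, 1); k <- sample(2:4, 1)
    M <- matrix(stats::rnorm(n, sd = 3), n, k) +
      matrix(stats::rnorm(n * k, sd = 0.4), n, k)
    r <- icc_agreement(M)
    expect_equal(r$icc, icc_bruteforce(M), tolerance = 1e-9)
    expect_lte(r$ci_low, r$icc + 1e-12)
    expect_gte(r$ci_high, r$icc - 1e-12)
    expect_lte(r$icc, 1)
    # invariance under item permutation
    perm <- sample(n)
    expect_equal(icc_agreement(M[perm, ])$icc, r$icc, tolerance = 1e-9)
  }
  ident <- cbind(1:6, 1:6)
  expect_equal(icc_agreement(ident)$icc, 1, tolerance = 1e-9)
  expect_error(icc_agreement(matrix(c(1, NA, 2, 3, 4, 5, 6, 7, 8, 9), 5)),
               "complete")
  expect_error(icc_agreement(cbind(1:4, 2:5)), "at least 5")
})

test_that("the Shapiro-Wilk screen separates normal from skewed samples", {
  expect_true(shapiro_screen(rep(2, 10))$degenerate)
  expect_error(shapiro_screen(c(1, 2)), "at least 3")
  normal_hits <- skew_hits <- 0
  for (s in 1:100) {
    set.seed(s)
    if (shapiro_screen(stats::rnorm(50))$p > 0.05) normal_hits <- normal_hits + 1
    if (shapiro_screen(stats::rexp(50))$p < 0.05) skew_hits <- skew_hits + 1
  }
  expect_gte(normal_hits, 90)
  expect_gte(skew_hits, 90)
})

test_that("the mixed model recovers simulated fixed effects and flags degeneracies", {
  p <- cohort_sim_params(n_patients = 200, seed = 47, baseline = "zero",
                         beta = list(MD_mm = list(U1 = c(tadsabsent = -1.79))),
                         sigma_patient = 0.5, sigma_residual = 1.0)
  sim <- simulate_cohort(p)
  sub <- sim$cohort[sim$cohort$tooth == "U1", ]
  fit <- fit_lmm(sub, "d_MD_mm")
  co <- fit$coefficients
  b <- co[co$term == "tadsabsent", ]
  expect_lt(abs(b$estimate - (-1.79)), 3 * b$se)
  expect_lt(abs(b$estimate - (-1.79)) / 1.79, 0.10)   # bias below 10% of effect
  expect_lt(b$p, 0.05)
  expect_gte(fit$var_patient, 0)
  expect_equal(fit$n_obs, nrow(sub))
  expect_equal(fit$n_patients, 200)

  # no simulated patient effect: estimated intercept variance near zero
  p0 <- cohort_sim_params(n_patients = 500, seed = 53, baseline = "zero",
                          sigma_patient = 0, sigma_residual = 1.0)
  sim0 <- simulate_cohort(p0)
  fit0 <- fit_lmm(sim0$cohort[sim0$cohort$tooth == "U3", ], "d_IE_mm")
  expect_lte(fit0$var_patient, 0.1)

  # rank-deficient design named explicitly
  sub$dup <- sub$overbite
  expect_error(fit_lmm(sub, "d_MD_mm", c(default_covariates(), "dup")),
               "rank-deficient.*dup")
  expect_error(fit_lmm(sub, "d_MD_mm", c("age", "nosuch")), "missing covariate")
})

test_that("the movement summary reproduces stage arithmetic and star codes", {
  sim <- simulate_cohort(cohort_sim_params(n_patients = 33, seed = 59))
  s <- summarize_movements(sim$cohort)
  expect_equal(nrow(s), 30)   # 6 tooth types x 5 metrics
  expect_equal(s$diff_mean, s$designed_mean - s$achieved_mean, tolerance = 1e-12)
  expect_true(all(s$stars[s$p < 0.001] == "***"))
  expect_true(all(s$stars[s$p >= 0.05] == ""))
  bh <- summarize_movements(sim$cohort, adjust_bh = TRUE)
  expect_true(all(bh$p >= s$p - 1e-15))

  # zero-deviation cohort: all differences zero, p degenerate
  case <- synth_case(with_meshes = FALSE)
  presc <- default_prescription()
  for (m in c("MD_deg", "BL_deg", "MD_mm", "BL_mm", "IE_mm"))
    presc[[paste0("achieved_", m)]] <- presc[[paste0("designed_", m)]]
  st <- apply_prescription(case, presc)
  rec <- case_movement_records(case, st$designed, st$achieved)
  s0 <- summarize_movements(rec)
  expect_lt(max(abs(s0$diff_mean)), 1e-9)
  expect_true(all(is.na(s0$p)))
})
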