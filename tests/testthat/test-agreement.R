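test_that("subject stats match hand computation and are scale invariant", {
  x <- annotation_matrix(matrix(c(10, 12, 5, 5), 2, 2, byrow = TRUE))
  st <- subject_stats(x)
  expect_equal(st$mean_volume[1], 11)
  expect_equal(st$sd_volume[1], sqrt(2))
  expect_equal(st$sd_rel_pct[1], 100 * sqrt(2) / 11)
  expect_equal(st$sd_rel_pct[2], 0)
  y <- annotation_matrix(7.3 * x$volumes)
  expect_equal(subject_stats(y)$sd_rel_pct, st$sd_rel_pct)
})

test_that("ANOVA mean squares match the hand-worked 3x2 example", {
  ms <- anova_mean_squares(hand_example())
  expect_equal(ms$ms_observer, 1.5)
  expect_equal(ms$ms_residual, 3.5)
  expect_equal(ms$ms_subject, 213.5)
  expect_equal(ms$df_residual, 2L)
  expect_error(anova_mean_squares(matrix(1, 1, 3)), "n >= 2")
})

test_that("ANOVA agrees with brute-force sums and with aov on random grids", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      Y <- matrix(rlnorm(12, 3, 1), 4, 3)
      ms <- anova_mean_squares(Y)
      bf <- brute_mean_squares(Y)
      expect_equal(ms$ms_subject, bf$ms_subject, tolerance = 1e-10)
      expect_equal(ms$ms_observer, bf$ms_observer, tolerance = 1e-10)
      expect_equal(ms$ms_residual, bf$ms_residual, tolerance = 1e-10)
      d <- data.frame(y = as.vector(Y),
                      s = factor(rep(1:4, 3)), o = factor(rep(1:3, each = 4)))
      tab <- summary(aov(y ~ s + o, d))[[1]]
      expect_equal(ms$ms_subject, tab["s", "Mean Sq"], tolerance = 1e-10)
      expect_equal(ms$ms_observer, tab["o", "Mean Sq"], tolerance = 1e-10)
      expect_equal(ms$ms_residual, tab["Residuals", "Mean Sq"], tolerance = 1e-10)
    }
  })
})

test_that("mean squares scale quadratically and vanish for constant grids", {
  Y <- hand_example()$volumes
  ms <- anova_mean_squares(Y)
  ms3 <- anova_mean_squares(3 * Y)
  expect_equal(ms3$ms_residual, 9 * ms$ms_residual)
  expect_equal(ms3$ms_subject, 9 * ms$ms_subject)
  msc <- anova_mean_squares(matrix(5, 3, 2))
  expect_equal(msc$ms_subject + msc$ms_observer + msc$ms_residual, 0)
})

test_that("variance components truncate negative observer variance", {
  vc <- variance_components(anova_mean_squares(hand_example()))
  expect_equal(vc$sigma2_observer, 0)
  expect_true(vc$observer_truncated)
  expect_equal(vc$sigma2_observer_raw, (1.5 - 3.5) / 3)
  expect_equal(vc$sigma2_residual, 3.5)

  ms <- structure(list(ms_subject = 50, ms_observer = 10.5, ms_residual = 3.5,
                       df_subject = 6L, df_observer = 4L, df_residual = 24L,
                       n = 7, m = 5), class = "mean_squares")
  vc2 <- variance_components(ms)
  expect_equal(vc2$sigma2_observer, 1)
  expect_false(vc2$observer_truncated)

  ms$ms_observer <- ms$ms_residual # raw estimate exactly zero: no truncation
  vc3 <- variance_components(ms)
  expect_equal(vc3$sigma2_observer, 0)
  expect_false(vc3$observer_truncated)
})

test_that("loam_estimate applies the finite-observer variance exactly", {
  vc <- variance_components(anova_mean_squares(hand_example()))
  expect_equal(loam_estimate(vc, z = 1.959964), 1.959964 * sqrt(0.5 * 3.5))
  expect_equal(loam_estimate(vc, finite_correction = FALSE),
               qnorm(0.975) * sqrt(3.5))
  zero <- variance_components(anova_mean_squares(matrix(5, 3, 2)))
  expect_equal(loam_estimate(zero), 0)
  # doubling both variances scales the limit by sqrt(2)
  ms <- anova_mean_squares(sqrt(2) * hand_example()$volumes)
  expect_equal(loam_estimate(variance_components(ms)),
               sqrt(2) * loam_estimate(vc))
})

test_that("deviation-from-mean variance matches (m-1)/m * (sigma_o^2 + sigma_r^2)", {
  withr::with_seed(21, {
    m <- 5; so <- 2; sr <- 6; reps <- 4e5
    b <- matrix(rnorm(reps * m, 0, so), reps, m)
    e <- matrix(rnorm(reps * m, 0, sr), reps, m)
    Y <- b + e
    dev <- Y[, 1] - rowMeans(Y)
    theory <- (m - 1) / m * (so^2 + sr^2)
    se <- sd(dev^2) / sqrt(reps)
    expect_lt(abs(var(dev) - theory), 3 * se)
  })
})

test_that("LOAM CI reproduces an independent Graybill-Wang evaluation", {
  ms <- anova_mean_squares(hand_example())
  n <- 3; m <- 2; alpha <- 0.05
  cO <- 1 / n; cR <- (n - 1) / n
  psi <- cO * ms$ms_observer + cR * ms$ms_residual
  HO <- (m - 1) / qchisq(alpha / 2, m - 1) - 1
  HR <- 2 / qchisq(alpha / 2, 2) - 1
  GO <- 1 - (m - 1) / qchisq(1 - alpha / 2, m - 1)
  GR <- 1 - 2 / qchisq(1 - alpha / 2, 2)
  hi <- psi + sqrt((HO * cO * ms$ms_observer)^2 + (HR * cR * ms$ms_residual)^2)
  lo <- psi - sqrt((GO * cO * ms$ms_observer)^2 + (GR * cR * ms$ms_residual)^2)
  z <- qnorm(0.975)
  expected <- z * sqrt(0.5 * c(max(0, lo), hi))
  ci <- loam_ci(ms)
  expect_equal(unname(ci), expected, tolerance = 1e-12)
  expect_lte(ci[["low"]], loam_estimate(variance_components(ms)))
  expect_gte(ci[["high"]], loam_estimate(variance_components(ms)))
})

test_that("degenerate all-zero variability yields a null CI", {
  ms <- anova_mean_squares(matrix(5, 3, 2))
  expect_equal(unname(loam_ci(ms)), c(0, 0))
})

test_that("component SD bootstrap is seeded, truncation-aware, and guarded", {
  ms <- anova_mean_squares(hand_example())
  a <- component_sd_cis(ms, n_boot = 500, seed = 9)
  b <- component_sd_cis(ms, n_boot = 500, seed = 9)
  expect_identical(a, b)
  expect_equal(unname(a$sigma_o_ci[1]), 0) # truncated component: zero lower bound
  expect_error(component_sd_cis(ms, n_boot = 50), "n_boot")
})

test_that("residual-SD bootstrap CI attains nominal coverage", {
  withr::with_seed(31, {
    n <- 26; m <- 5; sr <- 6; so <- 2
    df_r <- (n - 1) * (m - 1)
    hits <- 0; reps <- 1000
    for (r in seq_len(reps)) {
      x <- additive_cohort(n, m, so, sr)
      ci <- component_sd_cis(anova_mean_squares(x), n_boot = 400)$sigma_r_ci
      if (sr >= ci[1] && sr <= ci[2]) hits <- hits + 1
    }
    expect_gte(hits / reps, 0.93)
    expect_lte(hits / reps, 0.97)
  })
})

test_that("ICC matches the plug-in value and its invariances", {
  icc <- icc_absolute_single(anova_mean_squares(hand_example()))
  expect_equal(icc$icc, 210 / (215 + 2 / 3), tolerance = 1e-12)
  expect_true(icc$ci[["low"]] <= icc$icc && icc$icc <= icc$ci[["high"]])
  # identical observers with subject spread: perfect agreement
  Y <- matrix(c(1, 1, 5, 5, 9, 9), 3, 2, byrow = TRUE)
  expect_equal(icc_absolute_single(anova_mean_squares(Y))$icc, 1)
  # scale invariance
  icc_c <- icc_absolute_single(anova_mean_squares(4.2 * hand_example()$volumes))
  expect_equal(icc_c$icc, icc$icc)
  expect_equal(icc_c$ci, icc$ci)
  expect_error(icc_absolute_single(anova_mean_squares(matrix(5, 3, 2))),
               "undefined")
})

test_that("estimates recover known components without bias", {
  withr::with_seed(41, {
    so <- 2; sr <- 6; reps <- 300
    est_o2 <- est_r2 <- numeric(reps)
    for (r in seq_len(reps)) {
      vc <- variance_components(anova_mean_squares(additive_cohort(40, 5, so, sr)))
      est_o2[r] <- vc$sigma2_observer_raw # untruncated: unbiased
      est_r2[r] <- vc$sigma2_residual
    }
    expect_lt(abs(mean(est_o2) - so^2), 3 * sd(est_o2) / sqrt(reps))
    expect_lt(abs(mean(est_r2) - sr^2), 3 * sd(est_r2) / sqrt(reps))
  })
})

test_that("loam_result is permutation invariant and internally consistent", {
  x <- generate_cohort(synthetic_config(n = 20, m = 4, seed = 13))
  res <- loam_result(x, n_boot = 300, seed = 2)
  expect_equal(res$loam_pct, 100 * res$loam_abs / res$group_mean_volume)
  withr::with_seed(14, {
    perm_s <- sample(nrow(x$volumes))
    perm_o <- sample(ncol(x$volumes))
  })
  y <- annotation_matrix(x$volumes[perm_s, perm_o],
                         meta = x$meta[perm_s, , drop = FALSE])
  res_p <- loam_result(y, n_boot = 300, seed = 2)
  for (f in c("loam_abs", "loam_pct", "icc", "sigma_o", "sigma_r",
              "group_mean_volume")) {
    expect_equal(res_p[[f]], res[[f]], info = f)
  }
  expect_equal(res_p$loam_abs_ci, res$loam_abs_ci)
})
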