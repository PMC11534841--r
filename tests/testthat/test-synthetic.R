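test_that("config invariants are enforced", {
  expect_error(synthetic_config(n = 3), "n >= 4")
  expect_error(synthetic_config(tau_r = -1), "tau_o and tau_r")
  expect_error(synthetic_config(gamma = 1.5), "gamma")
  expect_error(synthetic_config(cyst_fraction = 2), "cyst_fraction")
  expect_error(synthetic_config(vol_range = c(10, 5)), "vol_range")
})

test_that("zero error scales give exact copies of the true volumes", {
  cfg <- synthetic_config(n = 12, m = 4, tau_o = 0, tau_r = 0, seed = 1)
  x <- generate_cohort(cfg)
  truth <- cohort_truth(x)
  expect_equal(unname(x$volumes), matrix(truth$volume, 12, 4), tolerance = 1e-12)
  expect_equal(loam_result(x, n_boot = 0)$loam_abs, 0)
  expect_equal(loam_result(x, n_boot = 0)$icc, 1)
  expect_equal(max(subject_stats(x)$sd_rel_pct), 0)
})

test_that("generation is deterministic in the seed", {
  a <- generate_cohort(synthetic_config(seed = 5))
  b <- generate_cohort(synthetic_config(seed = 5))
  c <- generate_cohort(synthetic_config(seed = 6))
  expect_identical(a$volumes, b$volumes)
  expect_identical(a$meta, b$meta)
  expect_false(identical(a$volumes, c$volumes))
})

test_that("volume distribution hits the calibrated median", {
  cfg <- synthetic_config(n = 10000, m = 2, covariates = FALSE, seed = 11)
  v <- cohort_truth(generate_cohort(cfg))$volume
  expect_lt(abs(median(v) / 903 - 1), 0.05)
  expect_true(all(v >= 20 & v <= 40000))
})

test_that("the closed-form relative limit behaves as derived", {
  cfg <- synthetic_config()
  expect_equal(analytic_loam_percent(1000, cfg), 12.4565, tolerance = 1e-4)
  expect_equal(analytic_loam_percent(100, cfg), 26.8378, tolerance = 1e-4)
  expect_equal(analytic_threshold_volume(cfg, 20), 241.6, tolerance = 1e-3)
  # zero error: zero limit everywhere
  cfg0 <- synthetic_config(tau_o = 0, tau_r = 0)
  expect_equal(analytic_loam_percent(c(10, 1000), cfg0), c(0, 0))
  # gamma = 1: volume-independent relative error
  cfg1 <- synthetic_config(gamma = 1)
  expect_equal(analytic_loam_percent(50, cfg1), analytic_loam_percent(5000, cfg1))
  expect_error(analytic_threshold_volume(cfg1), "gamma = 1")
})

test_that("agreement estimates recover the generator's error scales", {
  # gamma = 0 cohorts: tau_o, tau_r are the component SDs directly
  withr::with_seed(53, {
    reps <- 200
    est_r2 <- est_o2 <- numeric(reps)
    for (r in seq_len(reps)) {
      cfg <- synthetic_config(n = 50, m = 5, gamma = 0, tau_o = 2, tau_r = 6,
                              cyst_fraction = 0, covariates = FALSE)
      vc <- variance_components(anova_mean_squares(generate_cohort(cfg)))
      est_o2[r] <- vc$sigma2_observer_raw
      est_r2[r] <- vc$sigma2_residual
    }
    expect_lt(abs(mean(est_o2) - 4), 3 * sd(est_o2) / sqrt(reps))
    expect_lt(abs(mean(est_r2) - 36), 3 * sd(est_r2) / sqrt(reps))
  })
})

test_that("cysts inflate stratum-IV residual error", {
  diffs <- vapply(1:8, function(s) {
    with_cyst <- synthetic_config(cyst_fraction = 0.4, cyst_multiplier = 3,
                                  seed = s)
    no_cyst <- synthetic_config(cyst_fraction = 0, seed = s)
    top <- function(cfg) {
      x <- generate_cohort(cfg)
      a <- stratify_quartiles(subject_stats(x))
      ids <- a$subject[a$stratum == "IV"]
      loam_result(x[ids], n_boot = 0)$sigma_r
    }
    top(with_cyst) - top(no_cyst)
  }, numeric(1))
  expect_gt(mean(diffs > 0), 0.75) # one-sided: inflation in nearly all seeds
  expect_gt(mean(diffs), 0)
})

test_that("configs round-trip through YAML and JSON files", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(n = 20, m = 3, tau_r = 0.5, seed = 3), yml)
  cfg <- read_synthetic_config(yml)
  expect_equal(cfg$n, 20)
  expect_equal(cfg$tau_r, 0.5)
  jsn <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(n = 8, m = 2, gamma = 0.5), jsn, auto_unbox = TRUE)
  cfg2 <- read_synthetic_config(jsn)
  expect_equal(cfg2$gamma, 0.5)
  expect_identical(generate_cohort(cfg)$volumes,
                   generate_cohort(read_synthetic_config(yml))$volumes)
})
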