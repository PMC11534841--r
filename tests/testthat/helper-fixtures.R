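# 3 subjects x 2 observers worked example; its ANOVA is tractable by hand:
# ms_observer 1.5, ms_residual 3.5, ms_subject 213.5
hand_example <- function() {
  annotation_matrix(matrix(c(10, 12, 20, 18, 30, 33), 3, 2, byrow = TRUE),
                    subject_ids = c("a", "b", "c"),
                    observer_ids = c("o1", "o2"))
}

# brute-force two-way mean squares straight from the sums of squares,
# independent of the package's implementation
brute_mean_squares <- function(Y) {
  n <- nrow(Y); m <- ncol(Y)
  g <- mean(Y)
  ss_subj <- 0; ss_obs <- 0; ss_res <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    ss_res <- ss_res + (Y[i, j] - mean(Y[i, ]) - mean(Y[, j]) + g)^2
  }
  for (i in seq_len(n)) ss_subj <- ss_subj + m * (mean(Y[i, ]) - g)^2
  for (j in seq_len(m)) ss_obs <- ss_obs + n * (mean(Y[, j]) - g)^2
  list(ms_subject = ss_subj / (n - 1), ms_observer = ss_obs / (m - 1),
       ms_residual = ss_res / ((n - 1) * (m - 1)))
}

# additive-error cohort at fixed component SDs (gamma = 0): true
# loam = z * sqrt((m-1)/m * (sigma_o^2 + sigma_r^2))
additive_cohort <- function(n = 26, m = 5, sigma_o = 2, sigma_r = 6,
                            base = 903) {
  b <- rnorm(m, 0, sigma_o)
  subj <- runif(n, base / 2, base * 2)
  Y <- outer(subj, rep(1, m)) + outer(rep(1, n), b) +
    matrix(rnorm(n * m, 0, sigma_r), n, m)
  annotation_matrix(Y)
}

long_fixture_file <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  x <- generate_cohort(synthetic_config(n = 12, m = 3, seed = 42))
  path <- file.path(dir, "annotations.csv")
  write_annotations(x, path)
  list(path = path, x = x)
}
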