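#' Per-subject volume statistics
#'
#' For each subject, the mean and sample standard deviation of the `m`
#' observer volumes, and the relative volume standard deviation
#' SD\eqn{_{V\%}} = 100 * sd / mean — the response used in the covariate
#' regression.
#'
#' @param x An [annotation_matrix()].
#' @return A tibble with columns `subject`, `mean_volume`, `sd_volume`,
#'   `sd_rel_pct`, one row per subject in input order.
#' @export
subject_stats <- function(x) {
  stopifnot(inherits(x, "annotation_matrix"))
  mv <- rowMeans(x$volumes)
  sdv <- apply(x$volumes, 1, stats::sd)
  tibble::tibble(
    subject = subject_ids(x),
    mean_volume = unname(mv),
    sd_volume = unname(sdv),
    sd_rel_pct = unname(100 * sdv / mv)
  )
}

#' Two-way ANOVA mean squares for a complete subject-by-observer grid
#'
#' Classical balanced two-way crossed decomposition without interaction for
#' the model Y_ij = mu + a_i + b_j + e_ij (subject effect a_i, systematic
#' observer offset b_j, residual annotation error e_ij).
#'
#' @param x An [annotation_matrix()] or a complete numeric `n x m` matrix.
#' @return An object of class `mean_squares`: list with `ms_subject`,
#'   `ms_observer`, `ms_residual` (mm^6), the corresponding degrees of
#'   freedom, and `n`, `m`.
#' @export
anova_mean_squares <- function(x) {
  Y <- if (inherits(x, "annotation_matrix")) x$volumes else as.matrix(x)
  n <- nrow(Y)
  m <- ncol(Y)
  if (n < 2 || m < 2)
    stop("ANOVA needs n >= 2 subjects and m >= 2 observers", call. = FALSE)
  if (anyNA(Y)) stop("grid must be complete", call. = FALSE)
  g <- mean(Y)
  rm_ <- rowMeans(Y)
  cm_ <- colMeans(Y)
  res <- Y - outer(rm_, rep(1, m)) - outer(rep(1, n), cm_) + g
  structure(list(
    ms_subject = m * sum((rm_ - g)^2) / (n - 1),
    ms_observer = n * sum((cm_ - g)^2) / (m - 1),
    ms_residual = sum(res^2) / ((n - 1) * (m - 1)),
    df_subject = n - 1L, df_observer = m - 1L,
    df_residual = (n - 1L) * (m - 1L),
    n = n, m = m
  ), class = "mean_squares")
}

#' @export
print.mean_squares <- function(x, ...) {
  cat("<mean_squares> n =", x$n, ", m =", x$m, "\n")
  cat(sprintf("  subject : %g (df %d)\n", x$ms_subject, x$df_subject))
  cat(sprintf("  observer: %g (df %d)\n", x$ms_observer, x$df_observer))
  cat(sprintf("  residual: %g (df %d)\n", x$ms_residual, x$df_residual))
  invisible(x)
}

#' Variance components from the mean squares
#'
#' Method-of-moments estimators: the residual variance (random annotation
#' error) is the residual mean square; the inter-observer variance
#' (systematic rater bias) is `(ms_observer - ms_residual) / n`, truncated
#' at zero. A negative raw estimate — common when the true observer variance
#' is near zero and `m` is small — is reported as 0 with
#' `observer_truncated = TRUE`; the raw value is kept for diagnostics.
#'
#' @param ms A [anova_mean_squares()] result.
#' @return Object of class `variance_components`: `sigma2_observer`,
#'   `sigma2_residual`, `observer_truncated`, `sigma2_observer_raw`, `n`, `m`.
#' @export
variance_components <- function(ms) {
  stopifnot(inherits(ms, "mean_squares"))
  raw <- (ms$ms_observer - ms$ms_residual) / ms$n
  structure(list(
    sigma2_observer = max(0, raw),
    sigma2_residual = ms$ms_residual,
    observer_truncated = raw < 0,
    sigma2_observer_raw = raw,
    n = ms$n, m = ms$m
  ), class = "variance_components")
}

#' LOAM half-width from variance components
#'
#' The limits of agreement with the mean: how far a single observer's
#' measurement may plausibly deviate from the mean of all `m` observers'
#' measurements of the same subject. Under the two-way model,
#' Var(Y_ij - Ybar_i.) = (m-1)/m * (sigma_O^2 + sigma_R^2), so
#' `loam = z * sqrt((m-1)/m * (sigma2_observer + sigma2_residual))`.
#'
#' @param vc A [variance_components()] result.
#' @param m Observer count (defaults to `vc$m`).
#' @param z Normal quantile; default the exact 97.5% point (1.959964...).
#' @param finite_correction Apply the exact finite-observer factor
#'   `(m-1)/m` (default). Disabling it gives the infinite-observer limit
#'   `z * sqrt(sigma_O^2 + sigma_R^2)` for sensitivity analysis.
#' @return LOAM half-width in mm^3.
#' @export
loam_estimate <- function(vc, m = vc$m, z = stats::qnorm(0.975),
                          finite_correction = TRUE) {
  stopifnot(inherits(vc, "variance_components"), m >= 2)
  fac <- if (finite_correction) (m - 1) / m else 1
  z * sqrt(fac * (vc$sigma2_observer + vc$sigma2_residual))
}

# Modified large-sample (Graybill-Wang) CI for a positive linear combination
# sum(c_k * MS_k) of independent mean squares. Returns c(low, high).
mls_interval <- function(ms_values, dfs, coefs, alpha = 0.05) {
  est <- sum(coefs * ms_values)
  H <- dfs / stats::qchisq(alpha / 2, dfs) - 1
  G <- 1 - dfs / stats::qchisq(1 - alpha / 2, dfs)
  hi <- est + sqrt(sum((H * coefs * ms_values)^2))
  lo <- est - sqrt(sum((G * coefs * ms_values)^2))
  c(max(0, lo), hi)
}

#' Confidence interval for the LOAM half-width
#'
#' The LOAM is a monotone map of psi = sigma_O^2 + sigma_R^2 =
#' (1/n) ms_observer + ((n-1)/n) ms_residual, a positive linear combination
#' of independent mean squares. Its modified large-sample (Graybill-Wang)
#' interval is mapped through `z * sqrt((m-1)/m * psi)`. The interval is
#' asymmetric about the point estimate.
#'
#' @param ms A [anova_mean_squares()] result.
#' @param z Normal quantile used in the LOAM.
#' @param alpha Two-sided level (default 0.05 for a 95% CI).
#' @inheritParams loam_estimate
#' @return Named numeric `c(low, high)` in mm^3.
#' @export
loam_ci <- function(ms, z = stats::qnorm(0.975), alpha = 0.05,
                    finite_correction = TRUE) {
  stopifnot(inherits(ms, "mean_squares"))
  n <- ms$n
  psi_ci <- mls_interval(
    ms_values = c(ms$ms_observer, ms$ms_residual),
    dfs = c(ms$df_observer, ms$df_residual),
    coefs = c(1 / n, (n - 1) / n),
    alpha = alpha
  )
  fac <- if (finite_correction) (ms$m - 1) / ms$m else 1
  ci <- z * sqrt(fac * psi_ci)
  # the reported point estimate uses the truncated observer component, which
  # can exceed the plug-in combination; keep the interval ordered around it
  point <- loam_estimate(variance_components(ms), z = z,
                         finite_correction = finite_correction)
  c(low = min(ci[1], point), high = max(ci[2], point))
}

#' Bootstrap confidence intervals for the component standard deviations
#'
#' Parametric bootstrap from the fitted two-way model: the observer and
#' residual mean squares are redrawn as scaled chi-square variables
#' (`MS_O* ~ (n sigma_O^2 + sigma_R^2) chisq(m-1)/(m-1)`, residual
#' analogously), the components re-estimated per resample, and percentile
#' intervals taken on the SD scale. Truncation at zero propagates naturally
#' into zero lower bounds.
#'
#' @inheritParams loam_ci
#' @param n_boot Number of resamples (>= 100; default 10000).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return List with `sigma_o_ci` and `sigma_r_ci`, each `c(low, high)` mm^3.
#' @export
component_sd_cis <- function(ms, alpha = 0.05, n_boot = 10000, seed = NULL) {
  stopifnot(inherits(ms, "mean_squares"))
  if (n_boot < 100)
    stop("n_boot < 100 gives unstable percentile intervals", call. = FALSE)
  vc <- variance_components(ms)
  n <- ms$n
  draw <- function() {
    e_obs <- n * vc$sigma2_observer + vc$sigma2_residual
    ms_o <- e_obs * stats::rchisq(n_boot, ms$df_observer) / ms$df_observer
    ms_r <- vc$sigma2_residual * stats::rchisq(n_boot, ms$df_residual) / ms$df_residual
    list(
      sigma_o = sqrt(pmax(0, (ms_o - ms_r) / n)),
      sigma_r = sqrt(ms_r)
    )
  }
  boot <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  probs <- c(alpha / 2, 1 - alpha / 2)
  list(
    sigma_o_ci = stats::setNames(stats::quantile(boot$sigma_o, probs, names = FALSE),
                                 c("low", "high")),
    sigma_r_ci = stats::setNames(stats::quantile(boot$sigma_r, probs, names = FALSE),
                                 c("low", "high"))
  )
}

#' Intraclass correlation coefficient, absolute agreement, single measure
#'
#' Two-way random effects, absolute agreement, single rater — the ICC form
#' matching the LOAM model. The confidence interval is the standard F-based
#' interval with a Satterthwaite approximation for the denominator degrees
#' of freedom.
#'
#' @inheritParams loam_ci
#' @return List with `icc` and `ci = c(low, high)`.
#' @export
icc_absolute_single <- function(ms, alpha = 0.05) {
  stopifnot(inherits(ms, "mean_squares"))
  n <- ms$n
  m <- ms$m
  mss <- ms$ms_subject
  mso <- ms$ms_observer
  mse <- ms$ms_residual
  if (mss == 0 && mse == 0)
    stop("ICC undefined: no subject or residual variability", call. = FALSE)
  if (mse == 0 && mso == 0)
    return(list(icc = 1, ci = c(low = 1, high = 1)))
  icc <- (mss - mse) / (mss + (m - 1) * mse + (m / n) * (mso - mse))
  a <- m * icc / (n * (1 - icc))
  b <- 1 + m * icc * (n - 1) / (n * (1 - icc))
  v <- (a * mso + b * mse)^2 /
    ((a * mso)^2 / (m - 1) + (b * mse)^2 / ((n - 1) * (m - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (mss - f_l * mse) /
    (f_l * (m * mso + (m * n - m - n) * mse) + n * mss)
  hi <- n * (f_u * mss - mse) /
    (m * mso + (m * n - m - n) * mse + n * f_u * mss)
  list(icc = icc, ci = c(low = lo, high = min(1, hi)))
}

#' Full LOAM analysis of one subject group
#'
#' Runs the whole agreement stack on one group: ANOVA decomposition,
#' variance components with truncation, LOAM (absolute and as percent of the
#' group mean volume) with modified large-sample CIs, bootstrap CIs for the
#' component SDs, and the absolute-agreement single-measure ICC.
#'
#' @param x An [annotation_matrix()].
#' @param alpha Two-sided CI level (default 0.05).
#' @param z Normal quantile for the agreement limits.
#' @param n_boot Bootstrap resamples for the component SD CIs; `0` skips
#'   them (`NA` bounds), useful inside the sliding window.
#' @param seed Optional seed for the bootstrap.
#' @inheritParams loam_estimate
#' @return Object of class `loam_result` (a list; see [loam_tibble()] for
#'   the one-row tabular form).
#' @export
loam_result <- function(x, alpha = 0.05, z = stats::qnorm(0.975),
                        n_boot = 10000, seed = NULL, finite_correction = TRUE) {
  stopifnot(inherits(x, "annotation_matrix"))
  ms <- anova_mean_squares(x)
  vc <- variance_components(ms)
  loam_abs <- loam_estimate(vc, z = z, finite_correction = finite_correction)
  abs_ci <- loam_ci(ms, z = z, alpha = alpha,
                    finite_correction = finite_correction)
  gm <- mean(x$volumes)
  if (n_boot > 0) {
    sd_cis <- component_sd_cis(ms, alpha = alpha, n_boot = n_boot, seed = seed)
  } else {
    sd_cis <- list(sigma_o_ci = c(low = NA_real_, high = NA_real_),
                   sigma_r_ci = c(low = NA_real_, high = NA_real_))
  }
  icc <- icc_absolute_single(ms, alpha = alpha)
  structure(list(
    n = ms$n, m = ms$m,
    group_mean_volume = gm,
    loam_abs = loam_abs,
    loam_abs_ci = abs_ci,
    loam_pct = 100 * loam_abs / gm,
    loam_pct_ci = 100 * abs_ci / gm,
    sigma_o = sqrt(vc$sigma2_observer),
    sigma_o_ci = sd_cis$sigma_o_ci,
    sigma_r = sqrt(vc$sigma2_residual),
    sigma_r_ci = sd_cis$sigma_r_ci,
    icc = icc$icc,
    icc_ci = icc$ci,
    observer_truncated = vc$observer_truncated,
    mean_squares = ms,
    alpha = alpha, z = z
  ), class = "loam_result")
}

#' @export
print.loam_result <- function(x, ...) {
  fmt_ci <- function(ci, d = 3) sprintf("(%s-%s)", format(ci[1], digits = d),
                                        format(ci[2], digits = d))
  cat("<loam_result> n =", x$n, "subjects, m =", x$m, "observers\n")
  cat(sprintf("  mean volume : %s mm^3\n", format(x$group_mean_volume, digits = 4)))
  cat(sprintf("  LOAM        : +/- %s mm^3 %s; %s%% %s of mean\n",
              format(x$loam_abs, digits = 4), fmt_ci(x$loam_abs_ci),
              format(x$loam_pct, digits = 3), fmt_ci(x$loam_pct_ci)))
  cat(sprintf("  sigma_O     : %s mm^3 %s%s\n", format(x$sigma_o, digits = 3),
              fmt_ci(x$sigma_o_ci),
              if (x$observer_truncated) "  [raw estimate negative, truncated]" else ""))
  cat(sprintf("  sigma_R     : %s mm^3 %s\n", format(x$sigma_r, digits = 3),
              fmt_ci(x$sigma_r_ci)))
  cat(sprintf("  ICC(A,1)    : %s %s\n", format(x$icc, digits = 3),
              fmt_ci(x$icc_ci)))
  invisible(x)
}

#' One-row tibble form of a `loam_result`
#'
#' @param res A [loam_result()].
#' @return A one-row tibble with point estimates and `_lo` / `_hi` CI bounds.
#' @export
loam_tibble <- function(res) {
  stopifnot(inherits(res, "loam_result"))
  tibble::tibble(
    n = res$n, m = res$m,
    mean_volume = res$group_mean_volume,
    loam_abs = res$loam_abs,
    loam_abs_lo = res$loam_abs_ci[[1]], loam_abs_hi = res$loam_abs_ci[[2]],
    loam_pct = res$loam_pct,
    loam_pct_lo = res$loam_pct_ci[[1]], loam_pct_hi = res$loam_pct_ci[[2]],
    sigma_o = res$sigma_o,
    sigma_o_lo = res$sigma_o_ci[[1]], sigma_o_hi = res$sigma_o_ci[[2]],
    sigma_r = res$sigma_r,
    sigma_r_lo = res$sigma_r_ci[[1]], sigma_r_hi = res$sigma_r_ci[[2]],
    icc = res$icc,
    icc_lo = res$icc_ci[[1]], icc_hi = res$icc_ci[[2]],
    observer_truncated = res$observer_truncated
  )
}
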