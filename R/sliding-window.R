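#' Sliding-window volume-dependent LOAM curve
#'
#' Subjects are ordered by average observed volume; for each contiguous
#' block of `width` subjects (step 1, so consecutive windows differ by one
#' subject dropped and one added) the full agreement analysis is run. The
#' result is a continuous, volume-dependent agreement-limit curve: the
#' basis of per-tumor growth cutoffs.
#'
#' @param x An [annotation_matrix()].
#' @param width Window width in subjects (default 26, the reliability
#'   sample size from [required_sample_size()] at its defaults); must
#'   satisfy `4 <= width <= n`.
#' @param alpha,z,finite_correction Passed to [loam_result()].
#' @param n_boot Bootstrap resamples for component SD CIs per window;
#'   default 0 (skipped — the curve uses the analytic LOAM CI).
#' @return A `window_curve`: tibble with one row per window — `window`,
#'   `mean_volume` (arithmetic mean of member subject means), the
#'   [loam_tibble()] columns, and a `members` list-column of subject ids.
#'   Attributes: `width`, `alpha`, `z`.
#' @export
window_curve <- function(x, width = 26, alpha = 0.05,
                         z = stats::qnorm(0.975), n_boot = 0,
                         finite_correction = TRUE) {
  stopifnot(inherits(x, "annotation_matrix"))
  n <- nrow(x$volumes)
  if (width < 4) stop("window width must be at least 4", call. = FALSE)
  if (n < width)
    stop("need at least ", width, " subjects for window width ", width,
         ", got ", n, call. = FALSE)
  st <- subject_stats(x)
  ord <- order(st$mean_volume)
  ids <- st$subject[ord]
  means <- st$mean_volume[ord]
  rows <- lapply(seq_len(n - width + 1), function(k) {
    sel <- k:(k + width - 1)
    res <- loam_result(x[ids[sel]], alpha = alpha, z = z, n_boot = n_boot,
                       finite_correction = finite_correction)
    dplyr::bind_cols(
      tibble::tibble(window = k, mean_volume_rank = mean(means[sel])),
      loam_tibble(res),
      tibble::tibble(members = list(ids[sel]))
    )
  })
  out <- dplyr::bind_rows(rows)
  # mean_volume from loam_result equals the mean over member subject means
  # (complete grid), keep the single canonical column
  out$mean_volume_rank <- NULL
  attr(out, "width") <- width
  attr(out, "alpha") <- alpha
  attr(out, "z") <- z
  class(out) <- c("window_curve", class(out))
  out
}

#' Volume at which the agreement curve crosses a threshold
#'
#' Scans the windows in increasing mean-volume order for the first window
#' whose LOAM% (CI upper bound by default) falls to or below the threshold.
#' Under the default `"persistent"` rule all later windows must satisfy the
#' threshold too, which suppresses spurious early dips of the noisy curve;
#' `"first"` takes the first touch. The crossing volume is linearly
#' interpolated in log-volume between the qualifying window and its
#' predecessor.
#'
#' @param curve A [window_curve()].
#' @param threshold_pct Agreement threshold in percent (default 20, the
#'   conventional volumetric growth criterion).
#' @param bound Which curve to test: the CI `"upper"` bound (conservative,
#'   default) or the `"point"` estimate.
#' @param rule `"persistent"` (default) or `"first"`.
#' @return Crossing volume in mm^3, or `NA_real_` if the curve never
#'   satisfies the threshold.
#' @export
threshold_crossing <- function(curve, threshold_pct = 20,
                               bound = c("upper", "point"),
                               rule = c("persistent", "first")) {
  bound <- match.arg(bound)
  rule <- match.arg(rule)
  stopifnot(nrow(curve) > 0, threshold_pct > 0)
  val <- if (bound == "upper") curve$loam_pct_hi else curve$loam_pct
  mv <- curve$mean_volume
  ok <- val <= threshold_pct
  if (rule == "persistent") {
    # last FALSE, if any, blocks all earlier windows
    sustained <- rev(cumprod(rev(ok))) > 0
    k <- which(sustained)[1]
  } else {
    k <- which(ok)[1]
  }
  if (is.na(k)) return(NA_real_)
  if (k == 1) return(mv[1])
  v0 <- val[k - 1]
  v1 <- val[k]
  if (!is.finite(v0) || v0 <= threshold_pct || v1 == v0) return(mv[k])
  t <- (v0 - threshold_pct) / (v0 - v1)
  exp(log(mv[k - 1]) + t * (log(mv[k]) - log(mv[k - 1])))
}

#' Look up the agreement limit for an individual tumor volume
#'
#' The per-tumor calculator: piecewise-linear interpolation of LOAM% and
#' its CI bounds against log window mean volume. Volumes outside the
#' curve's range clamp to the nearest end and are flagged as extrapolated.
#'
#' @param curve A [window_curve()].
#' @param volume Tumor volume(s) in mm^3, strictly positive.
#' @return A tibble with columns `volume`, `loam_pct`, `ci_low`, `ci_high`,
#'   `extrapolated`.
#' @export
loam_lookup <- function(curve, volume) {
  stopifnot(nrow(curve) > 0)
  if (any(!is.finite(volume) | volume <= 0))
    stop("volume must be strictly positive", call. = FALSE)
  lx <- log(curve$mean_volume)
  interp <- function(y) stats::approx(lx, y, xout = log(volume), rule = 2,
                                      ties = mean)$y
  tibble::tibble(
    volume = volume,
    loam_pct = interp(curve$loam_pct),
    ci_low = interp(curve$loam_pct_lo),
    ci_high = interp(curve$loam_pct_hi),
    extrapolated = volume < min(curve$mean_volume) |
      volume > max(curve$mean_volume)
  )
}
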