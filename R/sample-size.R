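#' Assurance of the ICC lower-confidence-limit procedure
#'
#' Probability that the one-sided `1 - alpha` lower confidence limit of the
#' one-way random-effects ICC exceeds the minimum acceptable value `rho0`
#' when the true ICC is `rho`, for `n` subjects rated by `m` observers.
#'
#' Exact F representation: with theta = rho / (1 - rho), the between/within
#' F statistic satisfies F / (1 + m * theta) ~ F(n - 1, n(m - 1)), and the
#' lower limit exceeds rho0 iff F > (1 + m * theta0) * F_(1-alpha); hence
#' `power = P( F(n-1, n(m-1)) > (1 + m*theta0) / (1 + m*theta) * qf(1 - alpha, n-1, n(m-1)) )`.
#'
#' @param n Number of subjects (>= 2).
#' @param rho Anticipated ICC, in (rho0, 1).
#' @param rho0 Minimum acceptable ICC, in [0, rho).
#' @param alpha One-sided level of the lower confidence limit (default 0.05).
#' @param m Number of observers (>= 2).
#' @return The assurance probability.
#' @export
lower_limit_power <- function(n, rho = 0.9, rho0 = 0.8, alpha = 0.05, m = 5) {
  check_ss_spec(rho, rho0, alpha, m)
  stopifnot(n >= 2)
  theta <- rho / (1 - rho)
  theta0 <- rho0 / (1 - rho0)
  df1 <- n - 1
  df2 <- n * (m - 1)
  crit <- (1 + m * theta0) / (1 + m * theta) * stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, lower.tail = FALSE)
}

#' Required sample size for a reliability study
#'
#' Smallest number of subjects such that the one-sided lower confidence
#' limit of the one-way ICC exceeds `rho0` with probability at least
#' `power`, when the true ICC is `rho` — the confidence-interval
#' lower-limit (assurance) procedure. The assurance is monotone increasing
#' in `n`, so a linear scan suffices. At the defaults
#' (rho 0.9, rho0 0.8, power 0.8, one-sided alpha 0.05, 5 observers) the
#' minimum is 26 subjects.
#'
#' @inheritParams lower_limit_power
#' @param power Target assurance (default 0.8).
#' @param n_max Hard scan cap (default 1e6).
#' @return The required number of subjects (integer).
#' @export
required_sample_size <- function(rho = 0.9, rho0 = 0.8, power = 0.8,
                                 alpha = 0.05, m = 5, n_max = 1e6) {
  check_ss_spec(rho, rho0, alpha, m)
  if (power < 0.5 || power >= 1)
    stop("power must be in [0.5, 1)", call. = FALSE)
  for (n in 2:n_max) {
    if (lower_limit_power(n, rho, rho0, alpha, m) >= power) return(as.integer(n))
  }
  stop("assurance target not reached below n = ", n_max, call. = FALSE)
}

check_ss_spec <- function(rho, rho0, alpha, m) {
  if (!(rho0 >= 0 && rho0 < rho && rho < 1))
    stop("need 0 <= rho0 < rho < 1", call. = FALSE)
  if (!(alpha > 0 && alpha < 0.5))
    stop("alpha must be in (0, 0.5)", call. = FALSE)
  if (m < 2) stop("need at least 2 observers", call. = FALSE)
  invisible(TRUE)
}
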