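#' Subject-level regression data
#'
#' Joins the per-subject agreement statistics with the metadata and encodes
#' covariates numerically for linear regression: `volume` is the average
#' observed volume (mm^3), `laterality` is coded L = 0 / R = 1, `cyst`
#' no = 0 / yes = 1, `sex` F = 0 / M = 1. Dates are converted to decimal
#' years. Field strength stays numeric in tesla.
#'
#' @param x An [annotation_matrix()] with metadata.
#' @return A tibble, one row per subject, with `sd_rel_pct` (the response
#'   SD_V%) and the numerically coded covariates.
#' @export
regression_data <- function(x) {
  stopifnot(inherits(x, "annotation_matrix"))
  st <- subject_stats(x)
  out <- tibble::tibble(
    subject = st$subject,
    sd_rel_pct = st$sd_rel_pct,
    volume = st$mean_volume
  )
  if (is.null(x$meta)) return(out)
  meta <- x$meta
  for (nm in setdiff(names(meta), "subject")) {
    v <- meta[[nm]]
    if (inherits(v, "Date"))
      v <- as.numeric(format(v, "%Y")) + (as.POSIXlt(v)$yday / 365.25)
    if (is.logical(v)) v <- as.numeric(v)
    if (is.character(v) || is.factor(v)) {
      v <- as.character(v)
      lev <- sort(unique(stats::na.omit(v)))
      if (identical(lev, c("L", "R"))) v <- as.numeric(v == "R")
      else if (identical(lev, c("F", "M"))) v <- as.numeric(v == "M")
      else if (identical(sort(tolower(lev)), c("no", "yes")))
        v <- as.numeric(tolower(v) == "yes")
      else if (length(lev) == 2) v <- as.numeric(v == lev[2])
      else v <- suppressWarnings(as.numeric(v))
    }
    out[[nm]] <- as.numeric(v)
  }
  out
}

default_covariates <- function(data) {
  setdiff(names(data), c("subject", "sd_rel_pct"))
}

#' Univariable regression scan
#'
#' Ordinary least squares of the response on each covariate singly
#' (intercept included), complete cases per covariate; 95% CIs and
#' two-sided p-values from the t distribution. A covariate that is
#' constant over the complete cases (or leaves a degenerate fit) is
#' flagged inestimable.
#'
#' @param data Subject-level data from [regression_data()].
#' @param response Response column name (default `"sd_rel_pct"`).
#' @param covariates Covariate column names; default every column except
#'   `subject` and the response.
#' @param conf_level CI level (default 0.95).
#' @return A tibble: `covariate`, `n`, `estimate`, `ci_low`, `ci_high`,
#'   `p_value`, `estimable`, `adjusted = FALSE`.
#' @export
univariable_scan <- function(data, response = "sd_rel_pct",
                             covariates = NULL, conf_level = 0.95) {
  if (is.null(covariates)) covariates <- default_covariates(data)
  stopifnot(response %in% names(data), all(covariates %in% names(data)))
  rows <- lapply(covariates, function(cv) {
    d <- data[stats::complete.cases(data[c(response, cv)]), c(response, cv)]
    n_ok <- nrow(d)
    if (n_ok < 3 || length(unique(d[[cv]])) < 2) {
      return(tibble::tibble(covariate = cv, n = n_ok, estimate = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            p_value = NA_real_, estimable = FALSE,
                            adjusted = FALSE))
    }
    fit <- stats::lm(stats::reformulate(cv, response), data = d)
    co <- summary(fit)$coefficients
    ci <- suppressWarnings(stats::confint(fit, cv, level = conf_level))
    est <- co[cv, "Estimate"]
    p <- co[cv, "Pr(>|t|)"]
    # zero-residual fits give NaN inference; report the slope, flag degenerate
    degenerate <- !is.finite(co[cv, "Std. Error"]) ||
      co[cv, "Std. Error"] < .Machine$double.eps^0.5 * max(1, abs(est))
    if (degenerate) {
      ci <- matrix(c(est, est), 1)
      # an exact fit has p -> 0 unless the slope itself is negligible
      effect <- abs(est) * stats::sd(d[[cv]])
      p <- if (effect > max(1e-10, 1e-8 * stats::sd(d[[response]]))) 0 else NA_real_
    }
    tibble::tibble(covariate = cv, n = n_ok, estimate = est,
                   ci_low = ci[1], ci_high = ci[2], p_value = p,
                   estimable = TRUE, adjusted = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Multivariable (joint) regression fit
#'
#' Joint OLS of the response on the selected covariates over their common
#' complete cases, giving adjusted coefficients. A near-singular design
#' (condition number above `kappa_max`) triggers a warning and a
#' `collinear` flag; rank-deficient terms come back inestimable.
#'
#' @inheritParams univariable_scan
#' @param covariates Covariates to fit jointly (typically those significant
#'   in [univariable_scan()]).
#' @param kappa_max Condition-number threshold for the collinearity warning.
#' @return A tibble like [univariable_scan()]'s with `adjusted = TRUE` and
#'   a `collinear` flag column.
#' @export
multivariable_fit <- function(data, response = "sd_rel_pct", covariates,
                              conf_level = 0.95, kappa_max = 1e8) {
  stopifnot(length(covariates) >= 1, all(covariates %in% names(data)))
  d <- data[stats::complete.cases(data[c(response, covariates)]),
            c(response, covariates)]
  fit <- stats::lm(stats::reformulate(covariates, response), data = d)
  kap <- kappa(stats::model.matrix(fit), exact = TRUE)
  collinear <- !is.finite(kap) || kap > kappa_max
  if (collinear)
    warning("near-collinear design (condition number ", format(kap, digits = 3),
            "); adjusted estimates are unstable", call. = FALSE)
  co <- summary(fit)$coefficients
  ci <- suppressWarnings(stats::confint(fit, level = conf_level))
  rows <- lapply(covariates, function(cv) {
    if (!cv %in% rownames(co)) {
      return(tibble::tibble(covariate = cv, n = nrow(d), estimate = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_,
                            p_value = NA_real_, estimable = FALSE,
                            adjusted = TRUE, collinear = collinear))
    }
    tibble::tibble(covariate = cv, n = nrow(d),
                   estimate = co[cv, "Estimate"],
                   ci_low = ci[cv, 1], ci_high = ci[cv, 2],
                   p_value = co[cv, "Pr(>|t|)"],
                   estimable = TRUE, adjusted = TRUE, collinear = collinear)
  })
  dplyr::bind_rows(rows)
}

#' Combined covariate regression report
#'
#' The Table-3-shaped analysis: a univariable scan of all covariates, then
#' a joint (multivariable) fit of those with univariable p below
#' `select_alpha`, merged into one table. No multiplicity correction is
#' applied.
#'
#' @param x An [annotation_matrix()] with metadata, or a data frame already
#'   shaped like [regression_data()] output.
#' @inheritParams univariable_scan
#' @param select_alpha Univariable significance screen for entry into the
#'   multivariable model (default 0.05).
#' @return A tibble: `covariate`, `n`, `estimate`, `ci_low`, `ci_high`,
#'   `p_value`, and `adj_*` columns (NA for unselected covariates),
#'   `selected` flag.
#' @export
covariate_regression <- function(x, response = "sd_rel_pct",
                                 covariates = NULL, select_alpha = 0.05,
                                 conf_level = 0.95) {
  data <- if (inherits(x, "annotation_matrix")) regression_data(x) else x
  uni <- univariable_scan(data, response, covariates, conf_level)
  sel <- uni$covariate[uni$estimable & !is.na(uni$p_value) &
                         uni$p_value < select_alpha]
  out <- dplyr::select(uni, -"adjusted")
  out$selected <- out$covariate %in% sel
  out$adj_estimate <- NA_real_
  out$adj_ci_low <- NA_real_
  out$adj_ci_high <- NA_real_
  out$adj_p_value <- NA_real_
  if (length(sel) >= 1) {
    multi <- multivariable_fit(data, response, sel, conf_level)
    i <- match(multi$covariate, out$covariate)
    out$adj_estimate[i] <- multi$estimate
    out$adj_ci_low[i] <- multi$ci_low
    out$adj_ci_high[i] <- multi$ci_high
    out$adj_p_value[i] <- multi$p_value
  }
  out
}
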