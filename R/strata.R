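#' Stratify subjects into volume quartiles
#'
#' Subjects are ranked by average observed volume and split into four
#' contiguous, rank-based blocks labelled I (smallest) to IV (largest).
#' Rank-based blocks — rather than interpolated quantile thresholds —
#' guarantee equal 25/25/25/25 strata when `n` is divisible by four; any
#' remainder is distributed to the lowest strata first, so sizes never
#' differ by more than one. Ties in mean volume keep input order (stable
#' sort).
#'
#' @param stats Per-subject statistics from [subject_stats()] (or any data
#'   frame with `subject` and `mean_volume` columns).
#' @param n_strata Number of strata (default 4).
#' @return A tibble with columns `subject`, `stratum` (ordered factor
#'   I..IV), `mean_volume`; attribute `cuts` holds the maximum mean volume
#'   per stratum.
#' @export
stratify_quartiles <- function(stats, n_strata = 4) {
  stopifnot(all(c("subject", "mean_volume") %in% names(stats)))
  n <- nrow(stats)
  if (n < n_strata)
    stop("need at least ", n_strata, " subjects to form ", n_strata,
         " strata, got ", n, call. = FALSE)
  labels <- as.character(utils::as.roman(seq_len(n_strata)))
  sizes <- rep(n %/% n_strata, n_strata)
  rem <- n %% n_strata
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ord <- order(stats$mean_volume) # radix: stable, ties keep input order
  stratum <- rep(labels, times = sizes)
  out <- tibble::tibble(
    subject = stats$subject[ord],
    stratum = factor(stratum, levels = labels, ordered = TRUE),
    mean_volume = stats$mean_volume[ord]
  )
  attr(out, "cuts") <- tapply(out$mean_volume, out$stratum, max)
  out
}

#' Per-stratum LOAM report
#'
#' Runs the full agreement analysis ([loam_result()]) on each stratum's
#' submatrix — the Table-2-shaped report. With `exclude_cysts = TRUE`,
#' subjects flagged `cyst` in the metadata are dropped *within* their
#' full-cohort stratum (strata are not re-formed), the sensitivity analysis
#' for peritumoral cystic components. A stratum reduced below 2 subjects is
#' skipped with a warning.
#'
#' @param x An [annotation_matrix()].
#' @param assignment A stratum assignment from [stratify_quartiles()];
#'   computed from `x` when `NULL`.
#' @param exclude_cysts Drop cyst-flagged subjects within each stratum.
#' @param ... Passed to [loam_result()] (`alpha`, `z`, `n_boot`, `seed`, ...).
#' @return A tibble with one row per (retained) stratum: `stratum`,
#'   `cysts_excluded`, and the [loam_tibble()] columns.
#' @export
stratum_report <- function(x, assignment = NULL, exclude_cysts = FALSE, ...) {
  stopifnot(inherits(x, "annotation_matrix"))
  if (is.null(assignment)) assignment <- stratify_quartiles(subject_stats(x))
  if (!all(subject_ids(x) %in% assignment$subject))
    stop("assignment does not cover all subjects", call. = FALSE)
  if (exclude_cysts) {
    if (is.null(x$meta) || !"cyst" %in% names(x$meta))
      stop("exclude_cysts requires a 'cyst' metadata column", call. = FALSE)
    cyst_ids <- x$meta$subject[isTRUE_vec(x$meta$cyst)]
  } else {
    cyst_ids <- character(0)
  }
  rows <- lapply(levels(assignment$stratum), function(lab) {
    ids <- assignment$subject[assignment$stratum == lab]
    keep <- setdiff(ids, cyst_ids)
    if (length(keep) < 2) {
      warning("stratum ", lab, " has fewer than 2 subjects after exclusion; skipped",
              call. = FALSE)
      return(NULL)
    }
    res <- loam_result(x[keep], ...)
    dplyr::bind_cols(
      tibble::tibble(stratum = lab, cysts_excluded = exclude_cysts),
      loam_tibble(res)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$stratum <- factor(out$stratum, levels = levels(assignment$stratum),
                        ordered = TRUE)
  out
}

# TRUE where x is TRUE, FALSE for NA/FALSE; tolerates 0/1 coding
isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  !is.na(x) & (x == 1 | x == TRUE)
}
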