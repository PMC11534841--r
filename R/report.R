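#' Run the full agreement analysis and write a report bundle
#'
#' Ties every stage together on one cohort: per-subject statistics,
#' whole-cohort and per-quartile LOAM tables (inclusive and, when cyst
#' metadata is present, cyst-excluded), the sliding-window curve with its
#' threshold crossing, the covariate regression table, the agreement and
#' sliding-window figures, and a provenance log. Any stage error aborts
#' with the stage named and removes the partial outputs.
#'
#' @param x An [annotation_matrix()] or a [synthetic_config()] (generated
#'   on the fly).
#' @param out_dir Output directory (created if needed).
#' @param alpha CI level parameter (default 0.05).
#' @param z Normal quantile for the limits.
#' @param window Sliding-window width (default 26).
#' @param threshold_pct Agreement threshold for the crossing (default 20).
#' @param n_boot Bootstrap resamples for component SD CIs in the quartile
#'   tables.
#' @param seed Seed for the bootstrap (and recorded in provenance).
#' @param exclude_cysts Also produce cyst-excluded quartile rows.
#' @param figures Write PNG figures (default TRUE).
#' @return Invisibly, a list with the computed tables
#'   (`subject_stats`, `overall`, `quartiles`, `quartiles_excl`, `curve`,
#'   `crossing`, `regression`) and `files`.
#' @export
run_full_analysis <- function(x, out_dir, alpha = 0.05,
                              z = stats::qnorm(0.975), window = 26,
                              threshold_pct = 20, n_boot = 10000,
                              seed = 1L, exclude_cysts = TRUE,
                              figures = TRUE) {
  if (inherits(x, "synthetic_config")) x <- generate_cohort(x)
  stopifnot(inherits(x, "annotation_matrix"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  prov <- c(package = paste("volagree", as.character(utils::packageVersion("volagree"))),
            r_version = as.character(getRversion()),
            alpha = alpha, z = z, window = window,
            threshold_pct = threshold_pct, n_boot = n_boot, seed = seed)
  emit <- function(tbl, name) {
    path <- file.path(out_dir, name)
    write_table(tbl, path, provenance = c(prov, config_hash = prov_hash(prov, tbl)))
    written <<- c(written, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  stats_tbl <- stage("subject_stats", {
    st <- subject_stats(x)
    emit(st, "subject_stats.csv")
    st
  })
  assignment <- stage("stratification", stratify_quartiles(stats_tbl))
  overall <- stage("overall_loam", {
    res <- loam_tibble(loam_result(x, alpha = alpha, z = z, n_boot = n_boot,
                                   seed = seed))
    emit(res, "loam_overall.csv")
    res
  })
  quartiles <- stage("quartile_loam", {
    q <- stratum_report(x, assignment, exclude_cysts = FALSE, alpha = alpha,
                        z = z, n_boot = n_boot, seed = seed)
    emit(q, "loam_quartiles.csv")
    q
  })
  quartiles_excl <- NULL
  if (exclude_cysts && !is.null(x$meta) && "cyst" %in% names(x$meta) &&
      any(isTRUE_vec(x$meta$cyst))) {
    quartiles_excl <- stage("quartile_loam_excluding_cysts", {
      q <- suppressWarnings(
        stratum_report(x, assignment, exclude_cysts = TRUE, alpha = alpha,
                       z = z, n_boot = n_boot, seed = seed))
      # re-report only strata that actually contain cysts
      with_cysts <- unique(assignment$stratum[
        assignment$subject %in% x$meta$subject[isTRUE_vec(x$meta$cyst)]])
      q <- q[q$stratum %in% with_cysts, , drop = FALSE]
      if (nrow(q)) emit(q, "loam_quartiles_excluding_cysts.csv")
      q
    })
  }
  curve <- stage("window_curve", {
    cv <- window_curve(x, width = window, alpha = alpha, z = z)
    emit(dplyr::select(cv, -"members"), "window_curve.csv")
    cv
  })
  crossing <- stage("threshold_crossing", {
    cr <- tibble::tibble(
      threshold_pct = threshold_pct,
      crossing_upper_mm3 = threshold_crossing(curve, threshold_pct, "upper"),
      crossing_point_mm3 = threshold_crossing(curve, threshold_pct, "point")
    )
    emit(cr, "threshold_crossing.csv")
    cr
  })
  regression <- NULL
  if (!is.null(x$meta)) {
    regression <- stage("covariate_regression", {
      r <- covariate_regression(x, select_alpha = alpha)
      emit(r, "regression.csv")
      r
    })
  }
  if (figures) {
    stage("figures", {
      p1 <- plot_agreement(x, assignment, threshold_pct = threshold_pct)
      f1 <- file.path(out_dir, "agreement_quartiles.png")
      ggplot2::ggsave(f1, p1, width = 9, height = 7, dpi = 150)
      p2 <- plot_window_curve(curve, threshold_pct = threshold_pct)
      f2 <- file.path(out_dir, "window_curve.png")
      ggplot2::ggsave(f2, p2, width = 8, height = 5, dpi = 150)
      written <<- c(written, f1, f2)
    })
  }
  stage("provenance", {
    writeLines(paste0(names(prov), ": ", prov), file.path(out_dir, "provenance.txt"))
    written <<- c(written, file.path(out_dir, "provenance.txt"))
  })
  invisible(list(subject_stats = stats_tbl, overall = overall,
                 quartiles = quartiles, quartiles_excl = quartiles_excl,
                 curve = curve, crossing = crossing, regression = regression,
                 files = written))
}

prov_hash <- function(prov, tbl) {
  # cheap, dependency-free content fingerprint for the provenance header
  s <- paste(c(prov, names(tbl)), collapse = "|")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 0xFFFFFFFF)
}

#' Agreement plot: deviations from the subject mean by volume
#'
#' Per-measurement deviation from the subject's own mean (as percent of
#' that mean) against the subject mean volume, one marker shape per
#' observer, faceted by stratum when an assignment is given. Horizontal
#' lines mark each group's estimated LOAM% and the conventional
#' +/- `threshold_pct` reference.
#'
#' @param x An [annotation_matrix()].
#' @param assignment Optional [stratify_quartiles()] result; single panel
#'   when `NULL`.
#' @param threshold_pct Reference limit (default 20; dashed red).
#' @return A ggplot object.
#' @export
plot_agreement <- function(x, assignment = NULL, threshold_pct = 20) {
  stopifnot(inherits(x, "annotation_matrix"))
  st <- subject_stats(x)
  long <- tibble::tibble(
    subject = rep(subject_ids(x), ncol(x$volumes)),
    observer = rep(observer_ids(x), each = nrow(x$volumes)),
    volume = as.vector(x$volumes)
  )
  long <- dplyr::left_join(long, st, by = "subject")
  long$deviation_pct <- 100 * (long$volume - long$mean_volume) / long$mean_volume
  if (!is.null(assignment)) {
    long <- dplyr::left_join(long,
                             assignment[c("subject", "stratum")], by = "subject")
    groups <- split(long$subject, long$stratum)
    loam_lines <- dplyr::bind_rows(lapply(names(groups), function(lab) {
      res <- loam_result(x[unique(groups[[lab]])], n_boot = 0)
      tibble::tibble(stratum = lab, loam_pct = res$loam_pct)
    }))
    loam_lines$stratum <- factor(loam_lines$stratum,
                                 levels = levels(assignment$stratum), ordered = TRUE)
  } else {
    loam_lines <- tibble::tibble(loam_pct = loam_result(x, n_boot = 0)$loam_pct)
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$mean_volume,
                                          y = .data$deviation_pct,
                                          shape = .data$observer)) +
    ggplot2::geom_hline(yintercept = c(-threshold_pct, threshold_pct),
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_hline(data = loam_lines,
                        ggplot2::aes(yintercept = .data$loam_pct),
                        colour = "grey30") +
    ggplot2::geom_hline(data = loam_lines,
                        ggplot2::aes(yintercept = -.data$loam_pct),
                        colour = "grey30") +
    ggplot2::geom_point(alpha = 0.7, colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean observed volume (mm^3)",
                  y = "deviation from subject mean (%)",
                  shape = "observer") +
    ggplot2::theme_bw()
  if (!is.null(assignment))
    p <- p + ggplot2::facet_wrap(~stratum, scales = "free_x")
  p
}

#' Sliding-window agreement curve plot
#'
#' LOAM% with its CI band against window mean volume (log scale), with the
#' conventional threshold as a dashed red reference line.
#'
#' @param curve A [window_curve()].
#' @param threshold_pct Reference limit (default 20).
#' @return A ggplot object.
#' @export
plot_window_curve <- function(curve, threshold_pct = 20) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$mean_volume)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$loam_pct_lo,
                                      ymax = .data$loam_pct_hi),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$loam_pct), linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = threshold_pct, linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "window mean volume (mm^3)", y = "LOAM (% of mean)") +
    ggplot2::theme_bw()
}
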