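#' Construct an annotation matrix
#'
#' The universal input of the pipeline: an `n` subjects by `m` observers grid
#' of volumetric annotations (mm\eqn{^3}), one strictly positive measurement
#' per (subject, observer) cell, plus optional per-subject metadata.
#'
#' @param volumes Numeric matrix, `n x m`, all entries strictly positive.
#'   Row names are taken as subject identifiers and column names as observer
#'   identifiers when `subject_ids` / `observer_ids` are not supplied.
#' @param subject_ids Character vector of unique subject identifiers.
#' @param observer_ids Character vector of unique observer identifiers.
#' @param meta Optional per-subject metadata: a data frame with a `subject`
#'   column matching `subject_ids` (any order) and one row per subject.
#'   Typical columns: `cyst` (logical, peritumoral cystic component),
#'   `laterality` ("L"/"R"), `sex`, `age_at_followup`, `followup_time`,
#'   and imaging acquisition fields (`acquisition_date`, `echo_time`,
#'   `repetition_time`, `flip_angle`, `echo_train_length`, `field_strength`,
#'   `n_slices`, `slice_thickness`, `slice_spacing`, `voxel_spacing`).
#'   Missing values are allowed and preserved; missing volumes are not.
#'
#' @return An object of class `annotation_matrix`: a list with elements
#'   `volumes` (named numeric matrix) and `meta` (tibble or `NULL`).
#' @export
annotation_matrix <- function(volumes, subject_ids = rownames(volumes),
                              observer_ids = colnames(volumes), meta = NULL) {
  volumes <- as.matrix(volumes)
  storage.mode(volumes) <- "double"
  n <- nrow(volumes)
  m <- ncol(volumes)
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(n))
  if (is.null(observer_ids)) observer_ids <- paste0("obs", seq_len(m))
  subject_ids <- as.character(subject_ids)
  observer_ids <- as.character(observer_ids)
  if (n < 2 || m < 2)
    stop("an annotation matrix needs at least 2 subjects and 2 observers, got ",
         n, " x ", m, call. = FALSE)
  if (length(subject_ids) != n || length(observer_ids) != m)
    stop("identifier lengths do not match the volume grid", call. = FALSE)
  if (anyDuplicated(subject_ids))
    stop("subject identifiers must be unique", call. = FALSE)
  if (anyDuplicated(observer_ids))
    stop("observer identifiers must be unique", call. = FALSE)
  if (anyNA(volumes)) {
    idx <- which(is.na(volumes), arr.ind = TRUE)[1, ]
    stop("missing volume for subject '", subject_ids[idx[1]],
         "', observer '", observer_ids[idx[2]], "'", call. = FALSE)
  }
  if (any(volumes <= 0)) {
    idx <- which(volumes <= 0, arr.ind = TRUE)[1, ]
    stop("non-positive volume (", volumes[idx[1], idx[2]], " mm^3) for subject '",
         subject_ids[idx[1]], "', observer '", observer_ids[idx[2]], "'",
         call. = FALSE)
  }
  dimnames(volumes) <- list(subject_ids, observer_ids)
  if (!is.null(meta)) {
    meta <- tibble::as_tibble(meta)
    if (!"subject" %in% names(meta))
      stop("metadata must carry a 'subject' column", call. = FALSE)
    meta$subject <- as.character(meta$subject)
    if (anyDuplicated(meta$subject) || !setequal(meta$subject, subject_ids))
      stop("metadata must have exactly one row per subject", call. = FALSE)
    meta <- meta[match(subject_ids, meta$subject), , drop = FALSE]
    num <- vapply(meta, is.numeric, logical(1))
    for (nm in names(meta)[num]) {
      if (any(meta[[nm]] < 0, na.rm = TRUE))
        stop("metadata field '", nm, "' has negative values", call. = FALSE)
    }
  }
  structure(list(volumes = volumes, meta = meta), class = "annotation_matrix")
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat("<annotation_matrix> ", nrow(x$volumes), " subjects x ",
      ncol(x$volumes), " observers\n", sep = "")
  cat("  volume range: ", format(min(x$volumes), digits = 4), " - ",
      format(max(x$volumes), digits = 4), " mm^3\n", sep = "")
  if (!is.null(x$meta))
    cat("  metadata: ", paste(setdiff(names(x$meta), "subject"), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' @export
dim.annotation_matrix <- function(x) dim(x$volumes)

#' Subset subjects of an annotation matrix
#'
#' @param x An `annotation_matrix`.
#' @param i Subject selector (indices, logical, or ids).
#' @param ... Ignored.
#' @return An `annotation_matrix` restricted to the selected subjects.
#' @export
`[.annotation_matrix` <- function(x, i, ...) {
  vols <- x$volumes[i, , drop = FALSE]
  meta <- x$meta
  if (!is.null(meta)) meta <- meta[match(rownames(vols), meta$subject), , drop = FALSE]
  annotation_matrix(vols, meta = meta)
}

subject_ids <- function(x) rownames(x$volumes)
observer_ids <- function(x) colnames(x$volumes)

#' Read long-format volumetric annotations
#'
#' Reads a delimited text file with one row per (subject, observer)
#' annotation, pivots it to the complete subject-by-observer grid, and
#' validates it. Observer (and subject) order is first-appearance order in
#' the file. Any remaining columns are treated as per-subject metadata and
#' must be constant within subject.
#'
#' @param path Path to a delimited UTF-8 text file with a header row.
#' @param subject_col,observer_col,volume_col Column names.
#' @param delim Field delimiter; `NULL` (default) guesses between comma and
#'   tab from the header line.
#' @return An [annotation_matrix()].
#' @export
read_annotations <- function(path, subject_col = "subject",
                             observer_col = "observer", volume_col = "volume",
                             delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, comment = "#",
                           show_col_types = FALSE, progress = FALSE)
  for (col in c(subject_col, observer_col, volume_col))
    if (!col %in% names(raw))
      stop("column '", col, "' not found in ", path, call. = FALSE)
  subj <- as.character(raw[[subject_col]])
  obs <- as.character(raw[[observer_col]])
  vol <- as.numeric(raw[[volume_col]])
  sids <- unique(subj)
  oids <- unique(obs)
  key <- paste(subj, obs, sep = "\r")
  if (anyDuplicated(key)) {
    d <- strsplit(key[duplicated(key)][1], "\r")[[1]]
    stop("duplicate annotation for subject '", d[1], "', observer '", d[2], "'",
         call. = FALSE)
  }
  vols <- matrix(NA_real_, length(sids), length(oids),
                 dimnames = list(sids, oids))
  vols[cbind(match(subj, sids), match(obs, oids))] <- vol
  if (anyNA(vols)) {
    idx <- which(is.na(vols), arr.ind = TRUE)[1, ]
    stop("incomplete grid: no annotation for subject '", sids[idx[1]],
         "', observer '", oids[idx[2]], "'", call. = FALSE)
  }
  meta_cols <- setdiff(names(raw), c(subject_col, observer_col, volume_col))
  meta <- NULL
  if (length(meta_cols)) {
    meta_raw <- raw[meta_cols]
    meta_raw$subject <- subj
    per_subject <- dplyr::distinct(meta_raw)
    if (anyDuplicated(per_subject$subject)) {
      bad <- per_subject$subject[duplicated(per_subject$subject)][1]
      stop("metadata not constant within subject '", bad, "'", call. = FALSE)
    }
    meta <- per_subject[c("subject", meta_cols)]
  }
  annotation_matrix(vols, meta = meta)
}

#' Write annotations in the long input format
#'
#' Inverse of [read_annotations()]: one row per (subject, observer) with the
#' per-subject metadata repeated on every row.
#'
#' @param x An `annotation_matrix`.
#' @param path Output path (CSV).
#' @export
write_annotations <- function(x, path) {
  stopifnot(inherits(x, "annotation_matrix"))
  long <- tibble::tibble(
    subject = rep(subject_ids(x), times = ncol(x$volumes)),
    observer = rep(observer_ids(x), each = nrow(x$volumes)),
    volume = as.vector(x$volumes)
  )
  long <- long[order(match(long$subject, subject_ids(x))), ]
  if (!is.null(x$meta))
    long <- dplyr::left_join(long, x$meta, by = "subject")
  write_table(long, path)
  invisible(path)
}

#' Write a report table as delimited text
#'
#' Numbers are written at full (round-trip) precision so that reading the
#' file back reproduces the table exactly. An optional provenance header is
#' prepended as `#`-prefixed comment lines, which [read_table_file()] skips.
#'
#' @param rows A non-empty data frame.
#' @param path Output path.
#' @param provenance Optional named character vector written as comment lines.
#' @export
write_table <- function(rows, path, provenance = NULL) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0) stop("refusing to write an empty table", call. = FALSE)
  # list columns (e.g. window member ids) are flattened for serialization
  for (nm in names(rows)) {
    if (is.list(rows[[nm]]))
      rows[[nm]] <- vapply(rows[[nm]], paste, character(1), collapse = ";")
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", names(provenance), ": ", provenance), con)
  # readr serializes doubles with shortest round-trip representation
  writeLines(sub("\n$", "", readr::format_csv(rows)), con)
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path Path to the file.
#' @return A tibble (provenance comment lines skipped).
#' @export
read_table_file <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}
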