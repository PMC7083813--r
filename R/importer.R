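#' Read a slice-measurement file (CSV or Excel)
#'
#' The first four columns are interpreted, in order, as `MB` (bregma-
#' relative anteroposterior coordinate, mm), `M1` (medial reference point
#' to medial lesion edge, mm), `M2` (medial to lateral lesion edge along
#' the cortical surface, mm) and `M3` (lateral lesion edge to rhinal
#' fissure, mm).  A negative `M3` flags a lesion extending lateral to the
#' rhinal fissure; in that convention `M2` is measured from the medial
#' lesion edge to the fissure.  A single leading header row is skipped
#' automatically when any of its first four cells is non-numeric.  Fully
#' empty rows are ignored.  Decimal separator is the point; in CSV the
#' comma is strictly a field separator.
#'
#' @param path path to the measurement file.
#' @param format `"csv"`, `"xls"` or `"xlsx"`; default inferred from the
#'   file extension.  Excel files are read from the first sheet.
#' @param day measurement day (positive integer, default 1).
#' @param modality `"histology"` or `"mri"`.
#' @param slice_depth anteroposterior voxel size in mm; required (and only
#'   allowed) for MRI measurements.
#' @return object of class `measurement_set`: list with `slices` (data
#'   frame `mb`, `m1`, `m2`, `m3`, in file order), `day`, `modality`,
#'   `slice_depth`, `mri_shift_applied`.
#' @export
read_measurements <- function(path, format = NULL, day = 1L,
                              modality = c("histology", "mri"),
                              slice_depth = NULL) {
  modality <- match.arg(modality)
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("csv", "xls", "xlsx")) {
      stop("cannot infer measurement format from extension '", format,
           "'; pass format = \"csv\", \"xls\" or \"xlsx\"")
    }
  }
  format <- match.arg(format, c("csv", "xls", "xlsx"))
  cells <- if (format == "csv") .read_csv_cells(path) else .read_excel_cells(path)
  measurement_set(.parse_measurement_cells(cells), day = day,
                  modality = modality, slice_depth = slice_depth)
}

#' Construct a measurement set from a data frame
#'
#' @param slices data frame with numeric columns `mb`, `m1`, `m2`, `m3`.
#' @inheritParams read_measurements
#' @return `measurement_set` object.
#' @export
measurement_set <- function(slices, day = 1L,
                            modality = c("histology", "mri"),
                            slice_depth = NULL) {
  modality <- match.arg(modality)
  slices <- as.data.frame(slices)
  names(slices)[1:4] <- c("mb", "m1", "m2", "m3")
  if (nrow(slices) < 1L) stop("measurement set must contain at least one slice")
  if (!all(vapply(slices[1:4], is.numeric, logical(1L)))) {
    stop("measurement columns must be numeric")
  }
  bad <- which(slices$m2 <= 0)
  if (length(bad) > 0L) {
    stop("M2 must be positive (row ", bad[1L], " of the measurement set)")
  }
  bad <- which(slices$m1 < 0)
  if (length(bad) > 0L) {
    stop("M1 must be non-negative (row ", bad[1L], " of the measurement set)")
  }
  if (anyDuplicated(slices$mb)) {
    stop("duplicate MB coordinate ", slices$mb[duplicated(slices$mb)][1L],
         ": one medial/lateral edge pair per anteroposterior level is required")
  }
  if (!is.numeric(day) || length(day) != 1L || day < 1 || day != round(day)) {
    stop("day must be a positive integer")
  }
  if (modality == "mri") {
    if (is.null(slice_depth) || !is.numeric(slice_depth) || slice_depth <= 0) {
      stop("slice_depth (mm, > 0) must be specified for MRI measurements")
    }
  } else if (!is.null(slice_depth)) {
    stop("slice_depth applies to MRI measurements only")
  }
  structure(list(slices = slices[, c("mb", "m1", "m2", "m3")],
                 day = as.integer(day),
                 modality = modality,
                 slice_depth = slice_depth,
                 mri_shift_applied = FALSE),
            class = "measurement_set")
}

#' Shift MRI measurements by half the voxel size along the AP axis
#'
#' Accounts for the fact that an MRI slice samples a slab of tissue: the
#' recorded coordinate refers to a slab face while the measurement
#' represents its centre.  Every `mb` is replaced by
#' `mb + direction * slice_depth / 2`; the default shifts anteriorly.  The
#' shift is recorded in the set's metadata and a second application is
#' refused.  Histology sets are returned unchanged with a notice.
#'
#' @param ms a `measurement_set`.
#' @param direction `+1` (anterior, default) or `-1` (posterior).
#' @return the shifted `measurement_set`.
#' @export
apply_mri_shift <- function(ms, direction = 1) {
  stopifnot(inherits(ms, "measurement_set"))
  if (!direction %in% c(-1, 1)) stop("direction must be +1 or -1")
  if (ms$modality != "mri") {
    message("apply_mri_shift: histology measurement set, no shift applied")
    return(ms)
  }
  if (isTRUE(ms$mri_shift_applied)) {
    stop("MRI half-voxel shift has already been applied to this set")
  }
  ms$slices$mb <- ms$slices$mb + direction * ms$slice_depth / 2
  ms$mri_shift_applied <- TRUE
  ms
}

#' Write a measurement set back to CSV
#'
#' Full float precision; column order MB, M1, M2, M3 with a header row.
#'
#' @param ms a `measurement_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(ms, path) {
  stopifnot(inherits(ms, "measurement_set"))
  s <- ms$slices
  lines <- c("MB,M1,M2,M3",
             sprintf("%s,%s,%s,%s",
                     format(s$mb, digits = 17, trim = TRUE, scientific = FALSE),
                     format(s$m1, digits = 17, trim = TRUE, scientific = FALSE),
                     format(s$m2, digits = 17, trim = TRUE, scientific = FALSE),
                     format(s$m3, digits = 17, trim = TRUE, scientific = FALSE)))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("Measurement set: %d slice(s), %s, day %d%s\n",
              nrow(x$slices), x$modality, x$day,
              if (x$modality == "mri")
                sprintf(", slice depth %g mm%s", x$slice_depth,
                        if (x$mri_shift_applied) " (half-voxel shift applied)" else "")
              else ""))
  print(utils::head(x$slices, 10L))
  if (nrow(x$slices) > 10L) cat("  ...\n")
  invisible(x)
}

# --- raw cell readers --------------------------------------------------

.read_csv_cells <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) > 0L) lines[1L] <- sub("^\ufeff", "", lines[1L])
  # tolerate typographic minus signs from copy-pasted tables
  lines <- gsub("\u2212", "-", lines)
  keep <- nzchar(trimws(gsub(",", "", lines)))
  rows <- strsplit(lines, ",", fixed = TRUE)
  list(rows = lapply(rows, trimws), keep = keep)
}

.read_excel_cells <- function(path) {
  df <- readxl::read_excel(path, sheet = 1L, col_names = FALSE,
                           col_types = "text", .name_repair = "minimal")
  df <- as.data.frame(df)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    v <- as.character(unlist(df[i, ], use.names = FALSE))
    v[is.na(v)] <- ""
    gsub("\u2212", "-", trimws(v))
  })
  keep <- vapply(rows, function(v) any(nzchar(v)), logical(1L))
  list(rows = rows, keep = keep)
}

.parse_measurement_cells <- function(cells) {
  rows <- cells$rows
  keep <- cells$keep
  first_data <- TRUE
  out <- list()
  for (i in seq_along(rows)) {
    if (!keep[i]) next
    v <- rows[[i]]
    if (length(v) < 4L) {
      stop("measurement file must have at least 4 columns (MB, M1, M2, M3); ",
           "row ", i, " has ", length(v))
    }
    num <- suppressWarnings(as.numeric(v[1:4]))
    if (first_data) {
      first_data <- FALSE
      if (anyNA(num)) next  # auto-detected header row
    }
    if (anyNA(num)) {
      stop("non-numeric value '", v[1:4][which(is.na(num))[1L]],
           "' in row ", i, " of the measurement file")
    }
    if (num[3L] <= 0) {
      stop("M2 must be positive; row ", i, " has M2 = ", num[3L])
    }
    out[[length(out) + 1L]] <- num
  }
  if (length(out) == 0L) stop("measurement file contains no data rows")
  m <- do.call(rbind, out)
  data.frame(mb = m[, 1L], m1 = m[, 2L], m2 = m[, 3L], m3 = m[, 4L])
}
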