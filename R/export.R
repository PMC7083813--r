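#' Lesion overlay style
#'
#' @param border_color,fill_color hex triplet (`"#rrggbb"`) or R colour
#'   name.
#' @param border_style `"solid"`, `"dashed"` or `"dotted"`.
#' @param border_width line width in device-independent units.
#' @param fill_alpha fill opacity in `[0, 1]`.
#' @param dpi raster resolution, dots per inch (> 0).
#' @return list of class `contour_style`.
#' @export
contour_style <- function(border_color = "#cc0000", fill_color = "#cc0000",
                          border_style = c("solid", "dashed", "dotted"),
                          border_width = 1.5, fill_alpha = 0.35, dpi = 150) {
  border_style <- match.arg(border_style)
  stopifnot(is.numeric(dpi), dpi > 0, fill_alpha >= 0, fill_alpha <= 1,
            border_width > 0)
  .check_color(border_color)
  .check_color(fill_color)
  structure(list(border_color = border_color, fill_color = fill_color,
                 border_style = border_style, border_width = border_width,
                 fill_alpha = fill_alpha, dpi = dpi),
            class = "contour_style")
}

.check_color <- function(col) {
  ok <- grepl("^#[0-9a-fA-F]{6}$", col) || col %in% grDevices::colours()
  if (!ok) stop("invalid colour specification: '", col, "'")
  invisible(col)
}

#' Serialize quantification results to CSV text
#'
#' Header `day,region,area_mm2,percent`; one row per affected region,
#' followed by a `TOTAL` row per day giving the total damaged area and
#' the percentage of the whole cortex.  RFC-4180 comma dialect, UTF-8,
#' LF line endings, values rounded to 2 decimals.
#'
#' @param q a `quantification_result`, a `lesion_series`, or a series
#'   table data frame (columns `day`, `region`, `area_mm2`, `percent`).
#' @param path optional output file; when given, the text is written
#'   there.
#' @return the CSV text, invisibly when `path` is given.
#' @export
results_csv <- function(q, path = NULL) {
  if (inherits(q, "quantification_result")) {
    tab <- rbind(
      if (nrow(q$per_region) > 0L)
        data.frame(day = q$day, q$per_region, stringsAsFactors = FALSE),
      data.frame(day = q$day, region = "TOTAL", area_mm2 = q$total_area_mm2,
                 percent = q$total_percent_of_cortex,
                 stringsAsFactors = FALSE))
  } else if (inherits(q, "lesion_series")) {
    tab <- series_table(q)
  } else {
    tab <- as.data.frame(q)
    stopifnot(all(c("day", "region", "area_mm2", "percent") %in% names(tab)))
  }
  lines <- c("day,region,area_mm2,percent",
             sprintf("%d,%s,%.2f,%.2f", as.integer(tab$day), tab$region,
                     tab$area_mm2, tab$percent))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(enc2utf8(text)), con)
    return(invisible(text))
  }
  text
}

# --- scene drawing -----------------------------------------------------

.svg_col <- function(col, default = NA) {
  if (is.null(col) || is.na(col) || col == "none") return(default)
  col
}

.lty_of <- function(style) {
  switch(style, solid = "solid", dashed = "dashed", dotted = "dotted")
}

# draw the template scene plus lesion overlays on the active device.
# user coordinates = template units, y axis pointing down.
.draw_scene <- function(template, contours, style, extent) {
  op <- graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(xlim = extent$xlim, ylim = rev(extent$ylim),
                        asp = 1)
  for (obj in template$display) {
    st <- obj$style
    if (obj$type == "polygon") {
      graphics::polygon(obj$pts[, 1L], obj$pts[, 2L],
                        col = .svg_col(st$fill), border = .svg_col(st$stroke, "black"),
                        lwd = max(0.1, st$stroke_width),
                        lty = if (!is.null(st$dash) && !is.na(st$dash)) "dashed" else "solid")
    } else if (obj$type == "polyline") {
      graphics::lines(obj$pts[, 1L], obj$pts[, 2L],
                      col = .svg_col(st$stroke, "black"),
                      lwd = max(0.1, st$stroke_width),
                      lty = if (!is.null(st$dash) && !is.na(st$dash)) "dashed" else "solid")
    } else if (obj$type == "text") {
      graphics::text(obj$pts[1L, 1L], obj$pts[1L, 2L], labels = obj$label,
                     col = .svg_col(st$fill, "black"),
                     cex = st$font_size / 12, adj = c(0, 0))
    }
  }
  for (ct in contours) {
    v <- ct$vertices
    if (nrow(v) < 3L) next
    fill <- grDevices::adjustcolor(style$fill_color, alpha.f = style$fill_alpha)
    graphics::polygon(v[, 1L], v[, 2L], col = fill,
                      border = style$border_color,
                      lwd = style$border_width,
                      lty = .lty_of(style$border_style))
  }
  invisible(NULL)
}

.template_extent <- function(template, margin = 0) {
  all_pts <- do.call(rbind, c(lapply(template$display, `[[`, "pts"),
                              list(template$rhinal)))
  list(xlim = range(all_pts[, 1L]) + c(-margin, margin),
       ylim = range(all_pts[, 2L]) + c(-margin, margin))
}

#' Render the unfolded map with lesion overlays to TIFF and PDF
#'
#' Draws every object of the template SVG (including decorative ones)
#' plus the lesion contours in the given style.  The raster output is an
#' uncompressed RGB TIFF whose pixel size follows from the template's
#' physical extent (template units / units-per-mm) and `style$dpi`; the
#' PDF contains the same scene as vector graphics.  Both files are also
#' bundled into a ZIP archive.
#'
#' @param template a `cortex_template`.
#' @param contours list of `lesion_contour` objects (possibly empty).
#' @param style a `contour_style`.
#' @param out_dir output directory (created if missing).
#' @param name file stem for the `.tiff` / `.pdf` outputs.
#' @param bundle_zip name of the ZIP bundle, or `NULL` to skip bundling.
#' @return named character vector of the written file paths, invisibly.
#' @export
render_map <- function(template, contours = list(), style = contour_style(),
                       out_dir = ".", name = "map",
                       bundle_zip = "bundle.zip") {
  stopifnot(inherits(template, "cortex_template"),
            inherits(style, "contour_style"))
  if (inherits(contours, "lesion_contour")) contours <- list(contours)
  .check_color(style$border_color)
  .check_color(style$fill_color)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  extent <- .template_extent(template)
  w_in <- diff(extent$xlim) / template$units_per_mm / 25.4
  h_in <- diff(extent$ylim) / template$units_per_mm / 25.4
  px_w <- max(2L, round(w_in * style$dpi))
  px_h <- max(2L, round(h_in * style$dpi))

  tiff_path <- file.path(out_dir, paste0(name, ".tiff"))
  pdf_path <- file.path(out_dir, paste0(name, ".pdf"))

  png_tmp <- tempfile(fileext = ".png")
  grDevices::png(png_tmp, width = px_w, height = px_h, res = style$dpi,
                 type = "cairo", bg = "white")
  .draw_scene(template, contours, style, extent)
  grDevices::dev.off()
  img <- png::readPNG(png_tmp)
  unlink(png_tmp)
  tiff::writeTIFF(img[, , 1:3, drop = FALSE], tiff_path, compression = "none")

  grDevices::pdf(pdf_path, width = max(w_in, 0.5), height = max(h_in, 0.5),
                 useDingbats = FALSE)
  .draw_scene(template, contours, style, extent)
  grDevices::dev.off()

  paths <- c(tiff = tiff_path, pdf = pdf_path)
  if (!is.null(bundle_zip)) {
    zip_path <- file.path(out_dir, bundle_zip)
    if (file.exists(zip_path)) unlink(zip_path)
    zip::zip(zip_path, files = basename(paths), root = out_dir,
             include_directories = FALSE)
    paths <- c(paths, zip = zip_path)
  }
  invisible(paths)
}

#' Render a raster PNG of the map (used for animation frames)
#'
#' @inheritParams render_map
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
render_png <- function(template, contours, style, path) {
  extent <- .template_extent(template)
  w_in <- diff(extent$xlim) / template$units_per_mm / 25.4
  h_in <- diff(extent$ylim) / template$units_per_mm / 25.4
  grDevices::png(path, width = max(2L, round(w_in * style$dpi)),
                 height = max(2L, round(h_in * style$dpi)),
                 res = style$dpi, type = "cairo", bg = "white")
  .draw_scene(template, contours, style, extent)
  grDevices::dev.off()
  invisible(path)
}

#' Export numbered transition frames for a lesion series
#'
#' Replaces the in-browser video export: consecutive day pairs are
#' aligned with [align_contours()] and linearly interpolated with
#' [interpolate_transition()], writing `frame_0001.png`,
#' `frame_0002.png`, ... into `out_dir`.
#'
#' @param series a `lesion_series` with at least two days.
#' @param template the common `cortex_template`.
#' @param style a `contour_style`.
#' @param out_dir output directory.
#' @param steps_per_transition number of interpolation steps between
#'   consecutive days (including the arrival frame).
#' @return character vector of frame paths, invisibly.
#' @export
render_series_frames <- function(series, template, style = contour_style(),
                                 out_dir = ".", steps_per_transition = 10L) {
  stopifnot(inherits(series, "lesion_series"),
            length(series$days) >= 2L, steps_per_transition >= 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0L)
  frame <- 0L
  emit <- function(ct) {
    frame <<- frame + 1L
    p <- file.path(out_dir, sprintf("frame_%04d.png", frame))
    render_png(template, list(ct), style, p)
    p
  }
  paths <- c(paths, emit(series$entries[[1L]]$contour))
  for (i in seq_len(length(series$days) - 1L)) {
    al <- align_contours(series$entries[[i]]$contour,
                         series$entries[[i + 1L]]$contour)
    for (s in seq_len(steps_per_transition)) {
      tau <- s / steps_per_transition
      paths <- c(paths, emit(interpolate_transition(al$a, al$b, tau)))
    }
  }
  invisible(paths)
}

#' Static time-course chart of affected-region percentages
#'
#' One line per region (plus the cortex total) across measurement days;
#' written as PNG and PDF.
#'
#' @param series a `lesion_series`.
#' @param out_dir output directory.
#' @param basename file stem.
#' @param dpi raster resolution.
#' @return named vector of written paths, invisibly.
#' @export
render_series_chart <- function(series, out_dir = ".", basename = "chart",
                                dpi = 150) {
  tab <- series_table(series)
  regions <- unique(tab$region)
  days <- sort(unique(tab$day))
  mat <- sapply(regions, function(rg) {
    vapply(days, function(d) {
      v <- tab$percent[tab$day == d & tab$region == rg]
      if (length(v) == 0L) 0 else v
    }, numeric(1L))
  })
  mat <- matrix(mat, nrow = length(days), dimnames = list(NULL, regions))
  draw <- function() {
    op <- graphics::par(mar = c(4, 4, 1, 1))
    on.exit(graphics::par(op))
    graphics::matplot(days, mat, type = "b", pch = 19, lty = 1,
                      xlab = "day", ylab = "% of region affected",
                      col = seq_len(ncol(mat)))
    graphics::legend("topleft", legend = colnames(mat),
                     col = seq_len(ncol(mat)), lty = 1, pch = 19, cex = 0.7,
                     bty = "n")
  }
  png_path <- file.path(out_dir, paste0(basename, ".png"))
  pdf_path <- file.path(out_dir, paste0(basename, ".pdf"))
  grDevices::png(png_path, width = 6 * dpi, height = 4 * dpi, res = dpi,
                 type = "cairo", bg = "white")
  draw()
  grDevices::dev.off()
  grDevices::pdf(pdf_path, width = 6, height = 4)
  draw()
  grDevices::dev.off()
  invisible(c(png = png_path, pdf = pdf_path))
}
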