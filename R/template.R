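#' Parse an unfolded-cortex template (SVG + atlas-length JSON)
#'
#' The template SVG follows these labelling conventions:
#' \itemize{
#'   \item each cytoarchitectonic region is a unique closed path labelled
#'     with the prefix `"A_"` (label = `id` attribute, falling back to
#'     `inkscape:label`);
#'   \item the bregma level (anteroposterior zero) is given either by an
#'     `ap_zero` attribute on the root `<svg>` element or by a rectangle
#'     labelled `"ap_zero"` whose `y` position marks the level;
#'   \item the template-units-per-millimetre constant is given either by a
#'     `units_per_mm` root attribute or by a rectangle labelled
#'     `"units_per_mm"` whose width equals the constant.  When both forms
#'     are present, the attribute takes precedence over the rectangle;
#'   \item the rhinal fissure is a path labelled `"rhinal_fissure"`.
#' }
#' Any other SVG object (labels, axes, decorations) is kept for
#' visualisation but ignored by all computations.  Cubic Bezier path
#' segments are flattened to polylines by de Casteljau subdivision before
#' any geometry is computed.
#'
#' @param svg_text the SVG document as a single string (or a file path to
#'   it).
#' @param atlas_json JSON text (or file path) holding the atlas reference
#'   cortical surface lengths: an array of objects with fields `ap`
#'   (bregma-relative anteroposterior coordinate, mm), `medial_to_rhinal`
#'   (mm) and `medial_to_lateral` (mm).
#' @param tolerance Bezier flatness tolerance in template units.
#' @return an object of class `cortex_template`: a list with elements
#'   `regions` (named list of closed polygons, template units), `ap_zero`,
#'   `units_per_mm`, `rhinal` (open polyline), `atlas` (data frame of plate
#'   lengths), `region_areas_mm2`, `cortex_area_mm2` and `display` (drawable
#'   primitives for rendering).
#' @export
parse_template <- function(svg_text, atlas_json, tolerance = 0.01) {
  if (length(svg_text) == 1L && !grepl("<", svg_text, fixed = TRUE) &&
      file.exists(svg_text)) {
    svg_text <- paste(readLines(svg_text, warn = FALSE), collapse = "\n")
  }
  doc <- xml2::read_xml(svg_text)
  root <- xml2::xml_root(doc)
  xml2::xml_ns_strip(doc)

  ap_zero_attr <- .num_attr(root, "ap_zero")
  upm_attr <- .num_attr(root, "units_per_mm")

  regions <- list()
  rhinal <- NULL
  display <- list()
  ap_zero_rect <- NA_real_
  upm_rect <- NA_real_

  for (node in xml2::xml_find_all(doc, "//path | //rect | //line | //polyline | //polygon | //circle | //ellipse | //text")) {
    tag <- xml2::xml_name(node)
    M <- .composed_transform(node)
    label <- .element_label(node)
    style <- .element_style(node)

    if (tag == "rect") {
      x <- .num_attr(node, "x", 0); y <- .num_attr(node, "y", 0)
      w <- .num_attr(node, "width", 0); h <- .num_attr(node, "height", 0)
      corners <- .apply_transform(M, rbind(c(x, y), c(x + w, y),
                                           c(x + w, y + h), c(x, y + h)))
      if (!is.na(label) && label == "ap_zero") {
        ap_zero_rect <- corners[1L, 2L]
      } else if (!is.na(label) && label == "units_per_mm") {
        upm_rect <- sqrt(sum((corners[2L, ] - corners[1L, ])^2))
      }
      display[[length(display) + 1L]] <-
        list(type = "polygon", pts = corners, style = style)
    } else if (tag == "path") {
      subs <- svg_path_to_polylines(xml2::xml_attr(node, "d"), M, tolerance)
      if (!is.na(label) && startsWith(label, "A_")) {
        id <- sub("^A_", "", label)
        if (id %in% names(regions)) {
          stop("duplicate region label in template SVG: A_", id)
        }
        if (length(subs) != 1L || !subs[[1L]]$closed) {
          stop("region path is not a single closed subpath: ", id)
        }
        poly <- subs[[1L]]$pts
        if (nrow(poly) < 3L || polygon_area(poly) <= 0) {
          stop("region polygon is degenerate (zero area): ", id)
        }
        if (!polygon_is_simple(poly)) {
          stop("region polygon self-intersects after flattening: ", id)
        }
        regions[[id]] <- poly
      } else if (!is.na(label) && label == "rhinal_fissure") {
        rhinal <- do.call(rbind, lapply(subs, `[[`, "pts"))
      }
      for (s in subs) {
        display[[length(display) + 1L]] <-
          list(type = if (s$closed) "polygon" else "polyline",
               pts = s$pts, style = style)
      }
    } else if (tag == "line") {
      pts <- .apply_transform(M, rbind(
        c(.num_attr(node, "x1", 0), .num_attr(node, "y1", 0)),
        c(.num_attr(node, "x2", 0), .num_attr(node, "y2", 0))))
      display[[length(display) + 1L]] <-
        list(type = "polyline", pts = pts, style = style)
    } else if (tag %in% c("polyline", "polygon")) {
      v <- as.numeric(regmatches(xml2::xml_attr(node, "points"),
        gregexpr(.svg_num_re, xml2::xml_attr(node, "points"), perl = TRUE))[[1L]])
      pts <- .apply_transform(M, matrix(v, ncol = 2L, byrow = TRUE))
      display[[length(display) + 1L]] <-
        list(type = if (tag == "polygon") "polygon" else "polyline",
             pts = pts, style = style)
    } else if (tag == "text") {
      pos <- .apply_transform(M, c(.num_attr(node, "x", 0),
                                   .num_attr(node, "y", 0)))
      display[[length(display) + 1L]] <-
        list(type = "text", pts = matrix(pos, ncol = 2L),
             label = xml2::xml_text(node), style = style)
    }
  }

  ap_zero <- if (!is.na(ap_zero_attr)) ap_zero_attr else ap_zero_rect
  units_per_mm <- if (!is.na(upm_attr)) upm_attr else upm_rect
  if (is.na(ap_zero)) {
    stop("template defines no ap_zero: provide an 'ap_zero' svg attribute ",
         "or a rectangle labelled 'ap_zero'")
  }
  if (is.na(units_per_mm) || units_per_mm <= 0) {
    stop("template defines no positive units_per_mm: provide a ",
         "'units_per_mm' svg attribute or a rectangle labelled 'units_per_mm'")
  }
  if (length(regions) == 0L) {
    stop("template contains no region paths (labelled with prefix 'A_')")
  }
  if (is.null(rhinal) || nrow(rhinal) < 2L) {
    stop("template contains no 'rhinal_fissure' path")
  }

  atlas <- read_atlas_lengths(atlas_json)

  tmpl <- structure(list(
    regions = regions,
    ap_zero = ap_zero,
    units_per_mm = units_per_mm,
    rhinal = rhinal,
    atlas = atlas,
    display = display
  ), class = "cortex_template")
  tmpl$region_areas_mm2 <- vapply(regions, polygon_area, numeric(1L)) /
    units_per_mm^2
  tmpl$cortex_area_mm2 <- sum(tmpl$region_areas_mm2)

  # the fissure must laterally anchor every atlas plate's AP level
  plate_y <- ap_zero - units_per_mm * atlas$ap
  yr <- range(tmpl$rhinal[, 2L])
  if (any(plate_y < yr[1L] - 1e-9 | plate_y > yr[2L] + 1e-9)) {
    stop("rhinal_fissure path does not span the anteroposterior extent ",
         "covered by the atlas plates")
  }
  tmpl
}

#' Read and validate an atlas-lengths JSON file
#'
#' @param atlas_json JSON text or path to a JSON file: array of objects
#'   `{ "ap": <mm>, "medial_to_rhinal": <mm>, "medial_to_lateral": <mm> }`.
#' @param loader optional function mapping the parsed JSON to a data frame
#'   with those three columns, for atlas files using a different layout.
#' @return data frame sorted anterior (largest `ap`) first.
#' @export
read_atlas_lengths <- function(atlas_json, loader = NULL) {
  if (length(atlas_json) == 1L && !grepl("[{\\[]", atlas_json) &&
      file.exists(atlas_json)) {
    atlas_json <- paste(readLines(atlas_json, warn = FALSE), collapse = "\n")
  }
  a <- jsonlite::fromJSON(atlas_json)
  if (!is.null(loader)) a <- loader(a)
  a <- as.data.frame(a)
  req <- c("ap", "medial_to_rhinal", "medial_to_lateral")
  if (!all(req %in% names(a))) {
    stop("atlas lengths JSON must provide fields: ",
         paste(req, collapse = ", "))
  }
  a <- a[req]
  if (nrow(a) < 1L || anyNA(a)) stop("atlas lengths contain missing values")
  d <- diff(a$ap)
  if (length(d) > 0L && !(all(d > 0) || all(d < 0))) {
    stop("atlas plate ap coordinates must be strictly monotone")
  }
  if (any(a$medial_to_rhinal <= 0) || any(a$medial_to_lateral <= 0)) {
    stop("atlas lengths must be positive")
  }
  if (any(a$medial_to_lateral < a$medial_to_rhinal - 1e-12)) {
    stop("medial_to_lateral must be >= medial_to_rhinal on every plate")
  }
  a[order(-a$ap), , drop = FALSE]
}

#' Atlas reference length at an anteroposterior level
#'
#' Returns the requested surface length of the coronal plate whose `ap`
#' coordinate is nearest to `mb`; ties midway between two plates resolve to
#' the anterior (larger `ap`) plate, matching the manual practice of
#' assigning a section to an atlas plate.
#'
#' @param atlas data frame from [read_atlas_lengths()], or a
#'   `cortex_template`.
#' @param mb bregma-relative anteroposterior coordinate, mm (anterior
#'   positive).  Must lie within half a plate spacing of the plate range.
#' @param which `"medial_to_rhinal"` or `"medial_to_lateral"`.
#' @return length in mm.
#' @export
atlas_length_at <- function(atlas, mb,
                            which = c("medial_to_rhinal", "medial_to_lateral")) {
  if (inherits(atlas, "cortex_template")) atlas <- atlas$atlas
  which <- match.arg(which)
  stopifnot(is.numeric(mb), length(mb) == 1L, is.finite(mb))
  spacing <- if (nrow(atlas) > 1L) stats::median(abs(diff(atlas$ap))) else 0.2
  lo <- min(atlas$ap) - spacing / 2
  hi <- max(atlas$ap) + spacing / 2
  if (mb < lo || mb > hi) {
    stop(sprintf("anteroposterior coordinate %.3f mm is outside the template span [%.3f, %.3f] mm",
                 mb, lo, hi))
  }
  d <- abs(atlas$ap - mb)
  cand <- which(d == min(d))
  if (length(cand) > 1L) cand <- cand[which.max(atlas$ap[cand])]
  atlas[[which]][cand]
}

#' Mediolateral position of the rhinal fissure at a template ordinate
#'
#' Linear interpolation of the fissure polyline at ordinate `y` (template
#' units; y increases posteriorly).
#'
#' @param template a `cortex_template`.
#' @param y ordinate in template units, within the polyline's extent.
#' @return x in template units.
#' @export
rhinal_x_at <- function(template, y) {
  stopifnot(inherits(template, "cortex_template"),
            is.numeric(y), length(y) == 1L, is.finite(y))
  p <- template$rhinal
  ys <- p[, 2L]
  if (y < min(ys) - 1e-9 || y > max(ys) + 1e-9) {
    stop(sprintf("ordinate %.4f outside the rhinal fissure extent [%.4f, %.4f]",
                 y, min(ys), max(ys)))
  }
  # segment-wise interpolation; the polyline need not be globally sorted
  for (i in seq_len(nrow(p) - 1L)) {
    y0 <- p[i, 2L]; y1 <- p[i + 1L, 2L]
    if ((y >= min(y0, y1) - 1e-9) && (y <= max(y0, y1) + 1e-9)) {
      if (abs(y1 - y0) < 1e-12) return(p[i, 1L])
      t <- (y - y0) / (y1 - y0)
      return(p[i, 1L] + t * (p[i + 1L, 1L] - p[i, 1L]))
    }
  }
  # numeric fuzz at the extremes
  if (abs(y - ys[which.min(ys)]) < 1e-6) return(p[which.min(ys), 1L])
  p[which.max(ys), 1L]
}

#' Medial cortex boundary at a template ordinate
#'
#' The smallest x at which the horizontal line at `y` meets any region
#' polygon; used to clip implausible medial lesion edges.  Returns `NA`
#' when the line misses the cortex entirely.
#'
#' @inheritParams rhinal_x_at
#' @return x in template units, or `NA`.
#' @keywords internal
template_medial_x_at <- function(template, y) {
  xs <- numeric(0L)
  for (poly in template$regions) {
    n <- nrow(poly)
    nxt <- c(seq_len(n)[-1L], 1L)
    y0 <- poly[, 2L]; y1 <- poly[nxt, 2L]
    hit <- (pmin(y0, y1) <= y) & (pmax(y0, y1) >= y) & (abs(y1 - y0) > 1e-12)
    if (any(hit)) {
      t <- (y - y0[hit]) / (y1[hit] - y0[hit])
      xs <- c(xs, poly[hit, 1L] + t * (poly[nxt, 1L][hit] - poly[hit, 1L]))
    }
  }
  if (length(xs) == 0L) NA_real_ else min(xs)
}

#' @export
print.cortex_template <- function(x, ...) {
  ap <- range(x$atlas$ap)
  cat("Unfolded cortex template\n")
  cat(sprintf("  regions: %d (total cortex area %.2f mm^2)\n",
              length(x$regions), x$cortex_area_mm2))
  cat(sprintf("  units per mm: %g; ap_zero (bregma ordinate): %g\n",
              x$units_per_mm, x$ap_zero))
  cat(sprintf("  atlas plates: %d, AP %+.2f to %+.2f mm\n",
              nrow(x$atlas), ap[2L], ap[1L]))
  invisible(x)
}

# --- small node helpers ------------------------------------------------

.num_attr <- function(node, name, default = NA_real_) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) return(default)
  suppressWarnings(as.numeric(v))
}

# label = id attribute, falling back to inkscape:label
.element_label <- function(node) {
  id <- xml2::xml_attr(node, "id")
  if (!is.na(id) && nzchar(id)) return(id)
  at <- xml2::xml_attrs(node)
  lab <- at[grepl("(^|:)label$", names(at))]
  if (length(lab) > 0L && nzchar(lab[[1L]])) return(lab[[1L]])
  NA_character_
}

.element_style <- function(node) {
  st <- list(fill = xml2::xml_attr(node, "fill"),
             stroke = xml2::xml_attr(node, "stroke"),
             stroke_width = .num_attr(node, "stroke-width", 1),
             dash = xml2::xml_attr(node, "stroke-dasharray"),
             font_size = .num_attr(node, "font-size", 10))
  css <- xml2::xml_attr(node, "style")
  if (!is.na(css)) {
    for (kv in strsplit(css, ";", fixed = TRUE)[[1L]]) {
      p <- trimws(strsplit(kv, ":", fixed = TRUE)[[1L]])
      if (length(p) == 2L) {
        if (p[1L] == "fill") st$fill <- p[2L]
        if (p[1L] == "stroke") st$stroke <- p[2L]
        if (p[1L] == "stroke-width") {
          st$stroke_width <- suppressWarnings(as.numeric(gsub("[a-z]", "", p[2L])))
        }
        if (p[1L] == "stroke-dasharray") st$dash <- p[2L]
      }
    }
  }
  st
}

# compose transform attributes from root to node
.composed_transform <- function(node) {
  chain <- list()
  n <- node
  repeat {
    tr <- xml2::xml_attr(n, "transform")
    if (!is.na(tr)) chain <- c(list(tr), chain)
    parent <- tryCatch(xml2::xml_parent(n), error = function(e) NULL)
    if (is.null(parent) || inherits(parent, "xml_missing")) break
    n <- parent
  }
  M <- diag(3)
  for (tr in chain) M <- M %*% parse_svg_transform(tr)
  M
}
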