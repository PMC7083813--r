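# Shared fixtures and independent oracles used across the suite.

# random star-shaped polygon: simple by construction (angles jittered
# around an even spread, so no angular gap reaches pi and every chord
# stays on the centre's side)
star_polygon <- function(n_vertices = 12L, r_min = 0.3, r_max = 1,
                         center = c(0, 0)) {
  step <- 2 * pi / n_vertices
  ang <- (seq_len(n_vertices) - 1L) * step +
    stats::runif(n_vertices, 0.05, 0.95) * step
  rad <- stats::runif(n_vertices, r_min, r_max)
  cbind(center[1L] + rad * cos(ang), center[2L] + rad * sin(ang))
}

# Monte-Carlo area oracle (rejection sampling over the bounding box)
mc_polygon_area <- function(p, n = 1e6) {
  xr <- range(p[, 1L]); yr <- range(p[, 2L])
  px <- stats::runif(n, xr[1L], xr[2L])
  py <- stats::runif(n, yr[1L], yr[2L])
  inside <- sp::point.in.polygon(px, py, p[, 1L], p[, 2L]) > 0
  mean(inside) * diff(xr) * diff(yr)
}

# fine-grid rasterization oracle for intersection area
raster_intersection_area <- function(a, b, n_grid = 1000L) {
  xr <- c(max(min(a[, 1L]), min(b[, 1L])), min(max(a[, 1L]), max(b[, 1L])))
  yr <- c(max(min(a[, 2L]), min(b[, 2L])), min(max(a[, 2L]), max(b[, 2L])))
  if (xr[1L] >= xr[2L] || yr[1L] >= yr[2L]) return(0)
  gx <- seq(xr[1L], xr[2L], length.out = n_grid + 1L)
  gy <- seq(yr[1L], yr[2L], length.out = n_grid + 1L)
  cx <- (gx[-1L] + gx[-length(gx)]) / 2
  cy <- (gy[-1L] + gy[-length(gy)]) / 2
  pts <- expand.grid(x = cx, y = cy)
  in_a <- sp::point.in.polygon(pts$x, pts$y, a[, 1L], a[, 2L]) > 0
  in_b <- sp::point.in.polygon(pts$x, pts$y, b[, 1L], b[, 2L]) > 0
  mean(in_a & in_b) * diff(xr) * diff(yr)
}

# Barry-Goldman pyramid: independent evaluation of the parameterised
# Catmull-Rom segment P2 -> P3 of a 4-point window, at fraction s in [0,1]
bg_catmull_rom <- function(P, alpha, s) {
  t <- numeric(4L)
  for (i in 2:4) t[i] <- t[i - 1L] + sum((P[i, ] - P[i - 1L, ])^2)^(alpha / 2)
  u <- t[2L] + s * (t[3L] - t[2L])
  lerp <- function(a, b, ta, tb) {
    if (tb == ta) a else ((tb - u) * a + (u - ta) * b) / (tb - ta)
  }
  A1 <- lerp(P[1L, ], P[2L, ], t[1L], t[2L])
  A2 <- lerp(P[2L, ], P[3L, ], t[2L], t[3L])
  A3 <- lerp(P[3L, ], P[4L, ], t[3L], t[4L])
  B1 <- lerp(A1, A2, t[1L], t[3L])
  B2 <- lerp(A2, A3, t[2L], t[4L])
  lerp(B1, B2, t[2L], t[3L])
}

# max over `pts` of the distance to the polyline `poly` (segments, not
# just vertices)
max_dist_to_polyline <- function(pts, poly) {
  n <- nrow(poly)
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(n - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 > 0) {
      pmax(0, pmin(1, ((pts[, 1L] - a[1L]) * ab[1L] +
                       (pts[, 2L] - a[2L]) * ab[2L]) / len2))
    } else 0
    d2 <- (pts[, 1L] - a[1L] - t * ab[1L])^2 +
          (pts[, 2L] - a[2L] - t * ab[2L])^2
    best <- pmin(best, d2)
  }
  sqrt(max(best))
}

# standard kappa constant for circle-from-four-cubics approximation
circle_kappa <- 0.5522847498307936

# four-cubic-Bezier circle as an SVG path d string
circle_path_d <- function(cx, cy, r) {
  k <- circle_kappa * r
  sprintf(paste0("M %g %g C %g %g %g %g %g %g C %g %g %g %g %g %g ",
                 "C %g %g %g %g %g %g C %g %g %g %g %g %g Z"),
          cx + r, cy,
          cx + r, cy + k, cx + k, cy + r, cx, cy + r,
          cx - k, cy + r, cx - r, cy + k, cx - r, cy,
          cx - r, cy - k, cx - k, cy - r, cx, cy - r,
          cx + k, cy - r, cx + r, cy - k, cx + r, cy)
}

# minimal hand-built template SVG: given body elements and optional root
# attributes, wrapped in an svg element
svg_doc <- function(body, root_attrs = "") {
  paste0('<svg xmlns="http://www.w3.org/2000/svg" width="400" height="400" ',
         root_attrs, ">\n", paste(body, collapse = "\n"), "\n</svg>")
}

# simplest valid template pieces: one 10x10 square region, vertical fissure
basic_region <- '<path id="A_S1" d="M 50 50 L 60 50 L 60 60 L 50 60 Z"/>'
basic_fissure <- '<path id="rhinal_fissure" d="M 100 0 L 100 400"/>'

basic_atlas_json <- function(ap = c(1, 0, -1), mr = 4, ml = 5) {
  jsonlite::toJSON(data.frame(ap = ap, medial_to_rhinal = mr,
                              medial_to_lateral = ml),
                   dataframe = "rows", auto_unbox = TRUE)
}

# default synthetic template, parsed once per test file
make_default_template <- function(...) {
  syn <- generate_synthetic_template(...)
  list(syn = syn, template = parse_template(syn$svg, syn$atlas_json))
}

# write a minimal .xlsx (OOXML spreadsheet) so the Excel reading path can
# be exercised without a binary fixture; numbers as numeric cells, strings
# as inline strings
make_xlsx <- function(rows, path) {
  dir <- tempfile("xlsx")
  dir.create(file.path(dir, "_rels"), recursive = TRUE)
  dir.create(file.path(dir, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(dir, "xl", "worksheets"), recursive = TRUE)
  w <- function(rel, text) writeLines(text, file.path(dir, rel))
  w("[Content_Types].xml", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    "</Types>"))
  w("_rels/.rels", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>"))
  w("xl/workbook.xml", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="Sheet1" sheetId="1" r:id="rId1"/></sheets></workbook>'))
  w("xl/_rels/workbook.xml.rels", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    "</Relationships>"))
  cell <- function(ref, v) {
    if (is.numeric(v)) {
      sprintf('<c r="%s"><v>%.17g</v></c>', ref, v)
    } else {
      sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>', ref, v)
    }
  }
  body <- vapply(seq_along(rows), function(i) {
    refs <- paste0(LETTERS[seq_along(rows[[i]])], i)
    paste0('<row r="', i, '">',
           paste(mapply(cell, refs, rows[[i]]), collapse = ""), "</row>")
  }, character(1L))
  w("xl/worksheets/sheet1.xml", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    "<sheetData>", paste(body, collapse = ""), "</sheetData></worksheet>"))
  old <- setwd(dir)
  on.exit(setwd(old))
  zip::zip(path, files = c("[Content_Types].xml", "_rels/.rels",
                           "xl/workbook.xml", "xl/_rels/workbook.xml.rels",
                           "xl/worksheets/sheet1.xml"),
           mode = "mirror")
  invisible(path)
}
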