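#' Generate a synthetic unfolded-cortex template
#'
#' Builds a fully self-consistent template for testing and demonstration:
#' a grid of rectangular "regions" spanning the requested anteroposterior
#' extent, a straight vertical rhinal fissure at the grid's lateral edge,
#' `ap_zero` and `units_per_mm` encoded as attributes of the root `<svg>`
#' element, and a matching atlas-lengths JSON.  Cell heights equal the AP
#' span divided by the number of grid rows, and cells are square by
#' default, so e.g. `n_regions = 4` with `ap_span = c(1, -1)` yields a
#' 2x2 grid of 1 mm^2 regions.  With `jitter > 0` the interior column cuts
#' are perturbed (deterministically per `seed`), producing regions of
#' unequal, exactly known areas.
#'
#' The output is byte-deterministic for fixed arguments and round-trips
#' through [parse_template()].
#'
#' @param n_regions number of regions (>= 1).
#' @param ap_span length-2 numeric, anterior and posterior bregma-relative
#'   limits in mm (anterior first, larger value).  Default matches the
#'   published mouse template span, +3.20 to -4.96 mm.
#' @param units_per_mm template units per millimetre (> 0).
#' @param seed integer seed controlling the jitter stream.
#' @param n_plates number of atlas coronal plates spanning `ap_span`.
#' @param jitter relative jitter (0..0.4) of interior column boundaries.
#' @return list with elements `svg` (SVG text), `atlas_json` (JSON text)
#'   and `truth` (data frame: region id, area in mm^2 and template
#'   units^2), plus the layout constants `units_per_mm`, `ap_zero`,
#'   `fissure_x`, `medial_x`, `width_mm`.
#' @export
generate_synthetic_template <- function(n_regions = 16L,
                                        ap_span = c(3.20, -4.96),
                                        units_per_mm = 10,
                                        seed = 1L,
                                        n_plates = 40L,
                                        jitter = 0) {
  stopifnot(n_regions >= 1L, length(ap_span) == 2L, ap_span[1L] > ap_span[2L],
            units_per_mm > 0, n_plates >= 2L, jitter >= 0, jitter <= 0.4)
  r <- units_per_mm
  span_mm <- ap_span[1L] - ap_span[2L]
  ncols <- as.integer(ceiling(sqrt(n_regions)))
  nrows <- as.integer(ceiling(n_regions / ncols))
  cell_h_mm <- span_mm / nrows
  width_mm <- ncols * cell_h_mm

  medial_x <- 10                      # template-unit left margin
  y_top <- 10                         # ordinate of the anterior edge
  ap_zero <- y_top + r * ap_span[1L]  # y = ap_zero - r * mb
  fissure_x <- medial_x + r * width_mm
  y_bot <- y_top + r * span_mm

  set.seed(as.integer(seed) %% .Machine$integer.max)
  fmt <- function(v) sprintf("%.9g", v)

  # row-wise column cuts; the last row absorbs any cell deficit
  rows <- vector("list", nrows)
  left <- n_regions
  for (i in seq_len(nrows)) {
    k <- if (i < nrows) min(ncols, left - (nrows - i)) else left
    cuts <- medial_x + (fissure_x - medial_x) * seq(0, 1, length.out = k + 1L)
    if (jitter > 0 && k > 1L) {
      w <- (fissure_x - medial_x) / k
      cuts[2:k] <- cuts[2:k] + stats::runif(k - 1L, -jitter, jitter) * w
    }
    rows[[i]] <- cuts
    left <- left - k
  }

  paths <- character(0L)
  labels <- character(0L)
  truth <- data.frame(region = character(0L), area_units2 = numeric(0L))
  idx <- 0L
  for (i in seq_len(nrows)) {
    yt <- y_top + (i - 1L) * r * cell_h_mm
    yb <- yt + r * cell_h_mm
    cuts <- rows[[i]]
    for (j in seq_len(length(cuts) - 1L)) {
      idx <- idx + 1L
      id <- sprintf("R%02d", idx)
      x0 <- cuts[j]; x1 <- cuts[j + 1L]
      paths <- c(paths, sprintf(
        '  <path id="A_%s" d="M %s %s L %s %s L %s %s L %s %s Z" fill="none" stroke="#888888" stroke-width="0.5"/>',
        id, fmt(x0), fmt(yt), fmt(x1), fmt(yt), fmt(x1), fmt(yb), fmt(x0), fmt(yb)))
      labels <- c(labels, sprintf(
        '  <text x="%s" y="%s" font-size="4" fill="#555555">%s</text>',
        fmt((x0 + x1) / 2 - 3), fmt((yt + yb) / 2 + 1), id))
      truth <- rbind(truth, data.frame(region = id,
                                       area_units2 = (x1 - x0) * (yb - yt)))
    }
  }
  truth$area_mm2 <- truth$area_units2 / r^2

  # fissure extended by half a plate spacing beyond the plate range
  plate_ap <- seq(ap_span[1L], ap_span[2L], length.out = n_plates)
  half <- abs(plate_ap[1L] - plate_ap[2L]) / 2
  fy0 <- ap_zero - r * (ap_span[1L] + half)
  fy1 <- ap_zero - r * (ap_span[2L] - half)

  svg <- paste(c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" units_per_mm="%s" ap_zero="%s">',
            fmt(fissure_x + 10), fmt(y_bot + 10), fmt(r), fmt(ap_zero)),
    paths,
    sprintf('  <path id="rhinal_fissure" d="M %s %s L %s %s" fill="none" stroke="#000000" stroke-dasharray="3,2"/>',
            fmt(fissure_x), fmt(fy0), fmt(fissure_x), fmt(fy1)),
    sprintf('  <line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#aaaaaa" stroke-width="0.3"/>',
            fmt(medial_x - 5), fmt(ap_zero), fmt(fissure_x + 5), fmt(ap_zero)),
    labels,
    "</svg>"), collapse = "\n")

  atlas <- data.frame(ap = plate_ap,
                      medial_to_rhinal = width_mm,
                      medial_to_lateral = width_mm * 1.3)
  atlas_json <- paste0("[\n", paste(sprintf(
    '  {"ap": %s, "medial_to_rhinal": %s, "medial_to_lateral": %s}',
    fmt(atlas$ap), fmt(atlas$medial_to_rhinal), fmt(atlas$medial_to_lateral)),
    collapse = ",\n"), "\n]\n")

  list(svg = svg, atlas_json = atlas_json, truth = truth,
       units_per_mm = r, ap_zero = ap_zero, fissure_x = fissure_x,
       medial_x = medial_x, width_mm = width_mm, ap_span = ap_span)
}
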