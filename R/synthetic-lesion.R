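#' Paint a ground-truth elliptical lesion on a synthetic template
#'
#' Defines a smooth lesion directly in atlas space: at each
#' anteroposterior coordinate `mb` inside the lesion span, the medial and
#' lateral lesion edges sit at `u_center +/- e(mb)` millimetres medial of
#' the rhinal fissure, where `e(mb)` traces an ellipse of AP half-width
#' `ap_halfwidth` and maximal mediolateral half-width `ml_halfwidth`.
#' Negative lateral distances (lesion crossing the fissure) are allowed.
#' The exact lesion polygon in template coordinates and its analytic area
#' are returned alongside a sampler that converts the lesion into
#' M1/M2/M3/MB slice measurements with an optional per-slice shrinkage
#' factor, mimicking how a researcher would measure shrunk tissue.
#'
#' @param template_info list returned by [generate_synthetic_template()]
#'   (the layout constants are needed to place the lesion analytically).
#' @param center_mb lesion centre, bregma-relative mm.
#' @param ap_halfwidth AP half-width of the ellipse, mm.
#' @param ml_halfwidth maximal mediolateral half-width, mm.
#' @param u_center distance of the lesion centre medial of the rhinal
#'   fissure, mm (negative parts of the ellipse cross the fissure).
#' @param n_dense number of dense boundary samples per edge for the
#'   ground-truth polygon.
#' @return list with `polygon` (template units), `area_mm2` (shoelace
#'   area of the dense polygon), `area_analytic_mm2` (pi * a * b) and the
#'   lesion parameters.
#' @export
synthetic_lesion_truth <- function(template_info, center_mb = -1,
                                   ap_halfwidth = 1.8, ml_halfwidth = 1.2,
                                   u_center = 2, n_dense = 2000L) {
  r <- template_info$units_per_mm
  ap0 <- template_info$ap_zero
  fx <- template_info$fissure_x
  mb <- seq(center_mb - ap_halfwidth, center_mb + ap_halfwidth,
            length.out = n_dense)
  e <- ml_halfwidth * sqrt(pmax(0, 1 - ((mb - center_mb) / ap_halfwidth)^2))
  u_med <- u_center + e   # medial edge, mm medial of the fissure
  u_lat <- u_center - e   # lateral edge
  y <- ap0 - r * mb
  med <- cbind(fx - r * u_med, y)
  lat <- cbind(fx - r * u_lat, y)
  poly <- rbind(med[order(mb), , drop = FALSE],
                lat[rev(order(mb)), , drop = FALSE])
  list(polygon = poly,
       area_mm2 = polygon_area(poly) / r^2,
       area_analytic_mm2 = pi * ap_halfwidth * ml_halfwidth,
       center_mb = center_mb, ap_halfwidth = ap_halfwidth,
       ml_halfwidth = ml_halfwidth, u_center = u_center,
       template_info = template_info)
}

#' Sample slice measurements from a ground-truth lesion
#'
#' Cuts the ground-truth lesion into coronal slices at the given AP
#' spacing and emits the M1/M2/M3/MB quadruples a researcher would
#' record, applying a per-slice shrinkage factor to every along-surface
#' distance (the normalization step must undo it).  Slices crossing the
#' rhinal fissure follow the negative-M3 convention: M2 then runs from
#' the medial lesion edge to the fissure.
#'
#' @param truth list from [synthetic_lesion_truth()].
#' @param spacing slice spacing in mm (default 0.2).
#' @param shrinkage scalar or function of `mb` giving the multiplicative
#'   tissue-shrinkage factor applied to measured distances (1 = none).
#' @param day,modality,slice_depth metadata for the resulting set.
#' @return a `measurement_set`.
#' @export
synthetic_lesion_measurements <- function(truth, spacing = 0.2,
                                          shrinkage = 1, day = 1L,
                                          modality = "histology",
                                          slice_depth = NULL) {
  ti <- truth$template_info
  L <- ti$width_mm            # atlas medial-to-rhinal length (constant)
  a <- truth$ap_halfwidth
  c0 <- truth$center_mb
  # keep strictly inside the ellipse so every slice has positive width
  mb <- seq(c0 - a + spacing / 2, c0 + a - spacing / 2, by = spacing)
  e <- truth$ml_halfwidth * sqrt(pmax(0, 1 - ((mb - c0) / a)^2))
  u_med <- truth$u_center + e
  u_lat <- truth$u_center - e
  shr <- if (is.function(shrinkage)) vapply(mb, shrinkage, numeric(1L)) else
    rep(shrinkage, length(mb))
  m1 <- (L - u_med) * shr
  crossing <- u_lat < 0
  m2 <- ifelse(crossing, u_med, u_med - u_lat) * shr
  m3 <- u_lat * shr
  measurement_set(data.frame(mb = mb, m1 = m1, m2 = m2, m3 = m3),
                  day = day, modality = modality, slice_depth = slice_depth)
}
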