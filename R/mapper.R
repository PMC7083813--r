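#' Normalize one slice measurement against the atlas surface length
#'
#' Corrects for brain-size differences and tissue shrinkage between the
#' experimental case and the atlas-based template.  The measured
#' inter-reference distance `D` (medial reference point to rhinal fissure
#' along the cortical surface) is `m1 + m2 + m3` when the lesion lies
#' medial to the fissure (`m3 >= 0`), and `m1 + m2` when the lesion
#' crosses the fissure (`m3 < 0`, where `m2` by convention runs from the
#' medial lesion edge to the fissure).  The scale ratio is the atlas
#' medial-to-rhinal length at the slice's anteroposterior level divided by
#' `D`, and `m2`, `m3` are multiplied by it.  `m1` is not carried forward:
#' the adjusted `m2` and `m3` suffice to localise the lesion against the
#' fissure.
#'
#' @param s one slice: list or one-row data frame with `mb`, `m1`, `m2`,
#'   `m3` (mm).
#' @param atlas atlas lengths data frame (or a `cortex_template`).
#' @return list with `mb`, `m2_adj`, `m3_adj`, `scale_ratio`.
#' @export
normalize_slice <- function(s, atlas) {
  mb <- as.numeric(s[["mb"]]); m1 <- as.numeric(s[["m1"]])
  m2 <- as.numeric(s[["m2"]]); m3 <- as.numeric(s[["m3"]])
  stopifnot(is.finite(mb), is.finite(m1), is.finite(m2), is.finite(m3))
  if (m2 <= 0) stop("M2 must be positive")
  if (m1 < 0) stop("M1 must be non-negative")
  D <- if (m3 >= 0) m1 + m2 + m3 else m1 + m2
  if (D <= 0) stop("inter-reference distance must be positive at mb = ", mb)
  L <- atlas_length_at(atlas, mb, "medial_to_rhinal")
  ratio <- L / D
  if (ratio < 0.25 || ratio > 4) {
    warning(sprintf(
      "implausible scale ratio %.3f at mb = %.2f (atlas %.2f mm vs measured %.2f mm)",
      ratio, mb, L, D))
  }
  list(mb = mb, m2_adj = m2 * ratio, m3_adj = m3 * ratio, scale_ratio = ratio)
}

#' Translate normalized slices into template-coordinate edge polylines
#'
#' Uses the template's units-per-millimetre constant `r` and the rhinal
#' fissure as the lateral reference: for each slice at bregma-relative
#' coordinate `mb`, the ordinate is `y = ap_zero - r * mb` (anterior at
#' the top), the lateral lesion edge sits at
#' `x = rhinal_x(y) - r * m3_adj` (beyond the fissure when `m3 < 0`), and
#' the medial edge at `x = lateral_x - r * m2_adj`.  Slices are sorted by
#' ascending `mb` before assembly.  A medial edge falling medial to the
#' cortex boundary is clipped to it with a warning.
#'
#' An alternative midline-anchored reading (`anchor = "midline"`:
#' medial edge at `r * m1` from the template's medial border, lateral edge
#' `r * m2_adj` lateral of it) is provided for comparison but is not the
#' default; it requires `m1` in each element of `adj`.
#'
#' @param adj list of normalized slices from [normalize_slice()].
#' @param template a `cortex_template`.
#' @param anchor `"fissure"` (default) or `"midline"`.
#' @return list with `medial`, `lateral` (n x 2 matrices, ascending mb)
#'   and `mb` (sorted coordinates).
#' @export
translate_slices <- function(adj, template, anchor = c("fissure", "midline")) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(template, "cortex_template"), length(adj) >= 1L)
  r <- template$units_per_mm
  mb <- vapply(adj, `[[`, numeric(1L), "mb")
  o <- order(mb)
  adj <- adj[o]
  mb <- mb[o]
  y <- template$ap_zero - r * mb
  med <- matrix(NA_real_, length(adj), 2L)
  lat <- matrix(NA_real_, length(adj), 2L)
  clipped <- FALSE
  for (i in seq_along(adj)) {
    a <- adj[[i]]
    if (anchor == "fissure") {
      fx <- rhinal_x_at(template, y[i])
      x_lat <- fx - r * a$m3_adj
      # medial edge: m2 runs lateral-edge -> medial edge when the lesion is
      # medial of the fissure (m3 >= 0), but medial edge -> fissure when it
      # crosses it (m3 < 0)
      x_med <- fx - r * (a$m2_adj + max(a$m3_adj, 0))
    } else {
      x0 <- template_medial_x_at(template, y[i])
      if (is.na(x0)) stop("midline anchor: no cortex at mb = ", mb[i])
      x_med <- x0 + r * a$m1
      x_lat <- x_med + r * a$m2_adj
    }
    bound <- template_medial_x_at(template, y[i])
    if (!is.na(bound) && x_med < bound) {
      x_med <- bound
      clipped <- TRUE
    }
    med[i, ] <- c(x_med, y[i])
    lat[i, ] <- c(x_lat, y[i])
  }
  if (clipped) {
    warning("medial lesion edge extended beyond the medial cortex boundary; ",
            "clipped to the boundary")
  }
  list(medial = med, lateral = lat, mb = mb)
}

#' Map a measurement set to a lesion contour on the template
#'
#' Composition of the four mapping steps: per-slice normalization against
#' the atlas surface lengths, translation into template coordinates
#' anchored at the rhinal fissure, and contour interpolation (the
#' quantification step is [quantify()]).  Input slice order is
#' irrelevant; slices are sorted by ascending anteroposterior coordinate.
#'
#' @param ms a `measurement_set` (apply [apply_mri_shift()] beforehand for
#'   MRI data).
#' @param template a `cortex_template`.
#' @param method `"linear"` or `"spline"` contour interpolation.
#' @param alpha,n_insert spline parameters, see [catmull_rom()].
#' @param anchor see [translate_slices()].
#' @return a `lesion_contour` with `day` and `slice_mb` attached.  A
#'   single-slice set yields a degenerate contour (`degenerate = TRUE`)
#'   that quantifies to zero.
#' @export
map_lesion <- function(ms, template, method = c("linear", "spline"),
                       alpha = 0.5, n_insert = 0L,
                       anchor = c("fissure", "midline")) {
  method <- match.arg(method)
  anchor <- match.arg(anchor)
  stopifnot(inherits(ms, "measurement_set"),
            inherits(template, "cortex_template"))
  adj <- lapply(seq_len(nrow(ms$slices)), function(i) {
    a <- normalize_slice(ms$slices[i, ], template)
    a$m1 <- ms$slices$m1[i]
    a
  })
  edges <- translate_slices(adj, template, anchor = anchor)
  if (nrow(edges$medial) == 1L) {
    warning("single-slice measurement set: contour is degenerate, ",
            "quantification will be zero")
    contour <- structure(list(
      vertices = rbind(edges$medial, edges$lateral),
      medial_idx = 1L, lateral_idx = 2L,
      is_dummy = c(FALSE, FALSE),
      method = method, alpha = alpha, n_insert = as.integer(n_insert),
      degenerate = TRUE
    ), class = "lesion_contour")
  } else {
    contour <- interpolate_contour(edges$medial, edges$lateral,
                                   method = method, alpha = alpha,
                                   n_insert = n_insert)
    contour$degenerate <- FALSE
  }
  contour$day <- ms$day
  contour$slice_mb <- edges$mb
  contour$units_per_mm <- template$units_per_mm
  contour$ap_zero <- template$ap_zero
  contour
}

#' Quantify the lesion per cytoarchitectonic region
#'
#' Intersects the lesion contour with every template region (Boolean
#' polygon intersection) and reports, per affected region, the damaged
#' area in mm^2 and the percentage of the region affected.  The total
#' cortical damage percentage is the summed affected area over the total
#' cortex area (the sum of all region areas).  Regions with zero
#' intersection are omitted from `per_region` but kept in the cortex
#' denominator.
#'
#' @param contour a `lesion_contour` from [map_lesion()].
#' @param template the `cortex_template` it was mapped against.
#' @return object of class `quantification_result`: list with
#'   `per_region` (data frame `region`, `area_mm2`, `percent`),
#'   `total_area_mm2`, `total_percent_of_cortex`, `cortex_area_mm2`,
#'   `day`.
#' @export
quantify <- function(contour, template) {
  stopifnot(inherits(contour, "lesion_contour"),
            inherits(template, "cortex_template"))
  r2 <- template$units_per_mm^2
  day <- if (is.null(contour$day)) 1L else contour$day
  empty <- structure(list(
    per_region = data.frame(region = character(0L), area_mm2 = numeric(0L),
                            percent = numeric(0L)),
    total_area_mm2 = 0,
    total_percent_of_cortex = 0,
    cortex_area_mm2 = template$cortex_area_mm2,
    day = day
  ), class = "quantification_result")
  if (isTRUE(contour$degenerate) || nrow(contour$vertices) < 3L) {
    warning("degenerate lesion contour: quantification is zero")
    return(empty)
  }
  ids <- names(template$regions)
  areas <- vapply(ids, function(id) {
    polygon_list_area(polygon_intersection(contour$vertices,
                                           template$regions[[id]])) / r2
  }, numeric(1L))
  hit <- areas > 0
  if (!any(hit)) {
    warning("lesion contour lies entirely outside the cortex regions")
    return(empty)
  }
  res <- empty
  res$per_region <- data.frame(
    region = ids[hit],
    area_mm2 = unname(areas[hit]),
    percent = unname(100 * areas[hit] / template$region_areas_mm2[hit]),
    stringsAsFactors = FALSE)
  res$total_area_mm2 <- sum(areas[hit])
  res$total_percent_of_cortex <- 100 * res$total_area_mm2 /
    template$cortex_area_mm2
  res
}

#' @export
print.quantification_result <- function(x, ...) {
  cat(sprintf("Lesion quantification (day %d)\n", x$day))
  if (nrow(x$per_region) > 0L) {
    df <- x$per_region
    df$area_mm2 <- sprintf("%.2f", df$area_mm2)
    df$percent <- sprintf("%.2f", df$percent)
    print(df, row.names = FALSE)
  }
  cat(sprintf("TOTAL: %.2f mm^2 = %.2f%% of the cortex (%.2f mm^2)\n",
              x$total_area_mm2, x$total_percent_of_cortex, x$cortex_area_mm2))
  invisible(x)
}
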