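#' Parameterised Catmull-Rom spline through a sequence of points
#'
#' Inserts `n_insert` interpolated points between each pair of adjacent
#' control points using the alpha-parameterised Catmull-Rom recursion
#' (knot spacing proportional to chord length to the power `alpha`).
#' `alpha = 0.5` is the centripetal parameterisation (cusp- and
#' self-intersection-free within each segment); `alpha = 0` gives the
#' uniform spline and `alpha = 1` the chordal spline.  The curve passes
#' through every control point.  End segments are clamped by duplicating
#' the first and last control points as phantom neighbours.
#'
#' @param points numeric matrix (n x 2) of control points, n >= 2.
#' @param alpha parameterisation exponent in `[0, 1]`; default 0.5
#'   (centripetal).
#' @param n_insert number of points inserted between each adjacent pair
#'   (>= 0).  `n_insert = 0` returns the input unchanged.
#' @return matrix of points: all input points in order, with `n_insert`
#'   interpolated points between each adjacent pair.  Coincident adjacent
#'   control points are treated as one (degenerate segments are skipped
#'   with a warning).
#' @export
catmull_rom <- function(points, alpha = 0.5, n_insert = 0L) {
  p <- as_polygon_matrix(points)
  stopifnot(alpha >= 0, alpha <= 1, n_insert >= 0)
  if (nrow(p) < 2L) stop("catmull_rom needs at least 2 control points")
  dup <- c(FALSE, rowSums(abs(diff(p))) == 0)
  if (any(dup)) {
    warning("coincident adjacent control points: ",
            sum(dup), " degenerate segment(s) skipped")
    p <- p[!dup, , drop = FALSE]
    if (nrow(p) < 2L) return(p)
  }
  if (n_insert == 0L) return(p)

  n <- nrow(p)
  ext <- rbind(p[1L, ], p, p[n, ])  # clamped phantom ends
  s_grid <- seq_len(n_insert) / (n_insert + 1L)
  out <- vector("list", 2L * n - 1L)
  out[[1L]] <- p[1L, , drop = FALSE]
  for (i in seq_len(n - 1L)) {
    P <- ext[i:(i + 3L), , drop = FALSE]  # P0 P1 P2 P3; segment P1->P2
    seg <- .cr_segment(P, alpha, s_grid)
    out[[2L * i]] <- seg
    out[[2L * i + 1L]] <- p[i + 1L, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  dimnames(res) <- list(NULL, c("x", "y"))
  res
}

# Evaluate one Catmull-Rom segment (P1 -> P2 of the 4-point window) at
# normalised positions s in (0,1), via the non-uniform Hermite form with
# tangents derived from the alpha-parameterised knot vector.  Zero-length
# knot intervals (clamped phantom duplicates) contribute a zero term.
.cr_segment <- function(P, alpha, s) {
  d <- function(a, b) sum((b - a)^2)^(alpha / 2)
  t01 <- d(P[1L, ], P[2L, ])
  t12 <- d(P[2L, ], P[3L, ])
  t23 <- d(P[3L, ], P[4L, ])
  safe <- function(num, den) if (den > 0) num / den else c(0, 0)
  m1 <- t12 * (safe(P[2L, ] - P[1L, ], t01) -
               safe(P[3L, ] - P[1L, ], t01 + t12) +
               safe(P[3L, ] - P[2L, ], t12))
  m2 <- t12 * (safe(P[3L, ] - P[2L, ], t12) -
               safe(P[4L, ] - P[2L, ], t12 + t23) +
               safe(P[4L, ] - P[3L, ], t23))
  h00 <- 2 * s^3 - 3 * s^2 + 1
  h10 <- s^3 - 2 * s^2 + s
  h01 <- -2 * s^3 + 3 * s^2
  h11 <- s^3 - s^2
  cbind(h00 * P[2L, 1L] + h10 * m1[1L] + h01 * P[3L, 1L] + h11 * m2[1L],
        h00 * P[2L, 2L] + h10 * m1[2L] + h01 * P[3L, 2L] + h11 * m2[2L])
}

#' Assemble and interpolate the closed lesion contour from its two edges
#'
#' The medial and lateral lesion edges (one vertex per slice, sorted by
#' ascending anteroposterior coordinate) are densified independently —
#' kept as-is for linear interpolation, or passed through [catmull_rom()]
#' for spline interpolation — and then closed into a single polygon:
#' medial edge in ascending order followed by the lateral edge in
#' descending order, giving an anticlockwise contour (positive signed
#' area under the template's y-down axes).
#'
#' If spline overshoot makes the closed contour self-intersect, the
#' offending edge(s) fall back to linear interpolation with a warning.
#'
#' @param medial_edge,lateral_edge n x 2 matrices of template-unit
#'   vertices, same slice ordering (ascending MB).
#' @param method `"linear"` or `"spline"`.
#' @param alpha,n_insert spline parameters, see [catmull_rom()].
#' @return object of class `lesion_contour`: list with `vertices` (closed
#'   polygon matrix), `medial_idx`, `lateral_idx` (vertex index ranges of
#'   the two edges), `is_dummy` (logical, all `FALSE` here), `method`,
#'   `alpha`, `n_insert`.
#' @export
interpolate_contour <- function(medial_edge, lateral_edge,
                                method = c("linear", "spline"),
                                alpha = 0.5, n_insert = 0L) {
  method <- match.arg(method)
  med <- as_polygon_matrix(medial_edge)
  lat <- as_polygon_matrix(lateral_edge)
  if (nrow(med) != nrow(lat)) {
    stop("medial and lateral edges must have one vertex per slice each")
  }
  if (nrow(med) < 2L) stop("at least two slices are needed to form a contour")

  densify <- function(edge, use_spline) {
    if (use_spline && method == "spline" && n_insert > 0L) {
      catmull_rom(edge, alpha = alpha, n_insert = n_insert)
    } else {
      edge
    }
  }
  # spline both edges; on self-intersection retry with linear fallbacks
  for (fallback in list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE),
                        c(FALSE, FALSE))) {
    m <- densify(med, fallback[1L])
    l <- densify(lat, fallback[2L])
    verts <- rbind(m, l[rev(seq_len(nrow(l))), , drop = FALSE])
    if (polygon_is_simple(verts)) {
      if (method == "spline" && n_insert > 0L && !all(fallback)) {
        warning("spline interpolation produced a self-intersecting contour; ",
                "fell back to linear interpolation for the offending edge(s)")
      }
      return(structure(list(
        vertices = verts,
        medial_idx = seq_len(nrow(m)),
        lateral_idx = nrow(m) + seq_len(nrow(l)),
        is_dummy = rep(FALSE, nrow(verts)),
        method = method, alpha = alpha, n_insert = as.integer(n_insert)
      ), class = "lesion_contour"))
    }
  }
  stop("lesion contour self-intersects even with linear interpolation; ",
       "check the measurement ordering")
}

#' @export
print.lesion_contour <- function(x, ...) {
  cat(sprintf(
    "Lesion contour: %d vertices (%d medial, %d lateral), %s interpolation%s\n",
    nrow(x$vertices), length(x$medial_idx), length(x$lateral_idx), x$method,
    if (!is.null(x$day)) sprintf(", day %d", x$day) else ""))
  invisible(x)
}
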