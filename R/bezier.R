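#' Flatten a cubic Bezier curve by de Casteljau subdivision
#'
#' Recursively splits the curve at the parametric midpoint until the control
#' polygon is flat: the flatness measure is the maximum distance of the two
#' inner control points from the chord joining the end points.  Because the
#' curve lies in the convex hull of its control points, every point of the
#' curve is then within `tolerance` of the chord, so the returned polyline
#' deviates from the true curve by at most `tolerance` (tests assert a 2x
#' bound to allow for the chord-distance metric).
#'
#' @param p0,p1,p2,p3 numeric length-2 vectors: end and control points.
#' @param tolerance maximum allowed flatness, in input units (> 0).
#'   Default 0.01 template units.
#' @return numeric matrix of polyline vertices, starting at `p0` and ending
#'   at `p3`.  Degenerate curves (all points coincident) return the chord.
#' @examples
#' flatten_cubic_bezier(c(0, 0), c(1, 0), c(2, 0), c(3, 0))  # already flat
#' @export
flatten_cubic_bezier <- function(p0, p1, p2, p3, tolerance = 0.01) {
  stopifnot(is.numeric(tolerance), length(tolerance) == 1L, tolerance > 0)
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  out <- .bez_subdivide(p0, p1, p2, p3, tolerance, depth = 0L)
  rbind(p0, do.call(rbind, out))
}

# distance from point q to the segment a-b (clamped to the segment)
.seg_dist <- function(q, a, b) {
  ab <- b - a
  len2 <- sum(ab * ab)
  if (len2 == 0) return(sqrt(sum((q - a)^2)))
  t <- max(0, min(1, sum((q - a) * ab) / len2))
  sqrt(sum((q - a - t * ab)^2))
}

# returns list of points AFTER p0 (subdivision interior points and p3)
.bez_subdivide <- function(p0, p1, p2, p3, tol, depth) {
  flat <- max(.seg_dist(p1, p0, p3), .seg_dist(p2, p0, p3))
  if (flat <= tol || depth >= 32L) {
    return(list(p3))
  }
  # de Casteljau split at t = 1/2
  p01 <- (p0 + p1) / 2
  p12 <- (p1 + p2) / 2
  p23 <- (p2 + p3) / 2
  p012 <- (p01 + p12) / 2
  p123 <- (p12 + p23) / 2
  mid <- (p012 + p123) / 2
  c(.bez_subdivide(p0, p01, p012, mid, tol, depth + 1L),
    .bez_subdivide(mid, p123, p23, p3, tol, depth + 1L))
}

#' Evaluate a cubic Bezier at parameter values
#'
#' Direct Bernstein-basis evaluation; used for dense reference sampling.
#'
#' @inheritParams flatten_cubic_bezier
#' @param t numeric vector of parameters in `[0, 1]`.
#' @return matrix with one row per `t`.
#' @export
eval_cubic_bezier <- function(p0, p1, p2, p3, t) {
  s <- 1 - t
  b0 <- s^3; b1 <- 3 * s^2 * t; b2 <- 3 * s * t^2; b3 <- t^3
  cbind(x = b0 * p0[1L] + b1 * p1[1L] + b2 * p2[1L] + b3 * p3[1L],
        y = b0 * p0[2L] + b1 * p1[2L] + b2 * p2[2L] + b3 * p3[2L])
}
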