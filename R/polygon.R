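#' @title Polygon primitives
#' @description Internal representation: a polygon is a numeric matrix with
#'   two columns (x, y).  Closed polygons do not repeat their first vertex;
#'   closure is implicit.  Coordinates are template units unless stated
#'   otherwise.
#' @name polygon-utils
NULL

#' Coerce input to a two-column coordinate matrix
#'
#' Accepts a matrix, a data frame, or a `list(x =, y =)` pair (the form used
#' by the polyclip package).
#'
#' @param p polygon in any accepted form.
#' @return numeric matrix with columns `x`, `y`.
#' @keywords internal
as_polygon_matrix <- function(p) {
  if (is.list(p) && !is.data.frame(p) && !is.null(p$x)) {
    p <- cbind(p$x, p$y)
  }
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 2L) {
    stop("polygon must have exactly two coordinate columns, got ", ncol(p))
  }
  if (anyNA(p)) stop("polygon contains NA coordinates")
  colnames(p) <- c("x", "y")
  p
}

#' Signed area of a closed polygon (shoelace formula)
#'
#' The sign encodes orientation: positive for anticlockwise vertex order
#' under the template's screen-style axes (x rightward, y downward).
#'
#' @param p closed polygon (first vertex not repeated).
#' @return signed area in squared input units.
#' @export
polygon_signed_area <- function(p) {
  p <- as_polygon_matrix(p)
  n <- nrow(p)
  if (n < 3L) return(0)
  x <- p[, 1L]
  y <- p[, 2L]
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Absolute area of a closed polygon
#'
#' Degenerate polygons (fewer than three vertices, or collinear) have zero
#' area; fewer than three vertices additionally raises a warning.
#'
#' @inheritParams polygon_signed_area
#' @return area in squared input units (non-negative).
#' @examples
#' polygon_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))  # unit square -> 1
#' @export
polygon_area <- function(p) {
  p <- as_polygon_matrix(p)
  if (nrow(p) < 3L) {
    warning("polygon has fewer than 3 vertices; area is 0")
    return(0)
  }
  abs(polygon_signed_area(p))
}

#' Total area of a list of disjoint polygons
#' @param ps list of closed polygons.
#' @return sum of the absolute areas.
#' @export
polygon_list_area <- function(ps) {
  if (length(ps) == 0L) return(0)
  sum(vapply(ps, function(q) abs(polygon_signed_area(as_polygon_matrix(q))),
             numeric(1L)))
}

# Orientation test for three points: > 0 anticlockwise (y-down axes), 0
# collinear.
.cross2 <- function(ox, oy, ax, ay, bx, by) {
  (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
}

#' Test whether a closed polygon is simple (non-self-intersecting)
#'
#' Pairwise proper-intersection test over all non-adjacent edge pairs,
#' vectorised per edge.  Touching at shared endpoints of adjacent edges is
#' allowed; any other crossing or overlap makes the polygon non-simple.
#'
#' @inheritParams polygon_signed_area
#' @return logical scalar.
#' @export
polygon_is_simple <- function(p) {
  p <- as_polygon_matrix(p)
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  nxt <- c(seq_len(n)[-1L], 1L)
  ax <- p[, 1L]; ay <- p[, 2L]
  bx <- p[nxt, 1L]; by <- p[nxt, 2L]
  for (i in seq_len(n - 2L)) {
    # candidate edges j strictly after i, skipping adjacent ones
    j <- seq.int(i + 2L, n)
    if (i == 1L) j <- j[j != n]
    if (length(j) == 0L) next
    d1 <- .cross2(ax[i], ay[i], bx[i], by[i], ax[j], ay[j])
    d2 <- .cross2(ax[i], ay[i], bx[i], by[i], bx[j], by[j])
    d3 <- .cross2(ax[j], ay[j], bx[j], by[j], rep(ax[i], length(j)), rep(ay[i], length(j)))
    d4 <- .cross2(ax[j], ay[j], bx[j], by[j], rep(bx[i], length(j)), rep(by[i], length(j)))
    proper <- (d1 * d2 < 0) & (d3 * d4 < 0)
    if (any(proper)) return(FALSE)
    # collinear overlap: all four cross products zero and projections overlap
    col <- (d1 == 0) & (d2 == 0) & (d3 == 0) & (d4 == 0)
    if (any(col)) {
      jj <- j[col]
      lo1 <- pmin(ax[i], bx[i]); hi1 <- pmax(ax[i], bx[i])
      lo1y <- pmin(ay[i], by[i]); hi1y <- pmax(ay[i], by[i])
      ov <- pmin(hi1, pmax(ax[jj], bx[jj])) > pmax(lo1, pmin(ax[jj], bx[jj])) |
        pmin(hi1y, pmax(ay[jj], by[jj])) > pmax(lo1y, pmin(ay[jj], by[jj]))
      if (any(ov)) return(FALSE)
    }
  }
  TRUE
}

#' Boolean intersection of two closed polygons
#'
#' Clipping is delegated to the Clipper library (package polyclip), which
#' snaps coordinates onto an integer micro-grid internally, giving robust
#' results on near-degenerate edges.  Self-intersecting inputs are accepted:
#' they are interpreted under the even-odd fill rule (the union of their
#' even-odd pieces), with a warning.
#'
#' @param a,b closed polygons.
#' @return list of disjoint simple closed polygons covering the
#'   intersection; empty list when the polygons do not overlap.  The summed
#'   area never exceeds the smaller input area.
#' @examples
#' sq <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2))
#' polygon_list_area(polygon_intersection(sq, sq + 1))  # 1
#' @export
polygon_intersection <- function(a, b) {
  a <- as_polygon_matrix(a)
  b <- as_polygon_matrix(b)
  if (nrow(a) < 3L || nrow(b) < 3L) return(list())
  if (!polygon_is_simple(a) || !polygon_is_simple(b)) {
    warning("non-simple input polygon; interpreting via even-odd fill rule")
  }
  res <- polyclip::polyclip(list(x = a[, 1L], y = a[, 2L]),
                            list(x = b[, 1L], y = b[, 2L]),
                            op = "intersection",
                            fillA = "evenodd", fillB = "evenodd")
  lapply(res, function(q) cbind(x = q$x, y = q$y))
}

#' Union of a list of closed polygons
#'
#' Used for the cortex outline (union of all template regions) in the
#' conservation checks and for clipping lesions to the cortex.
#'
#' @param ps list of closed polygons.
#' @return list of closed polygons covering the union.
#' @export
polygon_union <- function(ps) {
  ps <- lapply(ps, as_polygon_matrix)
  if (length(ps) == 0L) return(list())
  acc <- list(list(x = ps[[1L]][, 1L], y = ps[[1L]][, 2L]))
  for (q in ps[-1L]) {
    acc <- polyclip::polyclip(acc, list(x = q[, 1L], y = q[, 2L]),
                              op = "union",
                              fillA = "nonzero", fillB = "nonzero")
  }
  lapply(acc, function(q) cbind(x = q$x, y = q$y))
}
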