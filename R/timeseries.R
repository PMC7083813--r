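#' Build a multi-day lesion series
#'
#' Maps and quantifies one measurement set per day against a common
#' template and collects the results sorted by day.
#'
#' @param sets list of `measurement_set` objects with unique days.
#' @param template a `cortex_template`.
#' @param ... mapping parameters passed to [map_lesion()].
#' @return object of class `lesion_series`: list with `days` (sorted) and
#'   `entries`, a named list (by day) of `list(contour, result)`.
#' @export
lesion_series <- function(sets, template, ...) {
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1L), "measurement_set")))
  days <- vapply(sets, `[[`, integer(1L), "day")
  if (anyDuplicated(days)) {
    stop("measurement sets must have unique days, got: ",
         paste(days, collapse = ", "))
  }
  o <- order(days)
  entries <- lapply(o, function(i) {
    contour <- map_lesion(sets[[i]], template, ...)
    list(contour = contour, result = quantify(contour, template))
  })
  names(entries) <- as.character(days[o])
  structure(list(days = days[o], entries = entries),
            class = "lesion_series")
}

#' Align two lesion contours to equal vertex counts
#'
#' For smooth visual transitions between two time points the two contours
#' must have the same number of vertices.  The contour with fewer
#' vertices gains interpolated dummy points, inserted on its existing
#' edges (hence collinear: the polygon's area is unchanged) at evenly
#' spaced arc-length positions, medial edge matched with medial edge and
#' lateral with lateral.  Original vertices are preserved and dummy
#' points are flagged in `is_dummy` so they can be dropped after the
#' transition visualisation.
#'
#' @param a,b `lesion_contour` objects.
#' @return list with elements `a` and `b`, aligned contours of equal
#'   vertex counts.
#' @export
align_contours <- function(a, b) {
  stopifnot(inherits(a, "lesion_contour"), inherits(b, "lesion_contour"))
  for (edge in c("medial", "lateral")) {
    na <- length(.edge_idx(a, edge))
    nb <- length(.edge_idx(b, edge))
    if (na < nb) a <- .pad_edge(a, edge, nb - na)
    if (nb < na) b <- .pad_edge(b, edge, na - nb)
  }
  list(a = a, b = b)
}

.edge_idx <- function(contour, edge) {
  if (edge == "medial") contour$medial_idx else contour$lateral_idx
}

# insert k dummy points on one edge of a contour, evenly by arc length
.pad_edge <- function(contour, edge, k) {
  idx <- .edge_idx(contour, edge)
  pts <- contour$vertices[idx, , drop = FALSE]
  n <- nrow(pts)
  seg_len <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                           pts[-n, , drop = FALSE])^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[n]
  # target arc positions; nudge off existing vertices so originals and
  # dummies stay distinct
  targets <- total * seq_len(k) / (k + 1L)
  eps <- total * 1e-9
  new_pts <- matrix(NA_real_, k, 2L)
  new_after <- integer(k)   # index (within edge) after which each point goes
  for (j in seq_len(k)) {
    t <- targets[j]
    hit <- which(abs(cum - t) <= eps)
    if (length(hit) > 0L) t <- min(t + 2 * eps, total - eps)
    seg <- findInterval(t, cum, rightmost.closed = TRUE)
    seg <- max(1L, min(seg, n - 1L))
    frac <- if (seg_len[seg] > 0) (t - cum[seg]) / seg_len[seg] else 0
    new_pts[j, ] <- pts[seg, ] + frac * (pts[seg + 1L, ] - pts[seg, ])
    new_after[j] <- seg
  }
  # rebuild the edge with dummies spliced in after their segment start
  ord <- order(new_after, targets)
  new_pts <- new_pts[ord, , drop = FALSE]
  new_after <- new_after[ord]
  out <- list(); flags <- logical(0L)
  for (i in seq_len(n)) {
    out[[length(out) + 1L]] <- pts[i, , drop = FALSE]
    flags <- c(flags, contour$is_dummy[idx[i]])
    ins <- which(new_after == i)
    for (j in ins) {
      out[[length(out) + 1L]] <- new_pts[j, , drop = FALSE]
      flags <- c(flags, TRUE)
    }
  }
  edge_pts <- do.call(rbind, out)

  med <- contour$vertices[contour$medial_idx, , drop = FALSE]
  lat <- contour$vertices[contour$lateral_idx, , drop = FALSE]
  med_fl <- contour$is_dummy[contour$medial_idx]
  lat_fl <- contour$is_dummy[contour$lateral_idx]
  if (edge == "medial") {
    med <- edge_pts; med_fl <- flags
  } else {
    # lateral edge is stored in contour order (descending mb); pad in that
    # stored order so correspondence stays monotone along the contour
    lat <- edge_pts; lat_fl <- flags
  }
  contour$vertices <- rbind(med, lat)
  contour$medial_idx <- seq_len(nrow(med))
  contour$lateral_idx <- nrow(med) + seq_len(nrow(lat))
  contour$is_dummy <- c(med_fl, lat_fl)
  contour
}

#' Remove dummy alignment points from a contour
#' @param contour a `lesion_contour`.
#' @return the contour without dummy vertices.
#' @export
drop_dummy_points <- function(contour) {
  stopifnot(inherits(contour, "lesion_contour"))
  keep <- !contour$is_dummy
  km <- keep[contour$medial_idx]
  contour$vertices <- contour$vertices[keep, , drop = FALSE]
  n_med <- sum(km)
  contour$medial_idx <- seq_len(n_med)
  contour$lateral_idx <- n_med + seq_len(nrow(contour$vertices) - n_med)
  contour$is_dummy <- rep(FALSE, nrow(contour$vertices))
  contour
}

#' Linear transition between two aligned contours
#'
#' Vertex-wise convex combination `(1 - tau) * a + tau * b`; `tau = 0`
#' reproduces `a` and `tau = 1` reproduces `b` exactly.
#'
#' @param a,b aligned `lesion_contour` objects (equal vertex counts, see
#'   [align_contours()]).
#' @param tau interpolation position in `[0, 1]`.
#' @return a `lesion_contour` at the intermediate position.
#' @export
interpolate_transition <- function(a, b, tau) {
  stopifnot(inherits(a, "lesion_contour"), inherits(b, "lesion_contour"),
            is.numeric(tau), length(tau) == 1L, tau >= 0, tau <= 1)
  if (nrow(a$vertices) != nrow(b$vertices) ||
      length(a$medial_idx) != length(b$medial_idx)) {
    stop("contours are not aligned; call align_contours() first")
  }
  out <- a
  out$vertices <- (1 - tau) * a$vertices + tau * b$vertices
  out$is_dummy <- a$is_dummy | b$is_dummy
  out$tau <- tau
  out$day <- NULL
  out
}

#' Long-format per-day quantification table
#'
#' One row per (day, affected region) plus one `TOTAL` row per day
#' carrying the total damaged area and its percentage of the whole
#' cortex.  This is the data behind the time-course chart and the series
#' CSV export.
#'
#' @param s a `lesion_series`.
#' @return data frame with columns `day`, `region`, `area_mm2`,
#'   `percent`.
#' @export
series_table <- function(s) {
  stopifnot(inherits(s, "lesion_series"))
  do.call(rbind, lapply(s$entries, function(e) {
    q <- e$result
    rbind(
      if (nrow(q$per_region) > 0L)
        data.frame(day = q$day, q$per_region, stringsAsFactors = FALSE),
      data.frame(day = q$day, region = "TOTAL",
                 area_mm2 = q$total_area_mm2,
                 percent = q$total_percent_of_cortex,
                 stringsAsFactors = FALSE)
    )
  }))
}

#' @export
print.lesion_series <- function(x, ...) {
  cat(sprintf("Lesion series over %d day(s): %s\n", length(x$days),
              paste(x$days, collapse = ", ")))
  for (e in x$entries) {
    cat(sprintf("  day %d: %.2f mm^2 (%.2f%% of cortex)\n",
                e$result$day, e$result$total_area_mm2,
                e$result$total_percent_of_cortex))
  }
  invisible(x)
}
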