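# SVG path-data ("d" attribute) parsing and transform handling.
#
# Supported commands: M/m L/l H/h V/v C/c S/s Q/q T/t Z/z.  Quadratic
# segments are raised to cubics before flattening.  Elliptical arcs (A/a)
# are not supported and raise an error.  Transforms (translate, scale,
# rotate, matrix, skewX, skewY) are composed down the element's ancestor
# chain and applied to control points BEFORE Bezier flattening, so the
# flatness tolerance is honoured in final template coordinates.

.svg_num_re <- "[-+]?(?:[0-9]*\\.[0-9]+|[0-9]+\\.?)(?:[eE][-+]?[0-9]+)?"

# Tokenise path data into single-letter commands and numbers.
.svg_path_tokens <- function(d) {
  pat <- paste0("[MmLlHhVvCcSsQqTtAaZz]|", .svg_num_re)
  m <- gregexpr(pat, d, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(character(0L))
  regmatches(d, gregexpr(pat, d, perl = TRUE))[[1L]]
}

#' Parse an SVG transform attribute into a 3x3 homogeneous matrix
#'
#' @param s transform string, e.g. `"translate(3,4) scale(2)"`; `NA` or
#'   empty gives the identity.
#' @return 3x3 numeric matrix.
#' @keywords internal
parse_svg_transform <- function(s) {
  M <- diag(3)
  if (is.null(s) || is.na(s) || !nzchar(trimws(s))) return(M)
  calls <- regmatches(s, gregexpr("[a-zA-Z]+\\s*\\(([^)]*)\\)", s))[[1L]]
  for (cl in calls) {
    name <- sub("\\s*\\(.*$", "", cl)
    args <- as.numeric(regmatches(cl, gregexpr(.svg_num_re, cl, perl = TRUE))[[1L]])
    T <- diag(3)
    switch(name,
      translate = {
        T[1L, 3L] <- args[1L]
        T[2L, 3L] <- if (length(args) > 1L) args[2L] else 0
      },
      scale = {
        T[1L, 1L] <- args[1L]
        T[2L, 2L] <- if (length(args) > 1L) args[2L] else args[1L]
      },
      rotate = {
        a <- args[1L] * pi / 180
        R <- diag(3)
        R[1L, 1L] <- cos(a); R[1L, 2L] <- -sin(a)
        R[2L, 1L] <- sin(a); R[2L, 2L] <- cos(a)
        if (length(args) >= 3L) {
          C1 <- diag(3); C1[1L, 3L] <- args[2L]; C1[2L, 3L] <- args[3L]
          C2 <- diag(3); C2[1L, 3L] <- -args[2L]; C2[2L, 3L] <- -args[3L]
          R <- C1 %*% R %*% C2
        }
        T <- R
      },
      matrix = {
        T[1L, 1L] <- args[1L]; T[2L, 1L] <- args[2L]
        T[1L, 2L] <- args[3L]; T[2L, 2L] <- args[4L]
        T[1L, 3L] <- args[5L]; T[2L, 3L] <- args[6L]
      },
      skewX = T[1L, 2L] <- tan(args[1L] * pi / 180),
      skewY = T[2L, 1L] <- tan(args[1L] * pi / 180),
      stop("unsupported SVG transform: ", name)
    )
    M <- M %*% T
  }
  M
}

.apply_transform <- function(M, xy) {
  # xy: length-2 vector or n x 2 matrix
  if (is.matrix(xy)) {
    t(M %*% rbind(t(xy), 1))[, 1:2, drop = FALSE]
  } else {
    as.numeric(M %*% c(xy, 1))[1:2]
  }
}

#' Convert SVG path data to flattened polylines
#'
#' @param d path data string.
#' @param transform 3x3 transform matrix applied to all control points
#'   before flattening.
#' @param tolerance flatness tolerance for [flatten_cubic_bezier()], in
#'   post-transform units.
#' @return list of subpaths; each is a `list(pts = <n x 2 matrix>,
#'   closed = <logical>)`.  Closed subpaths do not repeat the first vertex.
#' @keywords internal
svg_path_to_polylines <- function(d, transform = diag(3), tolerance = 0.01) {
  toks <- .svg_path_tokens(d)
  subpaths <- list()
  pts <- NULL            # accumulated vertices of current subpath (raw coords)
  start <- NULL          # subpath start point
  cur <- c(0, 0)
  prev_cmd <- ""
  prev_ctrl <- NULL      # last cubic/quadratic control point (for S/T)
  i <- 1L
  cmd <- ""

  tp <- function(p) .apply_transform(transform, p)
  flush <- function(closed) {
    if (!is.null(pts) && nrow(pts) >= 1L) {
      m <- pts
      if (closed && nrow(m) >= 2L &&
          max(abs(m[1L, ] - m[nrow(m), ])) < 1e-9) {
        m <- m[-nrow(m), , drop = FALSE]
      }
      subpaths[[length(subpaths) + 1L]] <<- list(pts = m, closed = closed)
    }
    pts <<- NULL
  }
  need <- function(k) {
    if (i + k - 1L > length(toks)) stop("malformed SVG path data: ", d)
    v <- suppressWarnings(as.numeric(toks[i:(i + k - 1L)]))
    if (anyNA(v)) stop("malformed SVG path data near token ", i, ": ", d)
    i <<- i + k
    v
  }
  add_point <- function(p) pts <<- rbind(pts, tp(p))
  add_cubic <- function(c1, c2, p3) {
    seg <- flatten_cubic_bezier(tp(cur), tp(c1), tp(c2), tp(p3), tolerance)
    pts <<- rbind(pts, seg[-1L, , drop = FALSE])
  }

  while (i <= length(toks)) {
    tok <- toks[i]
    if (grepl("^[A-Za-z]$", tok)) {
      cmd <- tok
      i <- i + 1L
    } else if (cmd %in% c("M", "m")) {
      # implicit lineto after the first coordinate pair of a moveto
      cmd <- if (cmd == "M") "L" else "l"
    } else if (cmd == "") {
      stop("SVG path data must start with a moveto: ", d)
    }
    rel <- (cmd == tolower(cmd)) && cmd != "z" && cmd != "Z"
    base <- if (rel) cur else c(0, 0)
    switch(toupper(cmd),
      M = {
        v <- need(2L)
        flush(FALSE)
        cur <- base + v
        start <- cur
        pts <- rbind(NULL, tp(cur))
        prev_ctrl <- NULL
      },
      L = {
        v <- need(2L); cur <- base + v; add_point(cur); prev_ctrl <- NULL
      },
      H = {
        v <- need(1L)
        cur <- c(if (rel) cur[1L] + v else v, cur[2L])
        add_point(cur); prev_ctrl <- NULL
      },
      V = {
        v <- need(1L)
        cur <- c(cur[1L], if (rel) cur[2L] + v else v)
        add_point(cur); prev_ctrl <- NULL
      },
      C = {
        v <- need(6L)
        c1 <- base + v[1:2]; c2 <- base + v[3:4]; p3 <- base + v[5:6]
        add_cubic(c1, c2, p3)
        prev_ctrl <- c2; cur <- p3
      },
      S = {
        v <- need(4L)
        c1 <- if (!is.null(prev_ctrl) && toupper(prev_cmd) %in% c("C", "S")) {
          2 * cur - prev_ctrl
        } else cur
        c2 <- base + v[1:2]; p3 <- base + v[3:4]
        add_cubic(c1, c2, p3)
        prev_ctrl <- c2; cur <- p3
      },
      Q = {
        v <- need(4L)
        q <- base + v[1:2]; p3 <- base + v[3:4]
        add_cubic(cur + 2 / 3 * (q - cur), p3 + 2 / 3 * (q - p3), p3)
        prev_ctrl <- q; cur <- p3
      },
      T = {
        v <- need(2L)
        q <- if (!is.null(prev_ctrl) && toupper(prev_cmd) %in% c("Q", "T")) {
          2 * cur - prev_ctrl
        } else cur
        p3 <- base + v[1:2]
        add_cubic(cur + 2 / 3 * (q - cur), p3 + 2 / 3 * (q - p3), p3)
        prev_ctrl <- q; cur <- p3
      },
      A = stop("elliptical arc commands (A/a) are not supported; ",
               "convert arcs to cubic Beziers when exporting the SVG"),
      Z = {
        flush(TRUE)
        if (!is.null(start)) cur <- start
        prev_ctrl <- NULL
      },
      stop("unsupported SVG path command: ", cmd)
    )
    prev_cmd <- cmd
  }
  flush(FALSE)
  subpaths
}
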