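test_that("a rectangular region parses with the correct area and id", {
  svg <- svg_doc(c(basic_region, basic_fissure),
                 'units_per_mm="10" ap_zero="200"')
  t <- parse_template(svg, basic_atlas_json())
  expect_named(t$regions, "S1")
  expect_equal(polygon_area(t$regions$S1), 100)    # template units^2
  expect_equal(t$region_areas_mm2[["S1"]], 1)      # 1 mm^2 at r = 10
  expect_equal(t$units_per_mm, 10)
  expect_equal(t$ap_zero, 200)
})

test_that("svg attributes take precedence over labelled rectangles", {
  rects <- c('<rect id="units_per_mm" x="0" y="0" width="20" height="2"/>',
             '<rect id="ap_zero" x="0" y="123" width="5" height="5"/>')
  # both forms present: attribute wins for both constants
  svg <- svg_doc(c(basic_region, basic_fissure, rects),
                 'units_per_mm="10" ap_zero="200"')
  t <- parse_template(svg, basic_atlas_json())
  expect_equal(t$units_per_mm, 10)
  expect_equal(t$ap_zero, 200)
  # rectangle form alone works
  svg2 <- svg_doc(c(basic_region, basic_fissure, rects))
  t2 <- parse_template(svg2, basic_atlas_json())
  expect_equal(t2$units_per_mm, 20)
  expect_equal(t2$ap_zero, 123)
})

test_that("missing constants, regions or closure raise hard errors", {
  expect_error(parse_template(svg_doc(c(basic_region, basic_fissure),
                                      'units_per_mm="10"'),
                              basic_atlas_json()),
               "ap_zero")
  expect_error(parse_template(svg_doc(c(basic_region, basic_fissure),
                                      'ap_zero="200"'),
                              basic_atlas_json()),
               "units_per_mm")
  expect_error(parse_template(svg_doc(basic_fissure,
                                      'units_per_mm="10" ap_zero="200"'),
                              basic_atlas_json()),
               "A_")
  unclosed <- '<path id="A_S1" d="M 50 50 L 60 50 L 60 60 L 50 60"/>'
  expect_error(parse_template(svg_doc(c(unclosed, basic_fissure),
                                      'units_per_mm="10" ap_zero="200"'),
                              basic_atlas_json()),
               "S1")
  expect_error(parse_template(svg_doc(basic_region,
                                      'units_per_mm="10" ap_zero="200"'),
                              basic_atlas_json()),
               "rhinal_fissure")
})

test_that("a four-cubic circle region flattens to the analytic circle area", {
  circ <- sprintf('<path id="A_CIRC" d="%s"/>', circle_path_d(200, 200, 50))
  svg <- svg_doc(c(circ, basic_fissure), 'units_per_mm="10" ap_zero="200"')
  t <- parse_template(svg, basic_atlas_json())
  expect_lt(abs(polygon_area(t$regions$CIRC) - pi * 50^2) / (pi * 50^2),
            0.001)
})

test_that("region geometry is invariant to an SVG translate transform", {
  moved <- '<g transform="translate(-30, 12.5)"><path id="A_S1" d="M 80 37.5 L 90 37.5 L 90 47.5 L 80 47.5 Z"/></g>'
  svg1 <- svg_doc(c(basic_region, basic_fissure), 'units_per_mm="10" ap_zero="200"')
  svg2 <- svg_doc(c(moved, basic_fissure), 'units_per_mm="10" ap_zero="200"')
  t1 <- parse_template(svg1, basic_atlas_json())
  t2 <- parse_template(svg2, basic_atlas_json())
  expect_equal(t2$regions$S1, t1$regions$S1, tolerance = 1e-12)
})

test_that("bezier flattening: flat input, oracle bound and refinement monotonicity", {
  # collinear control points collapse to the segment at any tolerance
  seg <- flatten_cubic_bezier(c(0, 0), c(1, 1), c(2, 2), c(3, 3),
                              tolerance = 1e-6)
  expect_equal(seg[1L, ], c(0, 0), ignore_attr = TRUE)
  expect_equal(seg[nrow(seg), ], c(3, 3), ignore_attr = TRUE)
  expect_lt(max(abs(seg[, 2L] - seg[, 1L])), 1e-12)

  # quarter-circle Bezier: every vertex within 2x tolerance of the dense curve
  r <- 50; k <- circle_kappa * r
  p0 <- c(r, 0); p1 <- c(r, k); p2 <- c(k, r); p3 <- c(0, r)
  for (tol in c(0.1, 0.01)) {
    poly <- flatten_cubic_bezier(p0, p1, p2, p3, tolerance = tol)
    dense <- eval_cubic_bezier(p0, p1, p2, p3, seq(0, 1, length.out = 20001L))
    for (i in seq_len(nrow(poly))) {
      d <- min(sqrt((dense[, 1L] - poly[i, 1L])^2 +
                    (dense[, 2L] - poly[i, 2L])^2))
      expect_lt(d, 2 * tol)
    }
  }
  # halving the tolerance never yields fewer vertices
  n_at <- function(tol) nrow(flatten_cubic_bezier(p0, p1, p2, p3, tol))
  tols <- 0.2 / 2^(0:6)
  counts <- vapply(tols, n_at, numeric(1L))
  expect_true(all(diff(counts) >= 0))
})

test_that("flattened polyline stays within 2x tolerance of random cubics", {
  set.seed(5)
  for (k in 1:10) {
    P <- matrix(runif(8, 0, 100), 4, 2)
    tol <- 0.05
    poly <- flatten_cubic_bezier(P[1, ], P[2, ], P[3, ], P[4, ], tol)
    dense <- eval_cubic_bezier(P[1, ], P[2, ], P[3, ], P[4, ],
                               seq(0, 1, length.out = 5000L))
    # max deviation of the dense curve from the polyline (segment distance)
    expect_lt(max_dist_to_polyline(dense, poly), 2 * tol)
  }
})

test_that("atlas length lookup uses the nearest plate with anterior ties", {
  atlas <- read_atlas_lengths(jsonlite::toJSON(data.frame(
    ap = c(1, 0.5, 0), medial_to_rhinal = c(4, 5, 6),
    medial_to_lateral = c(6, 7, 8)), dataframe = "rows", auto_unbox = TRUE))
  expect_equal(atlas_length_at(atlas, 0.5), 5)               # exact hit
  expect_equal(atlas_length_at(atlas, 0.75), 4)              # tie -> anterior
  expect_equal(atlas_length_at(atlas, 0.25, "medial_to_lateral"), 7)
  expect_error(atlas_length_at(atlas, 2), "outside the template span")
  expect_error(atlas_length_at(atlas, -0.5), "outside the template span")
  # brute-force nearest-plate oracle on a random atlas
  set.seed(9)
  ap <- sort(runif(15, -4, 3), decreasing = TRUE)
  atlas2 <- read_atlas_lengths(jsonlite::toJSON(data.frame(
    ap = ap, medial_to_rhinal = runif(15, 3, 6),
    medial_to_lateral = runif(15, 6, 8)), dataframe = "rows",
    auto_unbox = TRUE))
  for (k in 1:100) {
    mb <- runif(1, min(ap), max(ap))
    d <- abs(atlas2$ap - mb)
    nearest <- which(d == min(d))
    if (length(nearest) > 1L) nearest <- nearest[which.max(atlas2$ap[nearest])]
    expect_equal(atlas_length_at(atlas2, mb), atlas2$medial_to_rhinal[nearest])
  }
})

test_that("rhinal fissure interpolation matches a segment-search oracle", {
  svg <- svg_doc(c(basic_region, basic_fissure),
                 'units_per_mm="10" ap_zero="200"')
  t <- parse_template(svg, basic_atlas_json())
  # vertical fissure: constant x
  for (y in c(0, 57.3, 400)) expect_equal(rhinal_x_at(t, y), 100)
  expect_error(rhinal_x_at(t, 401), "outside")

  # diagonal polyline (0,0) - (10,10): midpoint
  diag_f <- '<path id="rhinal_fissure" d="M 0 0 L 10 10"/>'
  region2 <- '<path id="A_S1" d="M 2 2 L 4 2 L 4 4 L 2 4 Z"/>'
  t2 <- parse_template(svg_doc(c(region2, diag_f), 'units_per_mm="10" ap_zero="5"'),
                       basic_atlas_json(ap = c(0.4, 0.2, 0), mr = 4, ml = 5))
  expect_equal(rhinal_x_at(t2, 5), 5)

  # random monotone polyline vs brute-force segment search
  set.seed(13)
  ys <- cumsum(runif(12, 1, 10))
  xs <- runif(12, 0, 100)
  d <- paste("M", xs[1], ys[1],
             paste("L", xs[-1], ys[-1], collapse = " "))
  f3 <- sprintf('<path id="rhinal_fissure" d="%s"/>', d)
  reg3 <- sprintf('<path id="A_S1" d="M 1 %g L 2 %g L 2 %g L 1 %g Z"/>',
                  ys[1], ys[1], ys[12], ys[12])
  ap0 <- mean(ys)
  t3 <- parse_template(svg_doc(c(reg3, f3),
                               sprintf('units_per_mm="10" ap_zero="%g"', ap0)),
                       basic_atlas_json(ap = c(0.1, 0, -0.1)))
  for (k in 1:100) {
    y <- runif(1, ys[1], ys[12])
    i <- max(which(ys <= y))
    i <- min(i, 11L)
    want <- xs[i] + (y - ys[i]) / (ys[i + 1] - ys[i]) * (xs[i + 1] - xs[i])
    expect_equal(rhinal_x_at(t3, y), want, tolerance = 1e-9)
  }
})

test_that("synthetic templates round-trip exactly through the parser", {
  syn <- generate_synthetic_template(n_regions = 4L, ap_span = c(1, -1),
                                     units_per_mm = 10)
  t <- parse_template(syn$svg, syn$atlas_json)
  expect_length(t$regions, 4L)
  expect_setequal(names(t$regions), syn$truth$region)
  expect_equal(unname(t$region_areas_mm2[syn$truth$region]),
               rep(1, 4))                      # 2x2 grid of unit squares
  expect_equal(t$units_per_mm, syn$units_per_mm)
  expect_equal(t$ap_zero, syn$ap_zero)

  # jittered grid: parsed areas match the generator's bookkeeping to 1e-9
  syn2 <- generate_synthetic_template(n_regions = 7L, seed = 42L,
                                      jitter = 0.3)
  t2 <- parse_template(syn2$svg, syn2$atlas_json)
  expect_length(t2$regions, 7L)
  got <- vapply(syn2$truth$region,
                function(id) polygon_area(t2$regions[[id]]), numeric(1L))
  expect_equal(unname(got), syn2$truth$area_units2, tolerance = 1e-9)

  # determinism: same seed -> byte-identical output
  again <- generate_synthetic_template(n_regions = 7L, seed = 42L,
                                       jitter = 0.3)
  expect_identical(again$svg, syn2$svg)
  expect_identical(again$atlas_json, syn2$atlas_json)
})
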