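# vertical-fissure test template: fissure at x = 100, r = 10, ap_zero = 0,
# cortex spanning x in [20, 100] over y in [-40, 60] (mb in [-6, 4])
make_fissure_template <- function() {
  region <- '<path id="A_CTX" d="M 20 -40 L 100 -40 L 100 60 L 20 60 Z"/>'
  fissure <- '<path id="rhinal_fissure" d="M 100 -45 L 100 65"/>'
  atlas <- jsonlite::toJSON(data.frame(
    ap = seq(3.5, -5.5, by = -0.5), medial_to_rhinal = 8,
    medial_to_lateral = 10), dataframe = "rows", auto_unbox = TRUE)
  parse_template(svg_doc(c(region, fissure), 'units_per_mm="10" ap_zero="0"'),
                 atlas)
}

test_that("normalization scales M2/M3 by atlas-to-measured ratio", {
  atlas4 <- read_atlas_lengths(basic_atlas_json(ap = c(1, 0, -1), mr = 4, ml = 5))
  a <- normalize_slice(list(mb = 0, m1 = 1, m2 = 2, m3 = 1), atlas4)
  expect_equal(a$scale_ratio, 1)
  expect_equal(a$m2_adj, 2)
  expect_equal(a$m3_adj, 1)

  atlas8 <- read_atlas_lengths(basic_atlas_json(ap = c(1, 0, -1), mr = 8, ml = 10))
  b <- normalize_slice(list(mb = 0, m1 = 1, m2 = 2, m3 = 1), atlas8)
  expect_equal(b$scale_ratio, 2)
  expect_equal(b$m2_adj, 4)
  expect_equal(b$m3_adj, 2)

  # fissure-crossing rule: D = m1 + m2 when m3 < 0
  cc <- normalize_slice(list(mb = 0, m1 = 3, m2 = 1, m3 = -0.5), atlas8)
  expect_equal(cc$scale_ratio, 2)
  expect_equal(cc$m2_adj, 2)
  expect_equal(cc$m3_adj, -1)

  expect_warning(normalize_slice(list(mb = 0, m1 = 20, m2 = 20, m3 = 20),
                                 atlas8), "implausible scale ratio")
})

test_that("translation anchors the lateral edge at the rhinal fissure", {
  t <- make_fissure_template()
  tr <- translate_slices(list(list(mb = -1, m2_adj = 2, m3_adj = 1)), t)
  expect_equal(tr$medial[1L, ], c(70, 10), ignore_attr = TRUE)
  expect_equal(tr$lateral[1L, ], c(90, 10), ignore_attr = TRUE)
  # m3 = 0: lateral edge exactly on the fissure
  tr0 <- translate_slices(list(list(mb = -1, m2_adj = 2, m3_adj = 0)), t)
  expect_equal(tr0$lateral[1L, 1L], 100)
  # m3 < 0: lateral edge beyond the fissure, medial edge anchored at it
  trn <- translate_slices(list(list(mb = -1, m2_adj = 2, m3_adj = -1)), t)
  expect_equal(trn$lateral[1L, 1L], 110)
  expect_equal(trn$medial[1L, 1L], 80)
  # medial edge clipped at the cortex boundary with a warning
  expect_warning(
    trc <- translate_slices(list(list(mb = -1, m2_adj = 12, m3_adj = 0)), t),
    "clipped")
  expect_equal(trc$medial[1L, 1L], 20)
})

test_that("map_lesion composes identity-scale measurements to exact coordinates", {
  t <- make_fissure_template()
  # atlas medial_to_rhinal = 8; measurements sum to 8 -> ratio 1
  ms <- measurement_set(data.frame(mb = c(1, 0, -1),
                                   m1 = c(5, 4, 5),
                                   m2 = c(2, 3, 2),
                                   m3 = c(1, 1, 1)))
  ct <- map_lesion(ms, t, method = "linear")
  # ascending mb: (-1, 0, 1); y = -10*mb; lateral x = 100 - 10*m3
  expect_equal(ct$vertices[ct$medial_idx, ],
               cbind(c(70, 60, 70), c(10, 0, -10)), ignore_attr = TRUE)
  expect_equal(ct$vertices[ct$lateral_idx, ],
               cbind(c(90, 90, 90), c(-10, 0, 10)), ignore_attr = TRUE)
  expect_gt(polygon_signed_area(ct$vertices), 0)  # anticlockwise assembly
  expect_equal(ct$slice_mb, c(-1, 0, 1))
})

test_that("mapping is invariant to input row order and per-slice scaling", {
  t <- make_fissure_template()
  set.seed(17)
  mb <- seq(-2, 1, by = 0.5)
  df <- data.frame(mb = mb, m1 = runif(7, 0.5, 2), m2 = runif(7, 1, 3),
                   m3 = runif(7, 0.2, 1.5))
  ct <- map_lesion(measurement_set(df), t)
  # reversed row order
  ct_rev <- map_lesion(measurement_set(df[rev(seq_len(7)), ]), t)
  expect_equal(ct_rev$vertices, ct$vertices)
  # per-slice multiplicative distortion k > 0 cancels out (m3 >= 0)
  k <- runif(7, 0.5, 2)
  df2 <- data.frame(mb = mb, m1 = df$m1 * k, m2 = df$m2 * k, m3 = df$m3 * k)
  ct_k <- map_lesion(measurement_set(df2), t)
  expect_equal(ct_k$vertices, ct$vertices, tolerance = 1e-12)
})

test_that("quantification reports per-region areas, percentages and totals", {
  stuff <- make_default_template(n_regions = 4L, ap_span = c(1, -1),
                                 units_per_mm = 10)
  t <- stuff$template
  syn <- stuff$syn
  # lesion polygon identical to region R01 -> 100% of R01, 25% of cortex
  ct <- structure(list(vertices = t$regions$R01,
                       medial_idx = 1L:2L, lateral_idx = 3L:4L,
                       is_dummy = rep(FALSE, 4L), method = "linear",
                       degenerate = FALSE, day = 1L),
                  class = "lesion_contour")
  q <- quantify(ct, t)
  expect_equal(q$per_region$region, "R01")
  expect_equal(q$per_region$percent, 100, tolerance = 1e-9)
  expect_equal(q$total_area_mm2, 1, tolerance = 1e-9)
  expect_equal(q$total_percent_of_cortex, 25, tolerance = 1e-9)

  # rectangle covering the bottom half of R01 and R02 (top grid row):
  # 50% of each, total 1 mm^2
  y_mid <- (10 + 20) / 2  # top row spans y 10..20 in template units
  half <- cbind(c(syn$medial_x, syn$fissure_x, syn$fissure_x, syn$medial_x),
                c(y_mid, y_mid, 20, 20))
  ct2 <- ct
  ct2$vertices <- half
  q2 <- quantify(ct2, t)
  expect_setequal(q2$per_region$region, c("R01", "R02"))
  expect_equal(q2$per_region$percent, c(50, 50), tolerance = 1e-9)
  expect_equal(q2$total_area_mm2, 1, tolerance = 1e-9)
  # invariant: total equals the sum of per-region areas
  expect_equal(q2$total_area_mm2, sum(q2$per_region$area_mm2))

  # contour fully outside the cortex
  ct3 <- ct
  ct3$vertices <- cbind(c(500, 510, 510, 500), c(500, 500, 510, 510))
  expect_warning(q3 <- quantify(ct3, t), "outside")
  expect_equal(q3$total_area_mm2, 0)
})

test_that("per-region intersection areas agree with a Monte-Carlo oracle", {
  skip_if_not_installed("sp")
  stuff <- make_default_template(n_regions = 16L)
  t <- stuff$template
  truth <- synthetic_lesion_truth(stuff$syn)
  ms <- synthetic_lesion_measurements(truth, spacing = 0.2)
  ct <- map_lesion(ms, t, method = "linear")
  q <- quantify(ct, t)
  set.seed(23)
  r2 <- t$units_per_mm^2
  for (i in seq_len(nrow(q$per_region))) {
    reg <- t$regions[[q$per_region$region[i]]]
    want <- raster_intersection_area(ct$vertices, reg, n_grid = 500L) / r2
    expect_lt(abs(q$per_region$area_mm2[i] - want),
              0.01 * max(want, 0.5))
  }
})

test_that("single-slice sets degenerate to a zero quantification", {
  t <- make_fissure_template()
  ms <- measurement_set(data.frame(mb = 0, m1 = 4, m2 = 3, m3 = 1))
  expect_warning(ct <- map_lesion(ms, t), "degenerate")
  expect_warning(q <- quantify(ct, t), "degenerate")
  expect_equal(q$total_area_mm2, 0)
  expect_equal(nrow(q$per_region), 0L)
})
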