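test_that("resampling places points at uniform arc length and preserves endpoints", {
  # closed unit square traced by 5 points, n = 9 -> every half-edge point
  square <- tibble::tibble(x_mm = c(0, 1, 1, 0, 0), y_mm = c(0, 0, 1, 1, 0))
  rs <- resample_contour(square, 9L)
  expect_equal(as.matrix(rs),
               cbind(c(0, .5, 1, 1, 1, .5, 0, 0, 0), c(0, 0, 0, .5, 1, 1, 1, .5, 0)),
               ignore_attr = TRUE, tolerance = 1e-12)

  # idempotence: resampling an already-uniform contour returns the same points
  circ <- circle_pts(120, closed = FALSE) # 119 equal chords
  again <- resample_contour(circ, 120L)
  expect_lt(max(abs(as.matrix(circ) - as.matrix(again))), 1e-9)

  # random 12-gon: output arc positions uniform, checked against a dense
  # brute-force arc-length table
  set.seed(7)
  ang <- sort(stats::runif(12, 0, 2 * pi))
  gon <- tibble::tibble(x_mm = 20 * cos(ang) * stats::runif(12, .8, 1.2),
                        y_mm = 20 * sin(ang) * stats::runif(12, .8, 1.2))
  rs <- resample_contour(gon, 100L)
  pos <- arc_position_of(gon, rs$x_mm, rs$y_mm, sub = 20000L)
  total <- brute_length(gon)
  expect_lt(max(abs(pos - seq(0, total, length.out = 100))), total * 1e-4)
  expect_lt(max(abs(diff(pos) - total / 99)), total * 2e-4)

  # degenerate input
  flat <- tibble::tibble(x_mm = rep(0, 8) + c(0, 1e-300, 0, 1e-300, 0, 1e-300, 0, 1e-300),
                         y_mm = rep(0, 8))
  expect_error(resample_contour(flat, 16L), class = "lamotion_invalid_geometry")
})

test_that("contour length matches closed forms and a brute-force oracle", {
  expect_equal(contour_length(tibble::tibble(x_mm = c(0, 3, 3), y_mm = c(0, 0, 4))), 7)
  expect_equal(contour_length(circle_pts(720, r = 30)), 2 * pi * 30,
               tolerance = 1e-4)
  set.seed(11)
  poly <- tibble::tibble(x_mm = stats::rnorm(25, 0, 10), y_mm = stats::rnorm(25, 0, 10))
  expect_equal(contour_length(poly), brute_length(poly), tolerance = 1e-12)
})

test_that("contour length is invariant under rigid motion", {
  poly <- blob_pts()
  moved <- rotate_pts(poly, 0.83, about = c(5, -2))
  moved$x_mm <- moved$x_mm + 13.7
  moved$y_mm <- moved$y_mm - 41.2
  expect_equal(contour_length(moved), contour_length(poly), tolerance = 1e-12)
  expect_lt(abs(contour_length(moved) - contour_length(poly)), 1e-9)
})

test_that("resampling preserves total length within 0.1% on smooth convex contours", {
  for (shape in list(circle_pts(400, r = 30), ellipse_gap_pts(n = 400, gap_deg = 0.5))) {
    for (n in c(100L, 200L, 399L)) {
      rs <- resample_contour(shape, n)
      expect_lt(abs(contour_length(rs) - contour_length(shape)) / contour_length(shape),
                1e-3)
    }
  }
})

test_that("center of mass is arc-length weighted, chord-closed, and scales correctly", {
  expect_equal(unname(center_of_mass(circle_pts(360, r = 20, center = c(10, -5)))),
               c(10, -5), tolerance = 1e-6)
  expect_equal(unname(center_of_mass(tibble::tibble(x_mm = c(0, 2), y_mm = c(0, 0)))),
               c(1, 0))

  # asymmetric polygon: matches the vertex average after dense resampling
  poly <- blob_pts(seed = 3)
  dense <- resample_contour(rbind(poly, poly[1, ]), 100000L)
  expect_equal(unname(center_of_mass(poly)),
               c(mean(dense$x_mm), mean(dense$y_mm)), tolerance = 1e-3)

  # scaling a contour about the origin scales the centroid by the same factor
  sc <- poly
  sc$x_mm <- 2.5 * sc$x_mm
  sc$y_mm <- 2.5 * sc$y_mm
  expect_equal(unname(center_of_mass(sc)), 2.5 * unname(center_of_mass(poly)),
               tolerance = 1e-12)
})

test_that("segment radii recover constant and per-point values and match integration", {
  circ <- circle_pts(120, r = 25, closed = FALSE)
  for (k in c(3L, 6L, 12L)) {
    rad <- segment_radii(circ, c(0, 0), n_segments = k, resample = FALSE)
    expect_lt(max(abs(rad$radius_mm - 25)), 1e-6)
  }
  # n_segments = point count -> per-point distances to the center
  few <- circle_pts(12, r = 10, closed = FALSE)
  rad <- segment_radii(few, c(0, 0), n_segments = 12L, resample = FALSE)
  expect_equal(rad$radius_mm, rep(10, 12), tolerance = 1e-12)

  # ellipse quarters vs an arc-length-weighted numeric-integration oracle
  ell <- ellipse_gap_pts(a = 30, b = 20, gap_deg = 1e-9, n = 4000)
  got <- segment_radii(ell, c(0, 0), n_segments = 4L, n_points = 400L)
  theta <- seq(-pi / 2, 3 * pi / 2, length.out = 1e6)
  mid <- (theta[-1] + theta[-1e6]) / 2
  ds <- sqrt((30 * sin(mid))^2 + (20 * cos(mid))^2) * diff(theta)
  r_mid <- sqrt((30 * cos(mid))^2 + (20 * sin(mid))^2)
  s_mid <- cumsum(ds) - ds / 2
  qbin <- pmin(floor(4 * s_mid / sum(ds)) + 1, 4)
  oracle <- as.numeric(tapply(r_mid * ds, qbin, sum) / tapply(ds, qbin, sum))
  expect_equal(got$radius_mm, oracle, tolerance = 5e-3)

  # a zero radius (center on the contour) is flagged
  line <- tibble::tibble(x_mm = seq(-6, 6, length.out = 13), y_mm = rep(0, 13))
  expect_error(segment_radii(line, c(0, 0), n_segments = 13L, resample = FALSE),
               class = "lamotion_invalid_geometry")
})

test_that("contour validation rejects malformed input", {
  expect_error(contour_length(tibble::tibble(x_mm = c(0, NA), y_mm = c(0, 1))),
               class = "lamotion_invalid_geometry")
  dup <- tibble::tibble(x_mm = c(0, 1, 1, 2, 3, 4, 5, 6), y_mm = rep(0, 8))
  expect_error(contour_length(dup), class = "lamotion_invalid_geometry")
  expect_error(contour_length(list(1, 2)), class = "lamotion_invalid_input")
})
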