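# Sequence whose contour is an open circular arc (60-degree annulus gap at
# the bottom) centered at (0, 30), symmetric about x = 0, with annulus
# landmarks on the x-axis: mv_center (0,0), axis (0,-1) from the LA center.
mv_test_seq <- function(center = c(0, 30), lm = rbind(c(-10, 0), c(10, 0)),
                        translate = NULL, n_frames = 10) {
  base <- ellipse_gap_pts(a = 20, b = 20, gap_deg = 60, n = 121, center = center)
  frames <- lapply(seq_len(n_frames), function(i) {
    if (is.null(translate)) return(base)
    off <- translate(i)
    tibble::tibble(x_mm = base$x_mm + off[1], y_mm = base$y_mm + off[2])
  })
  mv <- lapply(seq_len(n_frames), function(i) {
    if (is.null(translate)) return(lm)
    sweep(lm, 2, -translate(i))
  })
  make_seq(frames, mv = mv)
}

test_that("MV geometry is the landmark midpoint with a unit axis from the LA center", {
  geom <- mv_geometry(mv_test_seq())
  expect_equal(geom$mv_center, c(0, 0), tolerance = 1e-9)
  expect_equal(geom$mv_axis, c(0, -1), tolerance = 1e-9)
  expect_equal(sqrt(sum(geom$mv_axis^2)), 1, tolerance = 1e-12)

  # coincident landmarks are accepted: center = that point
  geom2 <- mv_geometry(mv_test_seq(lm = rbind(c(3, 0), c(3, 0))))
  expect_equal(geom2$mv_center, c(3, 0), tolerance = 1e-9)

  # rotation equivariance of the axis
  ang <- 0.7
  rotm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  base <- ellipse_gap_pts(a = 20, b = 20, gap_deg = 60, n = 121, center = c(0, 30))
  rot_pts <- rotate_pts(base, ang)
  lm_rot <- rbind(c(-10, 0), c(10, 0)) %*% t(rotm)
  geom3 <- mv_geometry(make_seq(rep(list(rot_pts), 10), mv = lm_rot))
  expect_equal(geom3$mv_axis, as.numeric(rotm %*% c(0, -1)), tolerance = 1e-9)

  expect_error(mv_geometry(make_seq(rep(list(base), 10))),
               class = "lamotion_missing_landmark")
  # landmarks placed so mv_center coincides exactly with the LA center: no axis
  la_ctr <- mv_geometry(mv_test_seq())$la_center
  expect_error(
    mv_geometry(mv_test_seq(lm = rbind(la_ctr - c(10, 0), la_ctr + c(10, 0)))),
    class = "lamotion_degenerate_axis"
  )
})

test_that("rigid translations project onto the expected component only", {
  tau <- function(i) c(0, -(i - 1) * 0.5) # along axis (0,-1)
  seq_along_axis <- mv_test_seq(translate = tau)
  dec <- decompose_radial(seq_along_axis)
  expect_lt(max(abs(dec$pmr)), 1e-10)
  # cmr ~ translation magnitude / reference radius; the chord-closed centroid
  # of the open arc sits slightly off the circle center, so per-segment radii
  # vary around 20 mm and the normalised mean lands within ~1%
  expect_equal(dec$cmr, (0:9) * 0.5 / 20, tolerance = 0.01)
  expect_equal(dec$cmr / max(dec$cmr), (0:9) / 9, tolerance = 1e-12)

  tau_perp <- function(i) c((i - 1) * 0.5, 0)
  dec2 <- decompose_radial(mv_test_seq(translate = tau_perp))
  expect_lt(max(abs(dec2$cmr)), 1e-10)
  expect_equal(dec2$pmr, (0:9) * 0.5 / 20, tolerance = 0.01)
  expect_equal(dec2$pmr / max(dec2$pmr), (0:9) / 9, tolerance = 1e-12)
})

test_that("mixed contraction/translation matches a closed-form per-point oracle", {
  # circle contracting about its center while translating along the MV axis:
  # per segment, displacement = (lam-1) * r0 * u + tau, projected in closed form
  ctr <- c(0, 30)
  lam <- c(1, 1.08, 1.15, 1.10, 1.05, 1.02, 1.0, 0.98, 0.97, 1.0)
  tau <- seq(0, 4.5, by = 0.5)
  frames <- lapply(1:10, function(i) {
    p <- circle_pts(480, r = 20, center = c(0, 0))
    tibble::tibble(x_mm = lam[i] * p$x_mm + ctr[1],
                   y_mm = lam[i] * p$y_mm + ctr[2] - tau[i])
  })
  mv <- lapply(1:10, function(i) rbind(c(-10, -tau[i]), c(10, -tau[i])))
  seq <- make_seq(frames, mv = mv)
  per <- decompose_radial(seq, per_segment = TRUE)

  # oracle: after uniform arc-length resampling to 120 points, a closed
  # circle's points sit at angles 2*pi*i/119; segment unit vectors follow in
  # closed form
  phi <- 2 * pi * (0:119) / 119
  seg_of <- rep(1:12, each = 10)
  u <- cbind(tapply(cos(phi), seg_of, mean), tapply(sin(phi), seg_of, mean))
  axis <- c(0, -1)
  for (i in c(3L, 8L)) {
    d_exp <- cbind(20 * (lam[i] - 1) * u[, 1], 20 * (lam[i] - 1) * u[, 2] - tau[i])
    got <- per[per$time_ms == seq$times_ms[i], ]
    expect_equal(got$c_disp_mm, d_exp[, 1] * axis[1] + d_exp[, 2] * axis[2],
                 tolerance = 1e-3)
    expect_equal(got$total_disp_mm, sqrt(rowSums(d_exp^2)), tolerance = 1e-3)
  }
})

test_that("squared centric plus squared perpendicular equals squared displacement", {
  for (s in 1:3) {
    ph <- la_phantom(translation_along_mm = 4, translation_across_mm = 2,
                     noise_sd_mm = 0.3, seed = s)
    for (v in ph$views) {
      per <- decompose_radial(v, per_segment = TRUE)
      per <- per[per$total_disp_mm > 1e-9, ]
      rel <- abs(per$c_disp_mm^2 + per$p_disp_mm^2 - per$total_disp_mm^2) /
        per$total_disp_mm^2
      expect_lt(max(rel), 1e-12)
    }
  }
})

test_that("decomposition is invariant under rotation of all inputs", {
  ph <- la_phantom(translation_along_mm = 3, translation_across_mm = 1.5)
  seq <- ph$views[[1]]
  dec <- decompose_radial(seq)

  ang <- -1.1
  rotm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  frames_rot <- lapply(seq$frames, function(m) contour_tibble_rot(m, rotm))
  mv_rot <- lapply(seq$mv_points, function(m) m %*% t(rotm))
  seq_rot <- la_sequence(frames_rot, seq$times_ms, view = seq$view, mv_points = mv_rot)
  dec_rot <- decompose_radial(seq_rot)
  expect_equal(dec_rot$cmr, dec$cmr, tolerance = 1e-9)
  expect_equal(dec_rot$pmr, dec$pmr, tolerance = 1e-9)
})

test_that("decomposed phasic extraction mirrors the radial phasic rules", {
  t_ms <- seq(0, 1000, by = 50)
  mr <- stats::approx(c(0, 400, 700, 750, 1000), c(0, 0.351, 0.179, 0.179, 0),
                      xout = t_ms)$y
  phases <- detect_phases(mr, t_ms)
  dp <- decomposed_phasic(tibble::tibble(time_ms = t_ms, cmr = mr, pmr = 0), phases)
  expect_equal(dp$cmr_r, 35.1)
  expect_equal(dp$cmr_a, 17.9)
  expect_equal(dp$cmr_c, 17.2, tolerance = 1e-9)
  expect_equal(dp$pmr_r, 0)
  expect_equal(dp$cmr_r, dp$cmr_c + dp$cmr_a)

  bad <- phases
  bad$i_a <- 99L
  expect_error(decomposed_phasic(tibble::tibble(time_ms = t_ms, cmr = mr, pmr = 0), bad),
               class = "lamotion_phase_window_error")
})

test_that("segment grid must be commensurate with the resampling grid", {
  expect_error(decompose_radial(mv_test_seq(), n_segments = 7L, n_points = 120L),
               class = "lamotion_configuration_error")
})
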