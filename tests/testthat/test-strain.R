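make_circle_seq <- function(radii, times = NULL, n = 120) {
  frames <- lapply(radii, function(r) circle_pts(n, r = r, closed = FALSE))
  make_seq(frames, times)
}

test_that("longitudinal strain matches perimeter ratios", {
  # circle 30 -> 36 mm: sl = 0.20 exactly (polygon perimeter scales with radius)
  seq <- make_circle_seq(c(30, rep(30, 8), 36))
  sl <- longitudinal_strain_curve(seq)$sl
  expect_equal(sl[1], 0)
  expect_equal(sl[10], 0.20, tolerance = 1e-12)

  # rigid translation leaves strain at zero in every frame
  base <- blob_pts()
  frames <- lapply(0:9, function(i) {
    tibble::tibble(x_mm = base$x_mm + 3 * i, y_mm = base$y_mm - 2 * i)
  })
  expect_lt(max(abs(longitudinal_strain_curve(make_seq(frames))$sl)), 1e-12)

  # ellipse (20, 30) -> (24, 33): matches a dense numerical perimeter oracle
  ell0 <- ellipse_gap_pts(a = 30, b = 20, gap_deg = 1e-9, n = 1000)
  ell1 <- ellipse_gap_pts(a = 33, b = 24, gap_deg = 1e-9, n = 1000)
  frames <- c(list(ell0), rep(list(ell0), 8), list(ell1))
  sl <- longitudinal_strain_curve(make_seq(frames))$sl
  per0 <- brute_length(ellipse_gap_pts(a = 30, b = 20, gap_deg = 1e-9, n = 100000))
  per1 <- brute_length(ellipse_gap_pts(a = 33, b = 24, gap_deg = 1e-9, n = 100000))
  expect_equal(sl[10], per1 / per0 - 1, tolerance = 1e-5)
})

test_that("radial motion fraction tracks uniform and anisotropic scaling", {
  base <- blob_pts()
  ctr <- unname(center_of_mass(resample_contour(base, 120L)))
  scale_about <- function(df, fx, fy = fx) {
    tibble::tibble(x_mm = ctr[1] + fx * (df$x_mm - ctr[1]),
                   y_mm = ctr[2] + fy * (df$y_mm - ctr[2]))
  }
  # uniform scaling by (1+s) about the center of mass: mr = s (expansion
  # positive); contraction by 0.8 gives -0.20
  frames <- list(base, scale_about(base, 1.2), scale_about(base, 0.8),
                 base, base, base, base, base, base, base)
  mr <- radial_motion_curve(make_seq(frames))$mr
  expect_equal(mr[1], 0)
  expect_equal(mr[2], 0.2, tolerance = 1e-9)
  expect_equal(mr[3], -0.2, tolerance = 1e-9)
  expect_lt(max(abs(mr[4:10])), 1e-12)

  # anisotropic scaling of a circle vs per-segment brute-force radii
  circ <- circle_pts(480, r = 25, closed = FALSE)
  an <- tibble::tibble(x_mm = 0.9 * circ$x_mm, y_mm = 0.7 * circ$y_mm)
  frames <- c(list(circ), rep(list(an), 9))
  got <- radial_motion_curve(make_seq(frames), n_segments = 12, n_points = 120)$mr[2]
  # oracle: uniform-arc positions from a dense table, binned distances
  oracle_radii <- function(df) {
    tab <- dense_arc_table(df, sub = 400L)
    total <- max(tab$s)
    want <- seq(0, total, length.out = 120)
    idx <- vapply(want, function(s) which.min(abs(tab$s - s)), integer(1))
    px <- tab$x[idx]; py <- tab$y[idx]
    c0 <- unname(center_of_mass(circ))
    r <- sqrt((px - c0[1])^2 + (py - c0[2])^2)
    as.numeric(tapply(r, rep(1:12, each = 10), mean))
  }
  m0 <- oracle_radii(circ)
  mt <- oracle_radii(an)
  expect_equal(got, mean((mt - m0) / m0), tolerance = 1e-4)
})

test_that("rate curves recover linear, constant, and sinusoidal derivatives", {
  t_ms <- seq(0, 1000, by = 50)
  expect_equal(rate_curve(0.3 * t_ms / 1000, t_ms),
               rep(0.3, 21), tolerance = 1e-9)
  expect_equal(rate_curve(rep(0.5, 21), t_ms), rep(0, 21))
  expect_error(rate_curve(1:5, c(0, 1, 1, 2, 3)), class = "lamotion_invalid_input")

  n <- 200
  tt <- seq(0, 2 * pi, length.out = n)
  got <- rate_curve(sin(tt), tt * 1000, smooth = NULL)
  expect_lt(max(abs(got - cos(tt))), (2 * pi / n)^2)
})

test_that("phase detection finds the reservoir peak and the A-wave shoulder", {
  t_ms <- seq(0, 1000, by = 50)
  pw <- stats::approx(c(0, 400, 700, 750, 1000), c(0, 0.332, 0.167, 0.167, 0),
                      xout = t_ms)$y
  ph <- detect_phases(pw, t_ms)
  expect_equal(ph$t_peak_ms, 400)
  expect_true(ph$t_a_onset_ms >= 700 && ph$t_a_onset_ms <= 750)

  # smooth phantom: boundaries within one frame interval of the generator's
  ph20 <- la_phantom(n_frames = 20)
  fit <- la_strain(ph20$views)
  dt <- 1000 / 19
  expect_lt(max(abs(fit$phases$t_peak_ms - ph20$truth$phases$t_peak_ms)), dt)
  expect_lt(max(abs(fit$phases$t_a_onset_ms - ph20$truth$phases$t_a_onset_ms)), dt)

  # flat curve has no phases
  expect_error(detect_phases(rep(0, 21), t_ms),
               class = "lamotion_phase_detection_failure")
  # monotonically rising curve has no interior peak
  expect_error(detect_phases(seq(0, 0.3, length.out = 21), t_ms),
               class = "lamotion_phase_detection_failure")
})

test_that("phasic extraction reproduces constructed amplitudes and additivity", {
  t_ms <- seq(0, 1000, by = 50)
  sl <- stats::approx(c(0, 400, 700, 750, 1000), c(0, 0.332, 0.167, 0.167, 0),
                      xout = t_ms)$y
  curves <- tibble::tibble(time_ms = t_ms, sl = sl, mr = sl,
                           srl = rate_curve(sl, t_ms), vr = rate_curve(sl, t_ms))
  idx <- phasic_indices(curves, detect_phases(sl, t_ms))
  expect_equal(idx$sl_r, 33.2)
  expect_equal(idx$sl_a, 16.7)
  expect_equal(idx$sl_c, 16.5)
  expect_equal(idx$sl_r, idx$sl_c + idx$sl_a)
  expect_equal(idx$mr_r, idx$mr_c + idx$mr_a)

  # symmetric triangle with explicit A-onset at the midpoint of the decay:
  # conduit and contraction split the reservoir amplitude evenly
  tri <- stats::approx(c(0, 500, 1000), c(0, 0.30, 0), xout = t_ms)$y
  phases <- detect_phases(tri, t_ms, t_a_onset_ms = 750)
  idx <- phasic_indices(tibble::tibble(time_ms = t_ms, sl = tri, mr = tri,
                                       srl = rate_curve(tri, t_ms),
                                       vr = rate_curve(tri, t_ms)), phases)
  expect_equal(idx$sl_c, idx$sl_r / 2, tolerance = 1e-9)
  expect_equal(idx$sl_a_over_sl_r, 0.5, tolerance = 1e-9)

  # out-of-range boundaries are rejected
  bad <- detect_phases(tri, t_ms, t_a_onset_ms = 750)
  bad$i_a <- 60L
  expect_error(phasic_indices(curves, bad), class = "lamotion_phase_window_error")
})

test_that("phantom amplitudes are recovered within 2% at 20 frames, zero noise", {
  ph <- la_phantom(sl_r = 33.2, sl_a = 16.7, n_frames = 20L, noise_sd_mm = 0)
  g <- glance(la_strain(ph$views))
  truth <- ph$truth$indices
  for (v in c("sl_r", "sl_c", "sl_a", "mr_r", "mr_c", "mr_a")) {
    expect_lt(abs(g[[v]] - truth[[v]]) / abs(truth[[v]]), 0.02)
  }
  expect_lt(abs(g$sl_a_over_sl_r - truth$sl_a_over_sl_r) / truth$sl_a_over_sl_r, 0.02)
})

test_that("rate indices converge to the analytic peaks at high temporal resolution", {
  ph <- la_phantom(n_frames = 200L)
  g <- glance(la_strain(ph$views))
  truth <- ph$truth$indices
  for (v in c("srl_s", "srl_e", "srl_a")) {
    expect_lt(abs(g[[v]] - truth[[v]]) / abs(truth[[v]]), 0.02)
  }
  # E'/A' sign convention: conduit and contraction peaks negative
  expect_lt(g$srl_e, 0)
  expect_lt(g$srl_a, 0)
  expect_gt(g$srl_s, 0)
})

test_that("time dilation leaves amplitudes unchanged and scales rates inversely", {
  a <- glance(la_strain(la_phantom(cycle_ms = 1000)$views))
  b <- glance(la_strain(la_phantom(cycle_ms = 800)$views))
  for (v in c("sl_r", "sl_c", "sl_a", "mr_r", "mr_c", "mr_a",
              "sl_a_over_sl_r", "mr_a_over_mr_r")) {
    expect_equal(a[[v]], b[[v]], tolerance = 1e-9)
  }
  for (v in c("srl_s", "srl_e", "srl_a", "vr_s", "vr_e", "vr_a")) {
    expect_equal(b[[v]], a[[v]] / 0.8, tolerance = 1e-9)
  }
})

test_that("integrating the strain rate over the cycle recovers the net strain", {
  ph <- la_phantom(n_frames = 20L)
  curves <- strain_curves(ph$views[[1]])
  trapz <- function(y, t) sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  net <- trapz(curves$srl, curves$time_ms / 1000)
  expect_equal(net, curves$sl[nrow(curves)] - curves$sl[1], tolerance = 1e-12)
})

test_that("cross-view averaging is field-wise with ratios recomputed", {
  ph <- la_phantom(view_spread = 0.05)
  fit <- la_strain(ph$views)
  # identical indices in all views -> unchanged
  one <- fit$indices[1, setdiff(names(fit$indices), "view")]
  expect_equal(global_average(dplyr::bind_rows(one, one, one)), one)
  # two views with sl_r 30 and 36 -> 33
  two <- dplyr::bind_rows(one, one)
  two$sl_r <- c(30, 36)
  expect_equal(global_average(two)$sl_r, 33)
  # three phantom views: equals an independent column mean
  per <- fit$indices[setdiff(names(fit$indices), "view")]
  expect_equal(glance(fit)$sl_r, mean(per$sl_r), tolerance = 1e-12)
  expect_equal(glance(fit)$srl_e_over_a,
               abs(mean(per$srl_e)) / abs(mean(per$srl_a)), tolerance = 1e-12)
  expect_error(global_average(per[0, ]), class = "lamotion_invalid_input")
})

test_that("sequences with too few frames are rejected", {
  frames <- rep(list(circle_pts(60, closed = FALSE)), 5)
  expect_error(make_seq(frames), class = "lamotion_insufficient_temporal_resolution")
})
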