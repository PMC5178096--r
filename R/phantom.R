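#' Reference cohort means for obese-T2D vs control LA function and cardiac fat
#'
#' Published group means and standard deviations (healthy controls, n = 19,
#' vs obese type-2-diabetes patients, n = 20) for the LA phasic indices,
#' their rate ratios, the decomposed radial components, the Dixon fat
#' readouts and body metrics. These serve as the default effect table of
#' [simulate_cohort()] and as the reference values for desk-recomputable
#' percent changes; they are inputs to the simulator, not quantities this
#' package claims to reproduce from images.
#'
#' @return Tibble with `variable`, `unit`, `mean_control`, `sd_control`,
#'   `mean_case`, `sd_case`.
#' @export
cohort_reference <- function() {
  tibble::tribble(
    ~variable,          ~unit,     ~mean_control, ~sd_control, ~mean_case, ~sd_case,
    "la_edv",           "mL",      87.1,  24.7,  95.8,  22.3,
    "la_esv",           "mL",      37.4,  14.7,  40.5,  12.8,
    "la_ef",            "%",       57.7,   6.1,  58.0,   7.9,
    "sl_r",             "%",       33.2,   6.8,  29.4,   8.4,
    "sl_c",             "%",       16.5,   4.8,  13.1,   5.0,
    "sl_a",             "%",       16.7,   3.9,  16.8,   4.8,
    "sl_a_over_sl_r",   "ratio",    0.5,   0.1,   0.6,   0.1,
    "srl_s",            "1/s",      1.4,   0.3,   1.4,   0.4,
    "srl_e",            "1/s",     -1.5,   0.4,  -1.2,   0.6,
    "srl_a",            "1/s",     -1.4,   0.4,  -1.5,   0.5,
    "srl_e_over_a",     "ratio",    1.2,   0.5,   0.9,   0.3,
    "mr_r",             "%",       35.1,   6.7,  31.5,   9.1,
    "mr_c",             "%",       17.2,   4.7,  13.6,   5.9,
    "mr_a",             "%",       17.9,   4.3,  18.2,   4.3,
    "mr_a_over_mr_r",   "ratio",    0.5,   0.1,   0.6,   0.1,
    "vr_s",             "1/s",      1.4,   0.3,   1.5,   0.6,
    "vr_e",             "1/s",     -1.6,   0.5,  -1.3,   0.6,
    "vr_a",             "1/s",     -1.5,   0.5,  -1.8,   0.6,
    "vr_e_over_a",      "ratio",    1.2,   0.5,   0.7,   0.2,
    "cmr_r",            "%",       34.3,   9.6,  37.2,  10.6,
    "cmr_c",            "%",       14.0,   5.7,  11.3,   5.7,
    "cmr_a",            "%",       20.3,   5.6,  26.0,   6.3,
    "pmr_r",            "%",       53.3,  17.8,  42.5,  12.6,
    "pmr_c",            "%",       21.0,  15.2,  14.0,   9.5,
    "pmr_a",            "%",       32.3,  10.7,  28.6,  10.7,
    "intramyo_ff",      "%",        6.0,   1.5,   7.9,   3.7,
    "efv_abs",          "mL",     176.9,  76.6, 298.9,  83.4,
    "efv_indexed",      "mL/m2",   89.7,  29.6, 134.6,  30.8,
    "ef_fraction",      "%",       21.0,   4.0,  28.4,   5.5,
    "bsa",              "m2",       1.9,   0.2,   2.2,   0.2,
    "bmi",              "kg/m2",   24.8,   2.6,  39.7,   5.8
  )
}

# Generator-local arc-length-weighted centroid (chord-closed). Written
# independently of the analysis geometry so phantom construction does not
# lean on the code under test.
phantom_centroid <- function(pts) {
  closed <- rbind(pts, pts[1L, ])
  a <- closed[-nrow(closed), , drop = FALSE]
  b <- closed[-1L, , drop = FALSE]
  len <- sqrt(rowSums((b - a)^2))
  colSums((a + b) / 2 * len) / sum(len)
}

# Piecewise cosine-smoothed strain profile: exact amplitudes at the phase
# breakpoints, continuous first derivative (zero at each breakpoint).
strain_profile <- function(t_frac, a_r, a_a, tp, ta) {
  s <- numeric(length(t_frac))
  i1 <- t_frac <= tp
  i2 <- t_frac > tp & t_frac <= ta
  i3 <- t_frac > ta
  s[i1] <- a_r / 2 * (1 - cos(pi * t_frac[i1] / tp))
  s[i2] <- a_a + (a_r - a_a) / 2 * (1 + cos(pi * (t_frac[i2] - tp) / (ta - tp)))
  s[i3] <- a_a / 2 * (1 + cos(pi * (t_frac[i3] - ta) / (1 - ta)))
  s
}

#' Dynamic LA contour phantom with known phasic ground truth
#'
#' Builds three long-axis views of a beating left atrium as differently
#' oriented and squeezed elliptical arcs (the mitral-annulus gap spans
#' `gap_deg` degrees; the endpoints are the annulus landmarks). The contour
#' is scaled uniformly about its reference center of mass by
#' `1 + sl(t)`, where `sl(t)` is a piecewise cosine-smoothed profile rising
#' to `sl_r` at `t_peak_frac`, descending to `sl_a` at `t_a_onset_frac` and
#' returning to zero at the cycle end — so perimeter strain and radial
#' motion fraction both equal `sl(t)` by construction (when no translation
#' is added). A rigid translation along/across the mitral-valve axis with a
#' `sin^2` time profile emulates ventricular translational motion for the
#' cMr/pMr decomposition. Per-view amplitude factors `1 + view_spread *
#' {-1, 0, +1}` give genuine inter-view spread with the target preserved as
#' the cross-view mean.
#'
#' @param base_radius_mm Major semi-axis of the reference ellipse.
#' @param sl_r,sl_a Target reservoir and contraction amplitudes (%); the
#'   conduit amplitude is `sl_r - sl_a` and must be non-negative.
#' @param t_peak_frac,t_a_onset_frac Phase breakpoints as cycle fractions.
#' @param cycle_ms Cycle duration (ms).
#' @param n_frames Cine phases (default 20); the last frame closes the cycle.
#' @param translation_along_mm,translation_across_mm Peak rigid translation
#'   along / across the MV axis (mm).
#' @param view_spread Relative per-view amplitude spread (default 0).
#' @param noise_sd_mm Gaussian jitter added to every point coordinate (mm).
#' @param n_contour_points Raw points per generated contour.
#' @param gap_deg Angular width of the annulus gap (degrees).
#' @param seed Seed for the jitter.
#' @return List with `views` (named list of [la_sequence()]) and `truth`
#'   (list: `indices` one-row tibble of constructed amplitudes in % plus
#'   analytic continuous-time rate peaks in 1/s, `phases`, `sl_curve`,
#'   and the generator parameters).
#' @export
la_phantom <- function(base_radius_mm = 30, sl_r = 33.2, sl_a = 16.7,
                       t_peak_frac = 0.4, t_a_onset_frac = 0.75,
                       cycle_ms = 1000, n_frames = 20L,
                       translation_along_mm = 0, translation_across_mm = 0,
                       view_spread = 0, noise_sd_mm = 0,
                       n_contour_points = 200L, gap_deg = 50, seed = 1L) {
  if (!(t_peak_frac > 0 && t_peak_frac < t_a_onset_frac && t_a_onset_frac < 1)) {
    stop_invalid_params("need 0 < t_peak_frac < t_a_onset_frac < 1")
  }
  if (sl_a > sl_r) stop_invalid_params("sl_a > sl_r implies a negative conduit amplitude")
  a_r <- sl_r / 100
  a_a <- sl_a / 100
  times <- seq(0, cycle_ms, length.out = n_frames)
  t_frac <- times / cycle_ms
  sl_t <- strain_profile(t_frac, a_r, a_a, t_peak_frac, t_a_onset_frac)
  trans_w <- sin(pi * t_frac)^2

  views_def <- list(
    `2-chamber` = list(ecc = 0.80, rot = -0.20, fac = 1 - view_spread),
    `4-chamber` = list(ecc = 0.90, rot = 0.15, fac = 1),
    `3-chamber` = list(ecc = 0.85, rot = 0.00, fac = 1 + view_spread)
  )
  g <- gap_deg / 2 * pi / 180
  theta <- seq(-pi / 2 + g, 3 * pi / 2 - g, length.out = n_contour_points)

  views <- withr::with_seed(seed, purrr::imap(views_def, function(vd, vname) {
    rot <- matrix(c(cos(vd$rot), sin(vd$rot), -sin(vd$rot), cos(vd$rot)), 2L)
    base <- cbind(base_radius_mm * cos(theta),
                  base_radius_mm * vd$ecc * sin(theta)) %*% t(rot)
    c0 <- phantom_centroid(base)
    mv_center0 <- (base[1L, ] + base[nrow(base), ]) / 2
    axis <- mv_center0 - c0
    axis <- axis / sqrt(sum(axis^2))
    perp <- c(-axis[2L], axis[1L])
    frames <- vector("list", n_frames)
    mv <- vector("list", n_frames)
    for (i in seq_len(n_frames)) {
      lam <- 1 + vd$fac * sl_t[i]
      shift <- trans_w[i] * (translation_along_mm * axis + translation_across_mm * perp)
      pts <- sweep(lam * sweep(base, 2L, c0), 2L, c0 + shift, `+`)
      lm <- sweep(lam * sweep(rbind(base[1L, ], base[nrow(base), ]), 2L, c0),
                  2L, c0 + shift, `+`)
      if (noise_sd_mm > 0) {
        pts <- pts + matrix(stats::rnorm(length(pts), 0, noise_sd_mm), ncol = 2L)
      }
      frames[[i]] <- contour_tibble(pts)
      mv[[i]] <- lm
    }
    la_sequence(frames, times, view = vname, mv_points = mv)
  }))

  tp_s <- t_peak_frac * cycle_ms / 1000
  ta_s <- t_a_onset_frac * cycle_ms / 1000
  tend_s <- cycle_ms / 1000
  truth_idx <- tibble::tibble(
    sl_r = sl_r, sl_c = sl_r - sl_a, sl_a = sl_a,
    sl_a_over_sl_r = sl_a / sl_r,
    mr_r = if (translation_along_mm == 0 && translation_across_mm == 0) sl_r else NA_real_,
    mr_c = if (translation_along_mm == 0 && translation_across_mm == 0) sl_r - sl_a else NA_real_,
    mr_a = if (translation_along_mm == 0 && translation_across_mm == 0) sl_a else NA_real_,
    srl_s = a_r * pi / (2 * tp_s),
    srl_e = -(a_r - a_a) * pi / (2 * (ta_s - tp_s)),
    srl_a = -a_a * pi / (2 * (tend_s - ta_s))
  )
  list(
    views = views,
    truth = list(
      indices = truth_idx,
      phases = list(t_peak_ms = t_peak_frac * cycle_ms,
                    t_a_onset_ms = t_a_onset_frac * cycle_ms,
                    cycle_end_ms = cycle_ms),
      sl_curve = tibble::tibble(time_ms = times, sl = sl_t),
      params = list(base_radius_mm = base_radius_mm, view_spread = view_spread,
                    translation_along_mm = translation_along_mm,
                    translation_across_mm = translation_across_mm,
                    noise_sd_mm = noise_sd_mm, seed = seed)
    )
  )
}

#' Concentric-shell Dixon fat/water phantom with voxel-counted ground truth
#'
#' A spherical blood pool (water-dominant), a myocardial shell with a
#' specified Dixon fat fraction, and an epicardial fat shell whose volume is
#' hit exactly by voxel selection (the `n` nearest voxels outside the
#' myocardium, `n = round(target / voxel volume)`), all inside a whole-heart
#' cardiac mask. Class intensities sum to `s0` so that the noise-free
#' voxelwise fat fraction is exact by construction. Gaussian noise is added
#' per image and clipped at zero (magnitude images are non-negative).
#'
#' @param dim_vox Grid dimensions (length 3, default 64^3).
#' @param voxel_mm Isotropic voxel size (mm, default 2.5).
#' @param r_blood_mm Blood-pool radius.
#' @param myo_thickness_mm Myocardial shell thickness.
#' @param efv_target_ml Target epicardial fat volume (mL).
#' @param myo_ff_pct Myocardial-shell fat fraction (%).
#' @param s0 In-phase signal scale (fat + water per voxel).
#' @param blood_ff_pct,fatshell_ff_pct Fat fractions of blood pool and fat
#'   shell (%).
#' @param noise_sd Gaussian noise SD on each of the fat and water images.
#' @param seed Seed for the noise.
#' @return List with `study` (a [dixon_study()] with a septal ROI on the
#'   central slice) and `truth` (voxel-counted `efv_ml`, `mask_ml`,
#'   `ef_fraction_pct`, `myo_ff_pct`, counts).
#' @export
dixon_phantom <- function(dim_vox = c(64L, 64L, 64L), voxel_mm = 2.5,
                          r_blood_mm = 24, myo_thickness_mm = 10,
                          efv_target_ml = 90, myo_ff_pct = 6,
                          s0 = 1000, blood_ff_pct = 2, fatshell_ff_pct = 90,
                          noise_sd = 0, seed = 1L) {
  vox_ml <- voxel_mm^3 / 1000
  ctr <- (dim_vox + 1) / 2 * voxel_mm
  ax <- lapply(1:3, function(i) (seq_len(dim_vox[i]) - 0.5) * voxel_mm)
  r <- sqrt(outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, `+`),
                  (ax[[3]] - ctr[3])^2, `+`))
  r_myo_out <- r_blood_mm + myo_thickness_mm
  blood <- r <= r_blood_mm
  myo <- r > r_blood_mm & r <= r_myo_out
  n_fat <- round(efv_target_ml / vox_ml)
  cand <- which(r > r_myo_out)
  r_max_ok <- min(dim_vox * voxel_mm) / 2 - voxel_mm
  cand <- cand[r[cand] <= r_max_ok]
  if (n_fat > length(cand) || !any(blood) || !any(myo)) {
    stop_invalid_params("requested shells exceed the phantom grid")
  }
  fat_idx <- cand[order(r[cand])][seq_len(n_fat)]
  fat_shell <- array(FALSE, dim_vox)
  fat_shell[fat_idx] <- TRUE
  mask <- blood | myo | fat_shell

  ff <- array(0, dim_vox)
  ff[blood] <- blood_ff_pct / 100
  ff[myo] <- myo_ff_pct / 100
  ff[fat_shell] <- fatshell_ff_pct / 100
  fat_img <- ff * s0 * mask
  water_img <- (1 - ff) * s0 * mask
  if (noise_sd > 0) {
    imgs <- withr::with_seed(seed, list(
      fat = pmax(fat_img + array(stats::rnorm(length(fat_img), 0, noise_sd), dim_vox), 0),
      water = pmax(water_img + array(stats::rnorm(length(water_img), 0, noise_sd), dim_vox), 0)
    ))
    fat_img <- imgs$fat
    water_img <- imgs$water
  }

  # "septal" ROI: myocardial-shell voxels on the central slice, one side only
  k <- ceiling(dim_vox[3L] / 2)
  roi <- array(FALSE, dim_vox)
  roi[, , k] <- myo[, , k]
  roi[seq_len(ceiling(dim_vox[1L] / 2)), , k] <- FALSE

  study <- dixon_study(fat_img, water_img, rep(voxel_mm, 3L), mask, septal_roi = roi)
  list(
    study = study,
    truth = list(
      efv_ml = n_fat * vox_ml,
      mask_ml = sum(mask) * vox_ml,
      ef_fraction_pct = 100 * n_fat / sum(mask),
      myo_ff_pct = myo_ff_pct,
      n_fat_vox = n_fat, n_mask_vox = sum(mask), n_roi_vox = sum(roi)
    )
  )
}

#' Simulate a two-group cohort from an effect table
#'
#' Per-subject values drawn from normal distributions with the per-group
#' means and SDs of `effect_table` ([cohort_reference()] by default, i.e.
#' control vs obese-T2D effect sizes).
#'
#' @param n_control,n_case Group sizes (defaults 19 and 20).
#' @param effect_table Tibble with `variable`, `mean_control`, `sd_control`,
#'   `mean_case`, `sd_case`.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return Tidy tibble: `subject_id`, `group` (`control` / `ObT2D`),
#'   `variable`, `value`.
#' @export
simulate_cohort <- function(n_control = 19L, n_case = 20L,
                            effect_table = cohort_reference(), seed = 1L) {
  if (n_control < 1L || n_case < 1L) stop_invalid_params("group sizes must be positive")
  ids <- c(sprintf("C%03d", seq_len(n_control)), sprintf("P%03d", seq_len(n_case)))
  grp <- rep(c("control", "ObT2D"), c(n_control, n_case))
  withr::with_seed(seed, purrr::pmap_dfr(
    effect_table[c("variable", "mean_control", "sd_control", "mean_case", "sd_case")],
    function(variable, mean_control, sd_control, mean_case, sd_case) {
      tibble::tibble(
        subject_id = ids, group = grp, variable = variable,
        value = c(stats::rnorm(n_control, mean_control, sd_control),
                  stats::rnorm(n_case, mean_case, sd_case))
      )
    }
  ))
}
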