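#' Left atrial strain and radial motion-fraction curves
#'
#' Longitudinal strain at frame t is the fractional change of the contour
#' length relative to the reference frame, `Sl(t) = (Lt - L0)/L0`. The radial
#' motion fraction is the per-segment fractional change of the radius taken
#' towards the center of mass of the *reference* contour, `(Mt - M0)/M0`,
#' averaged over segments; the reference center is held fixed across frames
#' so that ventricular translational motion registers as radial motion (this
#' is what the mitral-valve-referenced decomposition later separates out).
#' Expansion during the reservoir phase is positive for both quantities.
#'
#' @name strain-curves
NULL

#' @rdname strain-curves
#' @param seq An [la_sequence()].
#' @return `longitudinal_strain_curve()`: tibble with `time_ms` and
#'   dimensionless `sl` (`sl[1] == 0`).
#' @export
longitudinal_strain_curve <- function(seq) {
  stopifnot(inherits(seq, "la_sequence"))
  len <- vapply(seq$frames, function(m) contour_length(contour_tibble(m)), numeric(1))
  if (len[1L] <= 0) stop_invalid_geometry("reference contour has zero length")
  tibble::tibble(time_ms = seq$times_ms, sl = (len - len[1L]) / len[1L])
}

#' @rdname strain-curves
#' @param n_segments Number of contiguous radial segments (default 12).
#' @param n_points Resampling grid for point correspondence (default 120).
#' @param per_segment If `TRUE`, return per-segment fractions instead of the
#'   segment-averaged curve.
#' @return `radial_motion_curve()`: tibble with `time_ms` and dimensionless
#'   `mr` (or `time_ms`, `segment`, `mr` when `per_segment = TRUE`).
#' @export
radial_motion_curve <- function(seq, n_segments = 12L, n_points = 120L,
                                per_segment = FALSE) {
  stopifnot(inherits(seq, "la_sequence"))
  ref <- resample_contour(contour_tibble(seq$frames[[1L]]), n_points)
  center <- arc_centroid(as.matrix(ref))
  m0 <- segment_radii(ref, center, n_segments, n_points, resample = FALSE)$radius_mm
  per <- purrr::map2_dfr(seq$frames, seq$times_ms, function(pts, t) {
    mt <- segment_radii(contour_tibble(pts), center, n_segments, n_points)$radius_mm
    tibble::tibble(time_ms = t, segment = seq_len(n_segments), mr = (mt - m0) / m0)
  })
  if (per_segment) return(per)
  dplyr::summarise(per, mr = mean(.data$mr), .by = "time_ms")
}

# 3-point moving average; endpoints are left untouched so that one-sided
# differences at the boundaries see the raw samples.
smooth_ma <- function(x, window = 3L) {
  if (is.null(window) || window <= 1L) return(x)
  if (window %% 2L == 0L) stop_invalid_input("smoothing window must be odd")
  n <- length(x)
  half <- (window - 1L) %/% 2L
  if (n < window) return(x)
  out <- x
  sm <- stats::filter(x, rep(1 / window, window), sides = 2)
  idx <- (half + 1L):(n - half)
  out[idx] <- as.numeric(sm[idx])
  out
}

#' Temporal derivative of a strain/motion series
#'
#' Centered finite differences on interior samples and one-sided differences
#' at the ends, after an optional 3-point moving-average smoothing of the
#' interior (20-phase cine derivatives are noise-amplifying). Times are in
#' ms; the returned rate is per second.
#'
#' @param series Numeric series (dimensionless strain or motion fraction).
#' @param times_ms Strictly increasing sample times (ms).
#' @param smooth Odd moving-average window; `NULL`, `0` or `1` disables.
#' @return Numeric vector of d(series)/dt in s^-1.
#' @export
rate_curve <- function(series, times_ms, smooth = 3L) {
  if (length(series) < 3L) stop_invalid_input("at least 3 samples required")
  if (length(series) != length(times_ms)) stop_invalid_input("series/times length mismatch")
  if (any(diff(times_ms) <= 0)) stop_invalid_input("times must be strictly increasing")
  x <- smooth_ma(series, smooth)
  t_s <- times_ms / 1000
  n <- length(x)
  d <- numeric(n)
  d[1L] <- (x[2L] - x[1L]) / (t_s[2L] - t_s[1L])
  d[n] <- (x[n] - x[n - 1L]) / (t_s[n] - t_s[n - 1L])
  i <- 2L:(n - 1L)
  d[i] <- (x[i + 1L] - x[i - 1L]) / (t_s[i + 1L] - t_s[i - 1L])
  d
}

#' Detect the three atrial phases from the strain curve
#'
#' The reservoir peak is the global maximum of `sl`. The onset of atrial
#' contraction is located at the mid-diastolic shoulder of the curve: the
#' earliest local minimum of `|dSl/dt|` among interior samples later than the
#' peak and within the last 40% of the cycle (the end-of-cycle flat point is
#' itself a derivative minimum on smooth cyclic curves, hence "earliest").
#' No ECG P-wave timing exists in the data model; a known onset time can be
#' supplied via `t_a_onset_ms` to override the morphological rule.
#'
#' @param sl Dimensionless longitudinal strain series, `sl[1] == 0`.
#' @param times_ms Frame times (ms).
#' @param smooth Smoothing window passed to [rate_curve()].
#' @param t_a_onset_ms Optional explicit contraction-onset time (ms).
#' @param late_fraction Portion of the cycle searched for the onset (default
#'   0.4, i.e. the last 40%).
#' @return List of class `la_phases` with `t_peak_ms`, `t_a_onset_ms`,
#'   `cycle_end_ms` and the corresponding frame indices `i_peak`, `i_a`.
#' @export
detect_phases <- function(sl, times_ms, smooth = 3L, t_a_onset_ms = NULL,
                          late_fraction = 0.4) {
  n <- length(sl)
  stopifnot(n == length(times_ms), n >= 5L)
  i_peak <- which.max(sl)
  if (i_peak %in% c(1L, n) || sl[i_peak] <= 0) {
    abort_lamotion(
      sprintf(
        "no interior reservoir peak: maximum %.4g at frame %d of %d (curve flat or monotonic)",
        sl[i_peak], i_peak, n
      ),
      "phase_detection_failure"
    )
  }
  t_end <- times_ms[n]
  if (!is.null(t_a_onset_ms)) {
    i_a <- which.min(abs(times_ms - t_a_onset_ms))
  } else {
    drv <- abs(rate_curve(sl, times_ms, smooth))
    cand <- which(times_ms >= (1 - late_fraction) * t_end &
                    seq_len(n) > i_peak & seq_len(n) < n)
    if (length(cand) == 0L) {
      abort_lamotion("no frames available after the reservoir peak in the late cycle",
                     "phase_detection_failure")
    }
    is_local_min <- vapply(cand, function(j) {
      drv[j] <= drv[j - 1L] && drv[j] <= drv[j + 1L]
    }, logical(1))
    i_a <- if (any(is_local_min)) cand[which(is_local_min)[1L]] else cand[which.min(drv[cand])]
  }
  if (!(i_peak < i_a && i_a < n)) {
    abort_lamotion("phase boundaries out of order (peak < A-onset < cycle end violated)",
                   "phase_detection_failure")
  }
  structure(
    list(t_peak_ms = times_ms[i_peak], t_a_onset_ms = times_ms[i_a],
         cycle_end_ms = t_end, i_peak = i_peak, i_a = i_a),
    class = "la_phases"
  )
}

#' @export
print.la_phases <- function(x, ...) {
  cat(sprintf(
    "<la_phases> reservoir [0, %.0f] ms | conduit (%.0f, %.0f] ms | contraction (%.0f, %.0f] ms\n",
    x$t_peak_ms, x$t_peak_ms, x$t_a_onset_ms, x$t_a_onset_ms, x$cycle_end_ms
  ))
  invisible(x)
}

#' Assemble the strain/motion curve table for one view
#'
#' @inheritParams radial_motion_curve
#' @param smooth Smoothing window for the derivative curves.
#' @return Tibble with `time_ms`, `sl`, `mr` (dimensionless) and `srl`, `vr`
#'   (s^-1).
#' @export
strain_curves <- function(seq, n_segments = 12L, n_points = 120L, smooth = 3L) {
  sl_tab <- longitudinal_strain_curve(seq)
  mr_tab <- radial_motion_curve(seq, n_segments, n_points)
  tibble::tibble(
    time_ms = sl_tab$time_ms,
    sl = sl_tab$sl,
    mr = mr_tab$mr,
    srl = rate_curve(sl_tab$sl, sl_tab$time_ms, smooth),
    vr = rate_curve(mr_tab$mr, mr_tab$time_ms, smooth)
  )
}

# Phase-window extraction shared by sl/mr and the decomposed cmr/pmr curves.
# amplitude series x (dimensionless): R = x at peak; A = x at A-onset minus x
# at cycle end; C = R - A (additivity exact by construction). Reported in %.
phasic_from_series <- function(x, phases) {
  n <- length(x)
  r <- x[phases$i_peak]
  a <- x[phases$i_a] - x[n]
  c(r = 100 * r, c = 100 * (r - a), a = 100 * a)
}

rate_peaks <- function(rate, phases) {
  n <- length(rate)
  res <- seq_len(phases$i_peak)
  con <- phases$i_peak:phases$i_a
  act <- phases$i_a:n
  if (length(res) == 0L || length(con) == 0L || length(act) == 0L) {
    abort_lamotion("empty phase window for rate-peak extraction", "phase_window_error")
  }
  c(s = max(rate[res]), e = min(rate[con]), a = min(rate[act]))
}

#' Phasic indices from strain/motion curves
#'
#' Extracts reservoir (R), conduit (C) and atrial-contraction (A) amplitudes
#' for longitudinal strain and radial motion fraction, the corresponding
#' rate peaks (S', E', A'), and the ratio indices. Amplitudes: R is the value
#' at the reservoir peak, A the drop from contraction onset to cycle end, and
#' C = R - A, so additivity `R = C + A` is exact. Rate peaks are the maximum
#' of the rate in the reservoir window and the minima in the conduit and
#' contraction windows (E' and A' are negative by convention); their ratio is
#' reported as a magnitude ratio `|E'|/|A'|`.
#'
#' @param curves Tibble from [strain_curves()].
#' @param phases An `la_phases` object from [detect_phases()].
#' @return One-row tibble; strain/motion amplitudes in %, rates in s^-1,
#'   ratios dimensionless.
#' @export
phasic_indices <- function(curves, phases) {
  stopifnot(inherits(phases, "la_phases"))
  n <- nrow(curves)
  if (phases$i_peak < 1L || phases$i_a > n || phases$i_peak >= phases$i_a) {
    abort_lamotion("phase boundaries outside the curve's time range", "phase_window_error")
  }
  sl <- phasic_from_series(curves$sl, phases)
  mr <- phasic_from_series(curves$mr, phases)
  srl <- rate_peaks(curves$srl, phases)
  vr <- rate_peaks(curves$vr, phases)
  tibble::tibble(
    sl_r = sl[["r"]], sl_c = sl[["c"]], sl_a = sl[["a"]],
    sl_a_over_sl_r = sl[["a"]] / sl[["r"]],
    srl_s = srl[["s"]], srl_e = srl[["e"]], srl_a = srl[["a"]],
    srl_e_over_a = abs(srl[["e"]]) / abs(srl[["a"]]),
    mr_r = mr[["r"]], mr_c = mr[["c"]], mr_a = mr[["a"]],
    mr_a_over_mr_r = mr[["a"]] / mr[["r"]],
    vr_s = vr[["s"]], vr_e = vr[["e"]], vr_a = vr[["a"]],
    vr_e_over_a = abs(vr[["e"]]) / abs(vr[["a"]])
  )
}

#' Average phasic indices across views
#'
#' Field-by-field arithmetic mean over the available long-axis views
#' (2-chamber, 4-chamber, 3-chamber). Ratio indices are recomputed from the
#' averaged numerators and denominators rather than averaged as ratios, so
#' the global table stays internally consistent (additivity and ratio
#' definitions keep holding exactly).
#'
#' @param per_view Tibble of per-view index rows (as from [phasic_indices()],
#'   optionally including the decomposed `cmr_*`/`pmr_*` columns).
#' @return One-row tibble with the same columns.
#' @export
global_average <- function(per_view) {
  if (!is.data.frame(per_view) || nrow(per_view) == 0L) {
    stop_invalid_input("per_view must be a non-empty data frame of index rows")
  }
  num_cols <- names(per_view)[vapply(per_view, is.numeric, logical(1))]
  out <- dplyr::summarise(per_view, dplyr::across(dplyr::all_of(num_cols), mean))
  if (all(c("sl_a", "sl_r") %in% num_cols)) out$sl_a_over_sl_r <- out$sl_a / out$sl_r
  if (all(c("srl_e", "srl_a") %in% num_cols)) out$srl_e_over_a <- abs(out$srl_e) / abs(out$srl_a)
  if (all(c("mr_a", "mr_r") %in% num_cols)) out$mr_a_over_mr_r <- out$mr_a / out$mr_r
  if (all(c("vr_e", "vr_a") %in% num_cols)) out$vr_e_over_a <- abs(out$vr_e) / abs(out$vr_a)
  out
}
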