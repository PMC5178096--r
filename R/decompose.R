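#' Mitral-valve reference geometry
#'
#' The radial motion decomposition needs a fixed external reference: the
#' center of the mitral valve (midpoint of the two annulus landmarks) and the
#' unit axis pointing from the reference-frame LA center of mass towards it.
#' The geometry is frozen at the reference frame deliberately — the purpose
#' of the decomposition is to separate ventricular translation from intrinsic
#' atrial deformation, and re-estimating the axis per frame would absorb the
#' very translation it is meant to expose.
#'
#' @param seq An [la_sequence()] carrying `mv_points`.
#' @param n_points Resampling grid used for the LA center of mass.
#' @return List of class `mv_geometry` with `mv_center` (mm), `mv_axis`
#'   (unit vector LA center -> MV center), `la_center` (mm).
#' @export
mv_geometry <- function(seq, n_points = 120L) {
  stopifnot(inherits(seq, "la_sequence"))
  if (is.null(seq$mv_points)) {
    abort_lamotion("sequence carries no mitral-annulus landmarks", "missing_landmark")
  }
  lm <- seq$mv_points[[1L]]
  mv_center <- colMeans(lm)
  ref <- resample_contour(contour_tibble(seq$frames[[1L]]), n_points)
  la_center <- arc_centroid(as.matrix(ref))
  axis <- mv_center - la_center
  nrm <- sqrt(sum(axis^2))
  if (nrm < sqrt(.Machine$double.eps)) {
    abort_lamotion(
      "LA center of mass coincides with the MV center: decomposition axis undefined",
      "degenerate_axis"
    )
  }
  structure(
    list(mv_center = unname(mv_center), mv_axis = unname(axis / nrm),
         la_center = unname(la_center)),
    class = "mv_geometry"
  )
}

#' @export
print.mv_geometry <- function(x, ...) {
  cat(sprintf(
    "<mv_geometry> MV center (%.1f, %.1f) mm, axis (%.3f, %.3f) from LA center (%.1f, %.1f)\n",
    x$mv_center[1], x$mv_center[2], x$mv_axis[1], x$mv_axis[2],
    x$la_center[1], x$la_center[2]
  ))
  invisible(x)
}

#' Decompose radial motion into MV-centric and MV-perpendicular components
#'
#' Per segment and frame, the displacement vector of the segment's wall
#' position from its reference position is projected onto the MV axis (the
#' centric component, cMr — motion towards/away from the mitral-valve
#' center) and onto the orthogonal direction (the perpendicular component,
#' pMr — which broadly carries the ventricular translational movement).
#' Each projection is normalised by the segment's reference radius `M0`, so
#' cMr/pMr are commensurate with the radial motion fraction. Vector
#' recombination holds exactly per segment: squared centric plus squared
#' perpendicular displacement equals the squared total displacement.
#'
#' The segment-averaged curves take the magnitude of each segment's
#' projection (signed projections of a symmetric expansion would cancel to
#' ~0 across segments); the signed per-segment projections are available
#' with `per_segment = TRUE`. Note cMr + pMr != Mr in general: they are
#' orthogonal components of the displacement while Mr is its radial
#' component.
#'
#' @inheritParams radial_motion_curve
#' @param geom An [mv_geometry()]; computed from `seq` if `NULL`.
#' @param per_segment If `TRUE`, return the signed per-segment projections
#'   (`c_disp_mm`, `p_disp_mm`, `total_disp_mm`, `m0_mm`) per frame.
#' @return Tibble with `time_ms`, `cmr`, `pmr` (dimensionless), or the
#'   per-segment displacement table when `per_segment = TRUE`.
#' @export
decompose_radial <- function(seq, geom = NULL, n_segments = 12L, n_points = 120L,
                             per_segment = FALSE) {
  stopifnot(inherits(seq, "la_sequence"))
  if (is.null(geom)) geom <- mv_geometry(seq, n_points)
  stopifnot(inherits(geom, "mv_geometry"))
  if (n_points %% n_segments != 0L) {
    abort_lamotion("n_points must be a multiple of n_segments", "configuration_error")
  }
  axis <- geom$mv_axis
  perp <- c(-axis[2L], axis[1L])
  bin <- rep(seq_len(n_segments), each = n_points %/% n_segments)

  seg_positions <- function(pts) {
    rs <- as.matrix(resample_contour(contour_tibble(pts), n_points))
    cbind(tapply(rs[, 1L], bin, mean), tapply(rs[, 2L], bin, mean))
  }
  ref_rs <- as.matrix(resample_contour(contour_tibble(seq$frames[[1L]]), n_points))
  ref_pos <- seg_positions(seq$frames[[1L]])
  center <- arc_centroid(ref_rs)
  # same M0 as the radial motion fraction: mean per-point distance per segment
  m0 <- segment_radii(contour_tibble(ref_rs), center, n_segments, n_points,
                      resample = FALSE)$radius_mm
  if (any(m0 <= sqrt(.Machine$double.eps))) {
    stop_invalid_geometry("zero reference radius in decomposition")
  }

  per <- purrr::map2_dfr(seq$frames, seq$times_ms, function(pts, t) {
    d <- seg_positions(pts) - ref_pos
    cd <- d[, 1L] * axis[1L] + d[, 2L] * axis[2L]
    pd <- d[, 1L] * perp[1L] + d[, 2L] * perp[2L]
    tibble::tibble(
      time_ms = t, segment = seq_len(n_segments),
      c_disp_mm = cd, p_disp_mm = pd,
      total_disp_mm = sqrt(d[, 1L]^2 + d[, 2L]^2),
      m0_mm = m0
    )
  })
  if (per_segment) return(per)
  per |>
    dplyr::summarise(
      cmr = mean(abs(.data$c_disp_mm) / .data$m0_mm),
      pmr = mean(abs(.data$p_disp_mm) / .data$m0_mm),
      .by = "time_ms"
    )
}

#' Phasic indices of the decomposed radial motion
#'
#' Applies the same phase-window extraction as [phasic_indices()] to the
#' cMr and pMr curves.
#'
#' @param decomposed Tibble from [decompose_radial()] (`time_ms`, `cmr`,
#'   `pmr`).
#' @param phases An `la_phases` object (detected on the longitudinal strain
#'   curve of the same view).
#' @return One-row tibble with `cmr_r`, `cmr_c`, `cmr_a`, `pmr_r`, `pmr_c`,
#'   `pmr_a` in %.
#' @export
decomposed_phasic <- function(decomposed, phases) {
  stopifnot(inherits(phases, "la_phases"))
  n <- nrow(decomposed)
  if (phases$i_a > n || phases$i_peak >= phases$i_a) {
    abort_lamotion("phase boundaries outside the curve's time range", "phase_window_error")
  }
  cm <- phasic_from_series(decomposed$cmr, phases)
  pm <- phasic_from_series(decomposed$pmr, phases)
  tibble::tibble(
    cmr_r = cm[["r"]], cmr_c = cm[["c"]], cmr_a = cm[["a"]],
    pmr_r = pm[["r"]], pmr_c = pm[["c"]], pmr_a = pm[["a"]]
  )
}
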