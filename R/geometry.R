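#' Geometric primitives for endocardial contours
#'
#' A contour is an ordered, open polyline tracing the left-atrial endocardium
#' from one mitral-annulus insertion point to the other, supplied as a data
#' frame with columns `x_mm` and `y_mm` (image-plane millimetres, y increasing
#' downward as in image rasters). All strain and motion-fraction quantities
#' are built from the primitives in this file.
#'
#' @name geometry
NULL

# Coerce + validate a contour data frame; returns a 2-column numeric matrix.
as_contour_matrix <- function(contour, min_points = 8L) {
  if (is.matrix(contour) && ncol(contour) == 2L) {
    pts <- contour
  } else if (is.data.frame(contour)) {
    cols <- if (all(c("x_mm", "y_mm") %in% names(contour))) c("x_mm", "y_mm") else c("x", "y")
    if (!all(cols %in% names(contour))) {
      stop_invalid_input("contour data frame needs columns x_mm/y_mm (or x/y)")
    }
    pts <- cbind(contour[[cols[1]]], contour[[cols[2]]])
  } else {
    stop_invalid_input("contour must be a data frame or a 2-column matrix")
  }
  if (!is.numeric(pts) || anyNA(pts) || any(!is.finite(pts))) {
    stop_invalid_geometry("contour coordinates must be finite numbers")
  }
  if (nrow(pts) < min_points) {
    stop_invalid_geometry(sprintf(
      "contour has %d points; at least %d required", nrow(pts), min_points
    ))
  }
  d <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  if (any(d == 0)) {
    stop_invalid_geometry(sprintf(
      "consecutive coincident points at row(s) %s",
      paste(which(d == 0) + 1L, collapse = ", ")
    ))
  }
  unname(pts)
}

contour_tibble <- function(pts) {
  tibble::tibble(x_mm = pts[, 1L], y_mm = pts[, 2L])
}

#' Total arc length of a contour
#'
#' Sum of Euclidean segment lengths of the polyline; the initial contour
#' length is the denominator of the longitudinal strain.
#'
#' @param contour Data frame with columns `x_mm`, `y_mm` (ordered points).
#' @return Length in mm (scalar).
#' @examples
#' contour_length(data.frame(
#'   x_mm = c(0, 1, 2, 3, 3, 3, 3, 3),
#'   y_mm = c(0, 0, 0, 0, 1, 2, 3, 4)
#' )) # 7
#' @export
contour_length <- function(contour) {
  pts <- as_contour_matrix(contour, min_points = 2L)
  sum(sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

#' Resample a contour to uniform arc-length spacing
#'
#' Places `n_points` points on the piecewise-linear input curve at uniform
#' arc-length spacing, preserving both endpoints. Establishes point
#' correspondence across cine frames before per-segment radii are taken.
#'
#' @param contour Data frame with `x_mm`, `y_mm`.
#' @param n_points Number of output points (>= 8).
#' @return Tibble with `x_mm`, `y_mm` of `n_points` rows.
#' @export
resample_contour <- function(contour, n_points = 120L) {
  if (n_points < 8L) stop_invalid_input("n_points must be >= 8")
  pts <- as_contour_matrix(contour, min_points = 2L)
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop_invalid_geometry("degenerate contour: total length is zero")
  target <- seq(0, total, length.out = n_points)
  # linear interpolation of x and y against arc length
  x <- stats::approx(s, pts[, 1L], xout = target, ties = "ordered")$y
  y <- stats::approx(s, pts[, 2L], xout = target, ties = "ordered")$y
  # exact endpoint preservation against rounding
  x[c(1L, n_points)] <- pts[c(1L, nrow(pts)), 1L]
  y[c(1L, n_points)] <- pts[c(1L, nrow(pts)), 2L]
  tibble::tibble(x_mm = x, y_mm = y)
}

# Arc-length-weighted centroid of a polyline given as a matrix. Each segment
# contributes its midpoint weighted by its length. With close_chord = TRUE the
# chord joining the endpoints participates, closing the annulus gap.
arc_centroid <- function(pts, close_chord = TRUE) {
  if (close_chord && !all(pts[1L, ] == pts[nrow(pts), ])) {
    pts <- rbind(pts, pts[1L, ])
  }
  a <- pts[-nrow(pts), , drop = FALSE]
  b <- pts[-1L, , drop = FALSE]
  w <- sqrt(rowSums((b - a)^2))
  if (sum(w) <= 0) stop_invalid_geometry("degenerate contour: total length is zero")
  mid <- (a + b) / 2
  colSums(mid * w) / sum(w)
}

#' Arc-length-weighted center of mass of a contour
#'
#' Centroid of the polyline with segment midpoints weighted by segment
#' length, so point density does not bias the center (a raw vertex mean
#' would be resampling-dependent). The left atrium is traced as an open
#' curve between the two mitral-annulus insertions; for centroid purposes
#' the gap is closed with the chord between the endpoints, since the valve
#' plane bounds the chamber even though it is not atrial wall.
#'
#' @inheritParams contour_length
#' @param close_chord Include the endpoint-to-endpoint chord (default TRUE).
#' @return Named numeric vector `c(x_mm, y_mm)`.
#' @export
center_of_mass <- function(contour, close_chord = TRUE) {
  pts <- as_contour_matrix(contour, min_points = 2L)
  cm <- arc_centroid(pts, close_chord = close_chord)
  c(x_mm = cm[1L], y_mm = cm[2L])
}

#' Per-segment radii of a contour about a center
#'
#' The contour is resampled to `n_points` and the points grouped into
#' `n_segments` contiguous arc-length bins; the radius of a segment is the
#' mean distance of its points to `center`. These are the `M0`/`Mt` radii of
#' the radial motion fraction.
#'
#' @inheritParams contour_length
#' @param center Numeric length-2, the reference center (mm).
#' @param n_segments Number of contiguous segments (default 12).
#' @param n_points Resampling grid; must be a multiple of `n_segments`.
#' @param resample If `FALSE`, `contour` is used as-is (its point count must
#'   then be a multiple of `n_segments`).
#' @return Tibble with columns `segment`, `radius_mm`.
#' @export
segment_radii <- function(contour, center, n_segments = 12L, n_points = 120L,
                          resample = TRUE) {
  stopifnot(length(center) == 2L, is.finite(center))
  if (resample) {
    pts <- as.matrix(resample_contour(contour, n_points))
  } else {
    pts <- as_contour_matrix(contour, min_points = 3L)
    n_points <- nrow(pts)
  }
  if (n_points %% n_segments != 0L) {
    stop_invalid_input("point count must be a multiple of n_segments")
  }
  r <- sqrt((pts[, 1L] - center[1L])^2 + (pts[, 2L] - center[2L])^2)
  bin <- rep(seq_len(n_segments), each = n_points %/% n_segments)
  radius <- as.numeric(tapply(r, bin, mean))
  if (any(radius <= .Machine$double.eps * 1e3)) {
    stop_invalid_geometry("segment radius is zero: center lies on the contour")
  }
  tibble::tibble(segment = seq_len(n_segments), radius_mm = radius)
}

# Shoelace area of a closed polygon (matrix of vertices, first != last ok).
polygon_area <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# TRUE if any two non-adjacent edges of the closed polygon cross.
polygon_self_intersects <- function(pts) {
  n <- nrow(pts)
  a <- pts
  b <- pts[c(2:n, 1L), , drop = FALSE]
  cross <- function(o, p, q) (p[1] - o[1]) * (q[2] - o[2]) - (p[2] - o[2]) * (q[1] - o[1])
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      d1 <- cross(a[i, ], b[i, ], a[j, ]); d2 <- cross(a[i, ], b[i, ], b[j, ])
      d3 <- cross(a[j, ], b[j, ], a[i, ]); d4 <- cross(a[j, ], b[j, ], b[i, ])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}
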