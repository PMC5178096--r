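#' Cine contour sequences
#'
#' An `la_sequence` holds one tracked endocardial contour per cine phase for
#' a single long-axis view, the frame times, and the per-frame mitral-annulus
#' landmark pair. Frame 1 (time 0) is the reference phase: the acquisition's
#' trigger frame at ventricular end-diastole, where the atrium is near its
#' minimal volume, so that reservoir expansion yields positive strain.
#'
#' @param frames List of contours (data frames with `x_mm`, `y_mm`), one per
#'   cine phase, or a single tidy data frame with columns `frame_index`,
#'   `point_index`, `x_mm`, `y_mm`.
#' @param times_ms Strictly increasing frame times in ms; first must be 0.
#' @param view View label: `"2-chamber"`, `"4-chamber"` or `"3-chamber"`.
#' @param mv_points Mitral-annulus landmark pair per frame: either a list of
#'   2x2 matrices (rows = the two landmarks, cols = x/y in mm) of the same
#'   length as `frames`, or a single 2x2 matrix taken as the reference-frame
#'   landmarks. May be `NULL` if no decomposition is needed.
#' @param min_frames Minimum accepted number of cine phases (default 10).
#' @return An object of class `la_sequence`.
#' @export
la_sequence <- function(frames, times_ms, view = c("2-chamber", "4-chamber", "3-chamber"),
                        mv_points = NULL, min_frames = 10L) {
  view <- match.arg(view)
  if (is.data.frame(frames)) {
    need <- c("frame_index", "point_index", "x_mm", "y_mm")
    if (!all(need %in% names(frames))) {
      stop_invalid_input("tidy contour table needs columns frame_index, point_index, x_mm, y_mm")
    }
    frames <- frames[order(frames$frame_index, frames$point_index), ]
    frames <- split(frames[c("x_mm", "y_mm")], frames$frame_index)
  }
  if (length(frames) < min_frames) {
    abort_lamotion(
      sprintf("%d cine frames supplied; at least %d required", length(frames), min_frames),
      "insufficient_temporal_resolution"
    )
  }
  mats <- unname(lapply(frames, as_contour_matrix))
  if (length(times_ms) != length(mats)) {
    stop_invalid_input("times_ms length must equal the number of frames")
  }
  if (times_ms[1L] != 0 || any(diff(times_ms) <= 0)) {
    stop_invalid_input("times_ms must start at 0 and be strictly increasing")
  }
  if (!is.null(mv_points)) {
    if (is.matrix(mv_points)) mv_points <- rep(list(mv_points), length(mats))
    if (length(mv_points) != length(mats)) {
      stop_invalid_input("mv_points must have one landmark pair per frame")
    }
    ok <- vapply(mv_points, function(m) {
      is.matrix(m) && all(dim(m) == c(2L, 2L)) && all(is.finite(m))
    }, logical(1))
    if (!all(ok)) stop_invalid_input("each mv_points entry must be a finite 2x2 matrix")
  }
  structure(
    list(frames = mats, times_ms = as.numeric(times_ms), view = view,
         mv_points = mv_points),
    class = "la_sequence"
  )
}

#' @export
print.la_sequence <- function(x, ...) {
  cat(sprintf(
    "<la_sequence> %s view: %d frames over %.0f ms, %d-%d points/frame, MV landmarks: %s\n",
    x$view, length(x$frames), max(x$times_ms),
    min(vapply(x$frames, nrow, 1L)), max(vapply(x$frames, nrow, 1L)),
    if (is.null(x$mv_points)) "absent" else "present"
  ))
  invisible(x)
}

#' Tidy a contour sequence into a long point table
#'
#' @param x An `la_sequence`.
#' @param ... Unused.
#' @return Tibble with `frame_index`, `time_ms`, `point_index`, `x_mm`,
#'   `y_mm`, `view`.
#' @method tidy la_sequence
#' @export
tidy.la_sequence <- function(x, ...) {
  purrr::map2_dfr(x$frames, seq_along(x$frames), function(pts, i) {
    tibble::tibble(
      frame_index = i, time_ms = x$times_ms[i],
      point_index = seq_len(nrow(pts)), x_mm = pts[, 1L], y_mm = pts[, 2L]
    )
  }) |>
    dplyr::mutate(view = x$view)
}

n_frames <- function(seq) length(seq$frames)

cycle_end_ms <- function(seq) seq$times_ms[length(seq$times_ms)]
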