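#' Contour sequence files
#'
#' A sequence is stored as a CSV of points (`frame_index`, `point_index`,
#' `x_mm`, `y_mm`) plus a JSON sidecar of the same stem (`.json`) carrying
#' `view`, `times_ms` and per-frame `mv_points` (list of 2x2 arrays). The
#' reader validates all sequence invariants and reports offending CSV line
#' numbers.
#'
#' @param seq An [la_sequence()].
#' @param stem Output path without extension; `<stem>.csv` and `<stem>.json`
#'   are written.
#' @return `write_contours()`: the stem, invisibly.
#' @export
write_contours <- function(seq, stem) {
  stopifnot(inherits(seq, "la_sequence"))
  pts <- tidy.la_sequence(seq)[c("frame_index", "point_index", "x_mm", "y_mm")]
  readr::write_csv(pts, paste0(stem, ".csv"))
  sidecar <- list(view = seq$view, times_ms = seq$times_ms)
  if (!is.null(seq$mv_points)) sidecar$mv_points <- seq$mv_points
  jsonlite::write_json(sidecar, paste0(stem, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(stem)
}

#' @rdname write_contours
#' @param csv_path Path to the points CSV; the sidecar is looked up at the
#'   same stem with extension `.json` unless `json_path` is given.
#' @param json_path Optional explicit sidecar path.
#' @return `read_contours()`: an [la_sequence()].
#' @export
read_contours <- function(csv_path, json_path = NULL) {
  if (is.null(json_path)) json_path <- paste0(sub("\\.csv$", "", csv_path), ".json")
  if (!file.exists(csv_path)) stop_invalid_input(paste("no such contour file:", csv_path))
  if (!file.exists(json_path)) stop_invalid_input(paste("missing JSON sidecar:", json_path))
  pts <- readr::read_csv(csv_path, show_col_types = FALSE)
  need <- c("frame_index", "point_index", "x_mm", "y_mm")
  if (!all(need %in% names(pts))) {
    stop_invalid_input(sprintf("%s: columns must be %s", csv_path, paste(need, collapse = ", ")))
  }
  bad <- which(!is.finite(pts$x_mm) | !is.finite(pts$y_mm))
  if (length(bad)) {
    stop_invalid_geometry(sprintf(
      "%s: non-finite coordinates at line(s) %s",
      csv_path, paste(utils::head(bad + 1L, 5L), collapse = ", ") # +1 for header
    ))
  }
  sc <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  mv <- NULL
  if (!is.null(sc$mv_points)) {
    mv <- if (is.array(sc$mv_points) && length(dim(sc$mv_points)) == 3L) {
      lapply(seq_len(dim(sc$mv_points)[1L]), function(i) sc$mv_points[i, , ])
    } else {
      lapply(sc$mv_points, function(m) matrix(unlist(m), nrow = 2L, byrow = is.list(m)))
    }
  }
  la_sequence(as.data.frame(pts), times_ms = as.numeric(sc$times_ms),
              view = sc$view, mv_points = mv)
}

#' Read/write a Dixon study as NIfTI volumes
#'
#' Volumes are exchanged as NIfTI files (`RNifti`); the mask and ROI are
#' byte volumes.
#'
#' @param study A [dixon_study()].
#' @param dir Directory for `fat.nii.gz`, `water.nii.gz`, `mask.nii.gz` and
#'   optionally `roi.nii.gz`.
#' @return `write_dixon()`: `dir`, invisibly; `read_dixon()`: a
#'   [dixon_study()].
#' @export
write_dixon <- function(study, dir) {
  stopifnot(inherits(study, "dixon_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pd <- study$voxel_size_mm
  wr <- function(img, name, datatype = "float") {
    attr(img, "pixdim") <- pd
    RNifti::writeNifti(RNifti::asNifti(img, datatype = datatype),
                       file.path(dir, name))
  }
  wr(study$fat, "fat.nii.gz")
  wr(study$water, "water.nii.gz")
  wr(study$cardiac_mask + 0L, "mask.nii.gz", "uint8")
  if (!is.null(study$septal_roi)) wr(study$septal_roi + 0L, "roi.nii.gz", "uint8")
  invisible(dir)
}

#' @rdname write_dixon
#' @export
read_dixon <- function(dir) {
  rd <- function(name, required = TRUE) {
    p <- file.path(dir, name)
    if (!file.exists(p)) {
      if (required) stop_invalid_input(paste("missing volume:", p)) else return(NULL)
    }
    RNifti::readNifti(p)
  }
  fat <- rd("fat.nii.gz")
  vox <- RNifti::pixdim(fat)[1:3]
  roi <- rd("roi.nii.gz", required = FALSE)
  dixon_study(
    fat = as.array(fat), water = as.array(rd("water.nii.gz")),
    voxel_size_mm = vox, cardiac_mask = as.array(rd("mask.nii.gz")) > 0,
    septal_roi = if (is.null(roi)) NULL else as.array(roi) > 0
  )
}

#' Read/write a tidy cohort table
#'
#' @param data Tidy tibble (`subject_id`, `group`, `variable`, `value`).
#' @param path CSV path.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_invalid_input(paste("no such cohort file:", path))
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("subject_id", "group", "variable", "value")
  if (!all(need %in% names(d))) {
    stop_invalid_input(sprintf("%s: columns must include %s", path, paste(need, collapse = ", ")))
  }
  d
}
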