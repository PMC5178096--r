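#' Assemble a 2-point Dixon study
#'
#' Bundles the fat and water image volumes, the voxel spacing, a whole-heart
#' cardiac mask (including the epicardial envelope) and an optional septal
#' region of interest for intra-myocardial fat measurement.
#'
#' @param fat,water 3D numeric arrays of the same dimensions, intensities
#'   >= 0.
#' @param voxel_size_mm Numeric length 3, voxel edge lengths (mm).
#' @param cardiac_mask Logical/0-1 array, same dimensions.
#' @param septal_roi Optional logical array, same dimensions, marking the
#'   hand-drawn septal ROI on its designated slice (use
#'   `roi_from_slice()` to lift a 2D mask onto one slice).
#' @return Object of class `dixon_study`.
#' @export
dixon_study <- function(fat, water, voxel_size_mm, cardiac_mask, septal_roi = NULL) {
  dims <- dim(fat)
  if (length(dims) != 3L) stop_invalid_input("fat must be a 3D array")
  if (!identical(dim(water), dims) || !identical(dim(cardiac_mask), dims) ||
      (!is.null(septal_roi) && !identical(dim(septal_roi), dims))) {
    stop_invalid_input("fat, water, mask and ROI must share dimensions")
  }
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    stop_invalid_input("voxel_size_mm must be 3 positive lengths")
  }
  if (min(fat) < 0 || min(water) < 0) stop_invalid_input("intensities must be >= 0")
  structure(
    list(fat = fat, water = water, voxel_size_mm = as.numeric(voxel_size_mm),
         cardiac_mask = cardiac_mask > 0,
         septal_roi = if (is.null(septal_roi)) NULL else septal_roi > 0),
    class = "dixon_study"
  )
}

#' Lift a 2D ROI mask onto one slice of a volume
#'
#' @param roi_2d Logical matrix (in-plane dimensions of the volume).
#' @param dims Volume dimensions (length 3).
#' @param slice Slice index along the third axis.
#' @return 3D logical array.
#' @export
roi_from_slice <- function(roi_2d, dims, slice) {
  if (!all(dim(roi_2d) == dims[1:2]) || slice < 1L || slice > dims[3L]) {
    stop_invalid_input("ROI dimensions or slice index do not match the volume")
  }
  out <- array(FALSE, dims)
  out[, , slice] <- roi_2d > 0
  out
}

#' Intra-myocardial fat fraction over the septal ROI
#'
#' Standard 2-point Dixon fat fraction: the mean over ROI voxels of
#' `F / (F + W)`, in percent. Voxels with no signal (`F + W == 0`) are
#' excluded from the mean and counted in the QC attributes.
#'
#' @param study A [dixon_study()] with a non-empty `septal_roi`.
#' @return Fat fraction in % (scalar), with attribute `qc` (tibble with
#'   `n_roi`, `n_excluded`).
#' @export
intramyocardial_fat_fraction <- function(study) {
  stopifnot(inherits(study, "dixon_study"))
  if (is.null(study$septal_roi) || !any(study$septal_roi)) {
    abort_lamotion("septal ROI is empty or missing", "invalid_roi")
  }
  f <- study$fat[study$septal_roi]
  w <- study$water[study$septal_roi]
  tot <- f + w
  ok <- tot > 0
  if (!any(ok)) {
    abort_lamotion("all ROI voxels have zero fat+water signal", "no_signal")
  }
  ff <- 100 * mean(f[ok] / tot[ok])
  attr(ff, "qc") <- tibble::tibble(n_roi = length(f), n_excluded = sum(!ok))
  ff
}

#' Epicardial fat volume by K-means clustering of Dixon fat intensities
#'
#' K-means (default k = 2: adipose vs non-adipose; the decision surface is a
#' single intensity threshold) on the fat-image intensities of the voxels
#' inside the cardiac mask. The cluster with the highest mean fat intensity
#' is the adipose cluster; its voxel count times the voxel volume is the
#' absolute epicardial fat volume, and the fat volume divided by the
#' whole-heart mask volume gives the 3D Dixon adipose fraction. The
#' clustering operates on intensity values only, so the partition is
#' invariant to voxel order and to positive rescaling of the intensities,
#' and is deterministic for a given seed.
#'
#' @param study A [dixon_study()].
#' @param k Number of clusters (default 2).
#' @param seed Integer seed for the clustering initialisation.
#' @param feature `"fat"` (default; mirrors clustering on the fat image) or
#'   `"fraction"` to cluster on the voxelwise fat fraction instead.
#' @return One-row tibble: `efv_ml`, `ef_fraction_pct`, `mask_ml`,
#'   `adipose_mean_intensity`.
#' @export
epicardial_fat_kmeans <- function(study, k = 2L, seed = 1L,
                                  feature = c("fat", "fraction")) {
  stopifnot(inherits(study, "dixon_study"))
  feature <- match.arg(feature)
  if (k < 2L) stop_invalid_input("k must be >= 2")
  sel <- study$cardiac_mask
  if (!any(sel)) stop_invalid_input("cardiac mask is empty")
  vals <- switch(feature,
    fat = study$fat[sel],
    fraction = {
      tot <- study$fat[sel] + study$water[sel]
      ifelse(tot > 0, study$fat[sel] / tot, 0)
    }
  )
  if (length(unique(vals)) <= k) {
    abort_lamotion(
      sprintf("only %d distinct intensity values inside the mask; k = %d clustering degenerate",
              length(unique(vals)), k),
      "clustering_degenerate"
    )
  }
  km <- withr::with_seed(seed,
    stats::kmeans(vals, centers = k, iter.max = 300L, nstart = 10L)
  )
  adipose <- which.max(km$centers[, 1L])
  vox_ml <- prod(study$voxel_size_mm) / 1000
  n_fat <- sum(km$cluster == adipose)
  tibble::tibble(
    efv_ml = n_fat * vox_ml,
    ef_fraction_pct = 100 * n_fat / sum(sel),
    mask_ml = sum(sel) * vox_ml,
    adipose_mean_intensity = unname(km$centers[adipose, 1L])
  )
}

#' Assemble all fat measures for one subject
#'
#' @param study A [dixon_study()].
#' @param bsa_m2 Body surface area (m^2) for indexing.
#' @inheritParams epicardial_fat_kmeans
#' @return One-row tibble: `intramyo_ff_pct`, `efv_ml`, `efv_indexed_ml_m2`,
#'   `ef_fraction_pct`.
#' @export
fat_measures <- function(study, bsa_m2, k = 2L, seed = 1L) {
  if (bsa_m2 <= 0) stop_invalid_input("BSA must be positive")
  efv <- epicardial_fat_kmeans(study, k, seed)
  ff <- if (is.null(study$septal_roi)) NA_real_ else as.numeric(intramyocardial_fat_fraction(study))
  tibble::tibble(
    intramyo_ff_pct = ff,
    efv_ml = efv$efv_ml,
    efv_indexed_ml_m2 = index_to_bsa(efv$efv_ml, bsa_m2),
    ef_fraction_pct = efv$ef_fraction_pct
  )
}
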