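#' Ventricular volumes and mass from a short-axis contour stack
#'
#' Summation-of-discs: each slice contributes its contour area (shoelace
#' formula on the closed polygon) times the slice increment (thickness +
#' gap). Myocardial mass is the end-diastolic epicardial minus endocardial
#' volume times the myocardial density (1.05 g/mL by convention).
#'
#' @param stack List with elements `slices` (a list, each slice a list with
#'   closed contours `endo_ed`, `endo_es`, `epi_ed` as data frames with
#'   `x_mm`/`y_mm`), `slice_thickness_mm`, `slice_gap_mm` (default 0).
#' @param myocardial_density Density in g/mL (default 1.05).
#' @param validate Check contours for self-intersection (default TRUE).
#' @return One-row tibble: `edv_ml`, `esv_ml`, `sv_ml`, `ef`, `mass_g`.
#' @export
lv_volumes <- function(stack, myocardial_density = 1.05, validate = TRUE) {
  if (length(stack$slices) < 5L) stop_invalid_input("at least 5 slices required")
  thk <- stack$slice_thickness_mm
  gap <- if (is.null(stack$slice_gap_mm)) 0 else stack$slice_gap_mm
  if (is.null(thk) || thk <= 0) stop_invalid_input("slice thickness must be positive")
  dz <- thk + gap
  area <- function(contour) {
    pts <- as_contour_matrix(contour, min_points = 3L)
    if (validate && polygon_self_intersects(pts)) {
      stop_invalid_geometry("self-intersecting slice contour")
    }
    polygon_area(pts)
  }
  vols <- purrr::map_dfr(stack$slices, function(sl) {
    tibble::tibble(
      endo_ed = area(sl$endo_ed) * dz,
      endo_es = area(sl$endo_es) * dz,
      epi_ed = area(sl$epi_ed) * dz
    )
  })
  edv <- sum(vols$endo_ed) / 1000
  esv <- sum(vols$endo_es) / 1000
  epi <- sum(vols$epi_ed) / 1000
  tibble::tibble(
    edv_ml = edv, esv_ml = esv, sv_ml = edv - esv, ef = (edv - esv) / edv,
    mass_g = (epi - edv) * myocardial_density
  )
}

#' Biplane area-length left atrial volume
#'
#' `V = 0.85 * A_2ch * A_4ch / min(L_2ch, L_4ch)`, the standard area-length
#' estimate for chambers covered only by long-axis views. If one view is
#' missing, the single-plane fallback `V = 0.85 * A^2 / L` is used.
#'
#' @param area_2ch,area_4ch Chamber areas (mm^2); one may be `NA`.
#' @param length_2ch,length_4ch Long-axis chamber lengths (mm).
#' @return Volume in mL.
#' @export
la_volume_biplane <- function(area_2ch, area_4ch, length_2ch, length_4ch) {
  vals <- c(area_2ch, area_4ch, length_2ch, length_4ch)
  if (all(is.na(c(area_2ch, area_4ch)))) stop_invalid_input("no view areas supplied")
  if (any(!is.na(vals) & vals <= 0)) stop_invalid_input("areas and lengths must be positive")
  if (is.na(area_2ch)) return(0.85 * area_4ch^2 / length_4ch / 1000)
  if (is.na(area_4ch)) return(0.85 * area_2ch^2 / length_2ch / 1000)
  0.85 * area_2ch * area_4ch / min(length_2ch, length_4ch) / 1000
}

#' Body surface area and body mass index
#'
#' BSA by the Mosteller formula `sqrt(height_cm * weight_kg / 3600)` by
#' default, or Du Bois (`0.007184 * h^0.725 * w^0.425`).
#'
#' @param height_cm,weight_kg Positive scalars or vectors.
#' @param method `"mosteller"` (default) or `"dubois"`.
#' @return Tibble with `bsa_m2`, `bmi_kg_m2`.
#' @export
body_metrics <- function(height_cm, weight_kg, method = c("mosteller", "dubois")) {
  method <- match.arg(method)
  if (any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop_invalid_input("height and weight must be positive")
  }
  bsa <- switch(method,
    mosteller = sqrt(height_cm * weight_kg / 3600),
    dubois = 0.007184 * height_cm^0.725 * weight_kg^0.425
  )
  tibble::tibble(bsa_m2 = bsa, bmi_kg_m2 = weight_kg / (height_cm / 100)^2)
}

#' Index a volume or mass to body surface area
#'
#' @param value Volume (mL) or mass (g).
#' @param bsa_m2 Body surface area (m^2), positive.
#' @return `value / bsa_m2`.
#' @export
index_to_bsa <- function(value, bsa_m2) {
  if (any(bsa_m2 <= 0)) stop_invalid_input("BSA must be positive")
  value / bsa_m2
}
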