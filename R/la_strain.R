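#' Fit the full LA function analysis for one subject
#'
#' Runs the strain engine on 1-3 long-axis views (2-chamber, 4-chamber,
#' 3-chamber), detects the atrial phases on each view's longitudinal strain
#' curve, extracts all phasic indices including the mitral-valve-referenced
#' decomposition where annulus landmarks are available, and averages the
#' per-view indices into a global row.
#'
#' @param views A single [la_sequence()] or a list of up to three.
#' @param n_segments,n_points,smooth See [strain_curves()].
#' @param t_a_onset_ms Optional explicit atrial-contraction onset (ms),
#'   overriding morphological detection; recycled across views.
#' @param decompose Compute cMr/pMr where landmarks exist (default TRUE).
#' @return Object of class `la_strain` with elements `curves` (long tibble:
#'   `view`, `time_ms`, `quantity`, `value`), `phases` (per-view tibble),
#'   `indices` (per-view phasic rows), `global` (one-row tibble) and
#'   `params`. Use [tidy()] for the curves and [glance()] for the global
#'   index row.
#' @examples
#' ph <- la_phantom(sl_r = 33.2, sl_a = 16.7, seed = 1)
#' fit <- la_strain(ph$views)
#' glance(fit)[, c("sl_r", "sl_c", "sl_a")]
#' @export
la_strain <- function(views, n_segments = 12L, n_points = 120L, smooth = 3L,
                      t_a_onset_ms = NULL, decompose = TRUE) {
  if (inherits(views, "la_sequence")) views <- list(views)
  if (length(views) < 1L || length(views) > 3L) {
    stop_invalid_input("between 1 and 3 views required")
  }
  stopifnot(all(vapply(views, inherits, logical(1), "la_sequence")))
  vn <- vapply(views, function(v) v$view, character(1))
  if (anyDuplicated(vn)) stop_invalid_input("duplicated view labels")
  names(views) <- vn

  per <- purrr::map(views, function(seq) {
    curves <- strain_curves(seq, n_segments, n_points, smooth)
    phases <- detect_phases(curves$sl, curves$time_ms, smooth, t_a_onset_ms)
    idx <- phasic_indices(curves, phases)
    if (decompose && !is.null(seq$mv_points)) {
      dec <- decompose_radial(seq, NULL, n_segments, n_points)
      curves <- dplyr::left_join(curves, dec, by = "time_ms")
      idx <- dplyr::bind_cols(idx, decomposed_phasic(dec, phases))
    }
    list(curves = curves, phases = phases, indices = idx)
  })

  curves_long <- purrr::imap_dfr(per, function(p, v) {
    tidyr::pivot_longer(p$curves, -"time_ms",
                        names_to = "quantity", values_to = "value") |>
      dplyr::mutate(view = v, .before = 1L)
  })
  phases_tab <- purrr::imap_dfr(per, function(p, v) {
    tibble::tibble(view = v, t_peak_ms = p$phases$t_peak_ms,
                   t_a_onset_ms = p$phases$t_a_onset_ms,
                   cycle_end_ms = p$phases$cycle_end_ms)
  })
  indices <- purrr::imap_dfr(per, function(p, v) {
    dplyr::mutate(p$indices, view = v, .before = 1L)
  })

  structure(
    list(curves = curves_long, phases = phases_tab, indices = indices,
         global = global_average(indices[setdiff(names(indices), "view")]),
         params = list(n_segments = n_segments, n_points = n_points,
                       smooth = smooth)),
    class = "la_strain"
  )
}

#' @export
print.la_strain <- function(x, ...) {
  g <- x$global
  cat(sprintf("<la_strain> %d view(s): %s\n", nrow(x$phases),
              paste(x$phases$view, collapse = ", ")))
  cat(sprintf("  Sl  R/C/A: %.1f / %.1f / %.1f %%\n", g$sl_r, g$sl_c, g$sl_a))
  cat(sprintf("  Mr  R/C/A: %.1f / %.1f / %.1f %%\n", g$mr_r, g$mr_c, g$mr_a))
  cat(sprintf("  SRl S'/E'/A': %.2f / %.2f / %.2f 1/s (|E'|/|A'| = %.2f)\n",
              g$srl_s, g$srl_e, g$srl_a, g$srl_e_over_a))
  if (!is.null(g$cmr_r)) {
    cat(sprintf("  cMr R/C/A: %.1f / %.1f / %.1f %%; pMr R/C/A: %.1f / %.1f / %.1f %%\n",
                g$cmr_r, g$cmr_c, g$cmr_a, g$pmr_r, g$pmr_c, g$pmr_a))
  }
  invisible(x)
}

#' Tidy the strain curves of a fitted LA analysis
#'
#' @param x An `la_strain` object.
#' @param ... Unused.
#' @return Long tibble: `view`, `time_ms`, `quantity` (sl, mr, srl, vr and,
#'   when decomposed, cmr, pmr), `value`.
#' @method tidy la_strain
#' @export
tidy.la_strain <- function(x, ...) x$curves

#' One-row summary of a fitted LA analysis
#'
#' @param x An `la_strain` object.
#' @param ... Unused.
#' @return The cross-view global phasic index row (strain/motion in %,
#'   rates in s^-1).
#' @method glance la_strain
#' @export
glance.la_strain <- function(x, ...) x$global

#' Plot strain and motion-fraction curves with phase boundaries
#'
#' @param object An `la_strain` object.
#' @param quantities Which curves to draw (default all present).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot la_strain
#' @export
autoplot.la_strain <- function(object, quantities = NULL, ...) {
  dat <- object$curves
  if (!is.null(quantities)) dat <- dplyr::filter(dat, .data$quantity %in% quantities)
  bounds <- tidyr::pivot_longer(object$phases, c("t_peak_ms", "t_a_onset_ms"),
                                names_to = "boundary", values_to = "time_ms")
  ggplot2::ggplot(dat, ggplot2::aes(.data$time_ms, .data$value, colour = .data$view)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(
      data = bounds,
      ggplot2::aes(xintercept = .data$time_ms, linetype = .data$boundary),
      colour = "grey40"
    ) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = "strain / motion fraction (rates in 1/s)",
                  linetype = "phase boundary") +
    ggplot2::theme_minimal()
}
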