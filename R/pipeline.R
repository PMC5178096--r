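# Stage-local RNG seeds derived deterministically from the run seed, the
# stage and the subject, so stages are reproducible in isolation and
# independent across subjects. Kept below 2^31.
derive_seed <- function(seed, stage, subject_index) {
  stage_code <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + subject_index * 104729 + stage_code) %% 2147483629)
}

#' Write a synthetic imaging study to disk
#'
#' Generates a full two-group study in the on-disk layout `run_pipeline()`
#' consumes: `subjects.csv` (id, group, height/weight), one contour CSV/JSON
#' pair per view under `contours/<subject>/`, and Dixon NIfTI volumes under
#' `dixon/<subject>/`. Per-subject phantom parameters are drawn from the
#' group distributions of [cohort_reference()] (strain amplitudes, fat
#' volume, myocardial fat fraction, BSA), so the downstream group comparison
#' operates on realistic effect sizes with known per-subject ground truth
#' (returned invisibly and written to `truth.csv`).
#'
#' @param dir Study directory to create.
#' @param n_control,n_case Group sizes.
#' @param seed Run seed; all subject-level draws derive from it.
#' @param n_frames Cine phases per sequence.
#' @param noise_sd_mm Contour jitter (mm).
#' @param dixon_dim,dixon_voxel_mm Dixon phantom grid.
#' @param dixon_noise_sd Dixon image noise SD (signal scale is 1000).
#' @return Invisibly, the per-subject truth tibble.
#' @export
simulate_study <- function(dir, n_control = 19L, n_case = 20L, seed = 1L,
                           n_frames = 20L, noise_sd_mm = 0.15,
                           dixon_dim = c(48L, 48L, 48L), dixon_voxel_mm = 3,
                           dixon_noise_sd = 100) {
  ref <- cohort_reference()
  pull <- function(v, g) {
    row <- ref[ref$variable == v, ]
    c(mean = row[[paste0("mean_", g)]], sd = row[[paste0("sd_", g)]])
  }
  dir.create(file.path(dir, "contours"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "dixon"), recursive = TRUE, showWarnings = FALSE)

  ids <- c(sprintf("C%03d", seq_len(n_control)), sprintf("P%03d", seq_len(n_case)))
  grp <- rep(c("control", "case"), c(n_control, n_case))
  truth <- purrr::map2_dfr(ids, seq_along(ids), function(id, i) {
    g <- if (grp[i] == "control") "control" else "case"
    draws <- withr::with_seed(derive_seed(seed, "subject_params", i), {
      sl_r <- max(stats::rnorm(1, pull("sl_r", g)["mean"], pull("sl_r", g)["sd"]), 8)
      sl_a <- min(max(stats::rnorm(1, pull("sl_a", g)["mean"], pull("sl_a", g)["sd"]), 4),
                  0.9 * sl_r)
      efv <- max(stats::rnorm(1, pull("efv_abs", g)["mean"], pull("efv_abs", g)["sd"]), 40)
      ff <- max(stats::rnorm(1, pull("intramyo_ff", g)["mean"], pull("intramyo_ff", g)["sd"]), 1)
      bsa <- max(stats::rnorm(1, pull("bsa", g)["mean"], pull("bsa", g)["sd"]), 1.4)
      t_peak <- stats::runif(1, 0.35, 0.45)
      t_a <- stats::runif(1, 0.70, 0.78)
      list(sl_r = sl_r, sl_a = sl_a, efv = efv, ff = ff, bsa = bsa,
           t_peak = t_peak, t_a = t_a)
    })
    ph <- la_phantom(
      sl_r = draws$sl_r, sl_a = draws$sl_a,
      t_peak_frac = draws$t_peak, t_a_onset_frac = draws$t_a,
      n_frames = n_frames, noise_sd_mm = noise_sd_mm, view_spread = 0.03,
      translation_along_mm = 4, translation_across_mm = 2,
      seed = derive_seed(seed, "la_phantom", i)
    )
    sdir <- file.path(dir, "contours", id)
    dir.create(sdir, showWarnings = FALSE)
    purrr::iwalk(ph$views, function(v, nm) write_contours(v, file.path(sdir, nm)))

    dx <- dixon_phantom(
      dim_vox = dixon_dim, voxel_mm = dixon_voxel_mm,
      efv_target_ml = draws$efv, myo_ff_pct = draws$ff,
      noise_sd = dixon_noise_sd, seed = derive_seed(seed, "dixon", i)
    )
    write_dixon(dx$study, file.path(dir, "dixon", id))

    height <- 170
    tibble::tibble(
      subject_id = id, group = grp[i],
      sl_r_true = draws$sl_r, sl_a_true = draws$sl_a,
      efv_true_ml = dx$truth$efv_ml, myo_ff_true_pct = draws$ff,
      bsa_true_m2 = draws$bsa,
      height_cm = height, weight_kg = 3600 * draws$bsa^2 / height
    )
  })
  readr::write_csv(
    truth[c("subject_id", "group", "height_cm", "weight_kg")],
    file.path(dir, "subjects.csv")
  )
  readr::write_csv(truth, file.path(dir, "truth.csv"))
  invisible(truth)
}

#' Run the full analysis pipeline on a study directory
#'
#' Per subject: body metrics from `subjects.csv`; strain, phase detection,
#' phasic indices and MV decomposition from every contour view found under
#' `contours/<subject>/`; Dixon fat measures from `dixon/<subject>/`. Then
#' cohort-level: normality-gated group comparisons with percent changes for
#' every derived variable, and correlations of the functional indices with
#' BSA and with the Dixon fat fraction. A stage failure is recorded with the
#' subject id and stage name and the subject is dropped from cohort tables
#' (never silently: see `failures` in the returned bundle); partial results
#' are preserved.
#'
#' @param config A list or path to a YAML file with fields `study_dir`,
#'   `out_dir` (optional; tables are written there as CSV when given) and
#'   optional `n_segments` (12), `n_points` (120), `smooth` (3), `k` (2),
#'   `seed` (1), `alpha_normality` (0.05).
#' @return List of class `la_report`: `subjects`, `indices` (per subject,
#'   global row), `curves`, `fat`, `cohort` (tidy long), `comparisons`,
#'   `correlations`, `failures`, `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(n_segments = 12L, n_points = 120L, smooth = 3L, k = 2L,
                   seed = 1L, alpha_normality = 0.05, out_dir = NULL)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$study_dir) || !dir.exists(config$study_dir)) {
    abort_lamotion("config$study_dir missing or not a directory", "configuration_error")
  }
  subj_path <- file.path(config$study_dir, "subjects.csv")
  if (!file.exists(subj_path)) {
    abort_lamotion("study directory has no subjects.csv", "configuration_error")
  }
  subjects <- readr::read_csv(subj_path, show_col_types = FALSE)
  if (nrow(subjects) == 0L) {
    abort_lamotion("subjects.csv is empty", "configuration_error")
  }
  subjects <- dplyr::bind_cols(subjects, body_metrics(subjects$height_cm, subjects$weight_kg))

  failures <- list()
  note_failure <- function(id, stage, e) {
    failures[[length(failures) + 1L]] <<- tibble::tibble(
      subject_id = id, stage = stage, message = conditionMessage(e)
    )
    NULL
  }

  per_subject <- purrr::map(seq_len(nrow(subjects)), function(i) {
    id <- subjects$subject_id[i]
    cdir <- file.path(config$study_dir, "contours", id)
    strain <- NULL
    if (dir.exists(cdir)) {
      strain <- tryCatch({
        csvs <- list.files(cdir, pattern = "\\.csv$", full.names = TRUE)
        views <- purrr::map(csvs, read_contours)
        fit <- la_strain(views, n_segments = config$n_segments,
                         n_points = config$n_points, smooth = config$smooth)
        fit
      }, error = function(e) note_failure(id, "strain", e))
    }
    fat <- NULL
    ddir <- file.path(config$study_dir, "dixon", id)
    if (dir.exists(ddir)) {
      fat <- tryCatch(
        fat_measures(read_dixon(ddir), bsa_m2 = subjects$bsa_m2[i],
                     k = config$k, seed = derive_seed(config$seed, "kmeans", i)),
        error = function(e) note_failure(id, "fat", e)
      )
    }
    list(id = id, strain = strain, fat = fat)
  })

  indices <- purrr::map_dfr(per_subject, function(s) {
    if (is.null(s$strain)) return(NULL)
    dplyr::mutate(glance.la_strain(s$strain), subject_id = s$id, .before = 1L)
  })
  curves <- purrr::map_dfr(per_subject, function(s) {
    if (is.null(s$strain)) return(NULL)
    dplyr::mutate(s$strain$curves, subject_id = s$id, .before = 1L)
  })
  fat <- purrr::map_dfr(per_subject, function(s) {
    if (is.null(s$fat)) return(NULL)
    dplyr::mutate(s$fat, subject_id = s$id, .before = 1L)
  })

  wide <- dplyr::left_join(
    dplyr::left_join(subjects[c("subject_id", "group", "bsa_m2", "bmi_kg_m2")],
                     indices, by = "subject_id"),
    fat, by = "subject_id"
  )
  cohort <- tidyr::pivot_longer(wide, -c("subject_id", "group"),
                                names_to = "variable", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))

  comparisons <- NULL
  correlations <- NULL
  if (length(unique(subjects$group)) == 2L && nrow(cohort) > 0L) {
    comparisons <- tryCatch(
      compare_cohort(cohort, control = subjects$group[1L],
                     alpha_normality = config$alpha_normality),
      error = function(e) NULL
    )
    fun_vars <- intersect(
      c("sl_r", "sl_c", "sl_a", "sl_a_over_sl_r", "srl_e_over_a",
        "mr_r", "mr_c", "mr_a", "mr_a_over_mr_r", "vr_e_over_a",
        "cmr_r", "cmr_a", "pmr_r"),
      names(wide)
    )
    correlations <- purrr::map_dfr(fun_vars, function(v) {
      purrr::map_dfr(intersect(c("bsa_m2", "ef_fraction_pct"), names(wide)), function(w) {
        tryCatch(correlate(wide[[v]], wide[[w]], pair = c(v, w)),
                 error = function(e) NULL)
      })
    })
  }

  failures <- if (length(failures)) dplyr::bind_rows(failures) else
    tibble::tibble(subject_id = character(), stage = character(), message = character())

  report <- structure(
    list(subjects = subjects, indices = indices, curves = curves, fat = fat,
         cohort = cohort, comparisons = comparisons, correlations = correlations,
         failures = failures,
         provenance = list(
           config = config[c("study_dir", "n_segments", "n_points", "smooth",
                             "k", "seed", "alpha_normality")],
           package_version = as.character(utils::packageVersion("lamotion")),
           n_subjects = nrow(subjects), n_failed = nrow(failures)
         )),
    class = "la_report"
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, nm) if (!is.null(x) && nrow(x)) {
      readr::write_csv(x, file.path(config$out_dir, nm))
    }
    wr(report$indices, "indices.csv")
    wr(report$curves, "curves.csv")
    wr(report$fat, "fat.csv")
    wr(report$cohort, "cohort.csv")
    wr(report$comparisons, "comparisons.csv")
    wr(report$correlations, "correlations.csv")
    wr(report$failures, "failures.csv")
    jsonlite::write_json(report$provenance, file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.la_report <- function(x, ...) {
  cat(sprintf("<la_report> %d subjects (%d failed stages)\n",
              nrow(x$subjects), nrow(x$failures)))
  if (!is.null(x$comparisons)) {
    sig <- sum(x$comparisons$significant, na.rm = TRUE)
    cat(sprintf("  %d variables compared, %d significant at p < 0.05\n",
                nrow(x$comparisons), sig))
  }
  invisible(x)
}
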