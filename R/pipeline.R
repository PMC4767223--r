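#' Run QC, voxel selection and pattern extraction for one participant
#'
#' The per-participant preprocessing chain: runs whose global-signal
#' variance exceeds the threshold are excluded; a voxel set is selected
#' either from the task-versus-baseline t-map of the experimental runs
#' (`selection = "task"`, top `n_voxels` voxels with positive t) or from the
#' air-on localiser contrast (`selection = "somatosensory"`, voxels
#' significant at `alpha`, capped at `n_voxels`); each kept run is z-scored
#' over time, block patterns are extracted with the haemodynamic shift, and
#' the run-mean pattern is subtracted.
#'
#' @param participant an `sd_participant` from [simulate_study()].
#' @param selection `"task"` or `"somatosensory"`.
#' @param n_voxels selection cap, see [select_voxels()].
#' @param alpha significance level for `"somatosensory"` selection.
#' @param qc_threshold run-exclusion threshold, see [exclude_runs()].
#' @param shift_s,window_volumes pattern extraction settings, see
#'   [extract_block_patterns()].
#' @param hrf,hrf_delay GLM response shape, see [fit_glm()].
#' @return A list of class `sd_prepared`: centered `patterns`
#'   (`sd_patterns`), the `voxels` selection tibble, and the `qc` report.
#' @export
participant_patterns <- function(participant,
                                 selection = c("task", "somatosensory"),
                                 n_voxels = 250, alpha = 0.05,
                                 qc_threshold = 0.23, shift_s = 4,
                                 window_volumes = 8,
                                 hrf = c("double_gamma", "delay"),
                                 hrf_delay = 4) {
  selection <- match.arg(selection)
  hrf <- match.arg(hrf)
  stopifnot(inherits(participant, "sd_participant"))
  qc <- exclude_runs(participant$runs, threshold = qc_threshold)
  runs <- qc$kept

  if (selection == "task") {
    glm <- fit_glm(runs, hrf = hrf, hrf_delay = hrf_delay)
    tmap <- t_contrast(glm, "task_vs_baseline")
    sel <- select_voxels(tmap, mode = "top_positive", n = n_voxels,
                         roi_name = "task")
  } else {
    if (is.null(participant$localiser))
      abort("participant has no localiser run; cannot select somatosensory voxels")
    glm <- fit_glm(participant$localiser, hrf = hrf, hrf_delay = hrf_delay)
    tmap <- t_contrast(glm, "air")
    sel <- select_voxels(tmap, mode = "significant", n = n_voxels,
                         alpha = alpha, roi_name = "somatosensory")
  }
  if (!nrow(sel))
    abort("voxel selection is empty; cannot extract patterns",
          class = "surfdecode_empty_selection")

  ps <- bind_patterns(lapply(runs, function(r) {
    z <- zscore_timeseries(r, voxels = sel$voxel)
    extract_block_patterns(z, r$schedule, shift_s = shift_s,
                           window_volumes = window_volumes)
  }))
  ps <- center_patterns(ps, scope = "per_run")
  structure(list(patterns = ps, voxels = sel, qc = qc$report,
                 participant_id = participant$participant_id,
                 selection = selection),
            class = "sd_prepared")
}

#' @export
print.sd_prepared <- function(x, ...) {
  cat(sprintf(
    "<prepared participant %s> %s selection: %d voxels, %d/%d runs kept\n",
    as.character(x$participant_id), x$selection, nrow(x$voxels),
    sum(!x$qc$excluded), nrow(x$qc)))
  invisible(x)
}

#' Decode one participant on one or more contrasts
#'
#' Leave-one-run-out decoding of each contrast on a prepared participant
#' (or an `sd_participant`, which is prepared first).
#'
#' @param x an `sd_prepared` or `sd_participant`.
#' @param contrasts contrast names (see [decoding_contrast()]) or
#'   `sd_contrast` objects.
#' @param seed optional integer seed for the balancing subsamples.
#' @param c_param,tol,max_iter SVM settings, see [loro_cv()].
#' @param ... passed to [participant_patterns()] when `x` is a raw
#'   participant.
#' @return A tibble with one row per contrast: `participant_id`, `roi`,
#'   `contrast`, `accuracy`, `n_folds`.
#' @export
decode_participant <- function(x, contrasts = c("G_vs_R", "GC_vs_RC",
                                                "G_vs_M", "R_vs_M"),
                               seed = NULL, c_param = 1, tol = 1e-3,
                               max_iter = 1e5, ...) {
  if (inherits(x, "sd_participant")) x <- participant_patterns(x, ...)
  stopifnot(inherits(x, "sd_prepared"))
  if (!is.list(contrasts) || inherits(contrasts, "sd_contrast"))
    contrasts <- as.list(contrasts)
  seeds <- derive_seeds(seed, length(contrasts))
  dplyr::bind_rows(lapply(seq_along(contrasts), function(i) {
    ds <- assemble_dataset(x$patterns, contrasts[[i]])
    dec <- loro_cv(ds, c_param = c_param, tol = tol, max_iter = max_iter,
                   seed = if (is.null(seed)) NULL else seeds[i],
                   participant_id = x$participant_id)
    tibble(participant_id = x$participant_id, roi = x$selection,
           contrast = dec$contrast, accuracy = dec$mean_accuracy,
           n_folds = dec$n_folds)
  }))
}

#' Prepare every participant of a study
#'
#' @param study an `sd_study`.
#' @param ... passed to [participant_patterns()].
#' @return A list of `sd_prepared`.
#' @export
prepare_study <- function(study, ...) {
  stopifnot(inherits(study, "sd_study"))
  lapply(study, participant_patterns, ...)
}

#' Assemble one contrast's datasets across participants
#'
#' @param prepared a list of `sd_prepared` (or an `sd_study`, prepared with
#'   defaults).
#' @param contrast a contrast name or `sd_contrast`.
#' @param ... passed to [prepare_study()] when `prepared` is a study.
#' @return A list of `sd_dataset`, one per participant, ready for
#'   [permutation_null()].
#' @export
study_datasets <- function(prepared, contrast, ...) {
  if (inherits(prepared, "sd_study")) prepared <- prepare_study(prepared, ...)
  stopifnot(all(vapply(prepared, inherits, logical(1), "sd_prepared")))
  lapply(prepared, function(p) assemble_dataset(p$patterns, contrast))
}

#' Group decoding accuracies for a study
#'
#' Decodes every participant on every contrast and returns the long
#' accuracy table used for group statistics and plots.
#'
#' @param prepared a list of `sd_prepared` (or an `sd_study`).
#' @param contrasts contrast names or `sd_contrast` objects.
#' @param seed optional master seed (one sub-seed per participant).
#' @param c_param,tol,max_iter SVM settings.
#' @param ... passed to [prepare_study()] when needed.
#' @return A tibble: `participant_id`, `roi`, `contrast`, `accuracy`,
#'   `n_folds`.
#' @export
decode_study <- function(prepared, contrasts = c("G_vs_R", "GC_vs_RC",
                                                 "G_vs_M", "R_vs_M"),
                         seed = NULL, c_param = 1, tol = 1e-3,
                         max_iter = 1e5, ...) {
  if (inherits(prepared, "sd_study")) prepared <- prepare_study(prepared, ...)
  seeds <- derive_seeds(seed, length(prepared))
  dplyr::bind_rows(lapply(seq_along(prepared), function(i) {
    decode_participant(prepared[[i]], contrasts = contrasts,
                       seed = if (is.null(seed)) NULL else seeds[i],
                       c_param = c_param, tol = tol, max_iter = max_iter)
  }))
}

#' Permutation null distribution for one contrast of a study
#'
#' Convenience wrapper: assembles the contrast's datasets across
#' participants and runs [permutation_null()].
#'
#' @param prepared a list of `sd_prepared` (or an `sd_study`).
#' @param contrast a contrast name or `sd_contrast`.
#' @param n_perm,seed,percentile,c_param,tol,max_iter see
#'   [permutation_null()].
#' @param ... passed to [prepare_study()] when needed.
#' @return An `sd_null`.
#' @export
study_permutation_null <- function(prepared, contrast, n_perm = 1000,
                                   seed = NULL, percentile = 95,
                                   c_param = 1, tol = 1e-3, max_iter = 1e5,
                                   ...) {
  datasets <- study_datasets(prepared, contrast, ...)
  permutation_null(datasets, n_perm = n_perm, seed = seed,
                   percentile = percentile, c_param = c_param, tol = tol,
                   max_iter = max_iter)
}
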