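#' z-score voxel time series within a run
#'
#' Each selected voxel's time course is standardised to mean 0 and SD 1
#' within the run (population SD, i.e. the 1/n convention), ahead of block
#' averaging. z-scores are invariant to affine transforms of the raw series.
#'
#' @param run an `sd_run` or voxels x volumes matrix.
#' @param voxels indices of the voxels to keep (default: all).
#' @return A voxels x volumes matrix of z-scores; the selected voxel indices
#'   are stored in attribute `"voxels"`.
#' @export
zscore_timeseries <- function(run, voxels = NULL) {
  x <- if (inherits(run, "sd_run")) run$signal else run
  if (!is.matrix(x) || ncol(x) < 2)
    abort("need a voxels x volumes matrix with at least 2 volumes")
  voxels <- voxels %||% seq_len(nrow(x))
  x <- x[voxels, , drop = FALSE]
  m <- rowMeans(x)
  s <- sqrt(rowMeans((x - m)^2))
  if (any(s == 0))
    abort(paste0("zero-variance voxel(s): ",
                 paste(voxels[s == 0], collapse = ", ")),
          class = "surfdecode_zero_variance")
  z <- (x - m) / s
  attr(z, "voxels") <- voxels
  z
}

new_patterns <- function(x, info, centered = FALSE, scope = NULL) {
  structure(list(x = x, info = info, centered = centered,
                 center_scope = scope),
            class = "sd_patterns")
}

#' @export
print.sd_patterns <- function(x, ...) {
  cat(sprintf("<pattern set> %d patterns x %d voxels (%scentered)\n",
              nrow(x$x), ncol(x$x), if (x$centered) "" else "not "))
  print(dplyr::count(x$info, .data$run_id, .data$condition))
  invisible(x)
}

#' Extract per-block multivoxel response patterns
#'
#' The time series is shifted by `shift_s` seconds to account for the
#' haemodynamic delay, then the signal of each experimental block is
#' averaged over `window_volumes` volumes: the pattern of a block with
#' 0-based onset s is the mean over volumes `[s + shift, s + shift +
#' window)`. Fixation (and air-off) blocks yield no pattern.
#'
#' @param series voxels x volumes matrix (typically z-scored).
#' @param schedule the run's `sd_schedule`.
#' @param tr repetition time; defaults to the schedule attribute.
#' @param shift_s haemodynamic shift in seconds; must be a multiple of `tr`.
#' @param window_volumes volumes averaged per block (8 = one 16-s block at
#'   TR 2).
#' @return An `sd_patterns` object: a patterns x voxels matrix `x` plus an
#'   `info` tibble (`run_id`, `block`, `condition`).
#' @export
extract_block_patterns <- function(series, schedule, tr = NULL, shift_s = 4,
                                   window_volumes = 8) {
  tr <- schedule_tr(schedule, tr)
  if (shift_s %% tr != 0)
    abort("`shift_s` must be a multiple of `tr`",
          class = "surfdecode_config_error")
  shift <- as.integer(shift_s / tr)
  exp_blocks <- schedule[!is_baseline_label(schedule$label), ]
  if (!nrow(exp_blocks)) abort("schedule has no experimental blocks")
  last_needed <- max(exp_blocks$onset) + shift + window_volumes
  if (last_needed > ncol(series))
    abort(sprintf(
      "shifted averaging window ends at volume %d but the run has only %d",
      last_needed, ncol(series)), class = "surfdecode_window_error")

  x <- t(vapply(seq_len(nrow(exp_blocks)), function(k) {
    idx <- exp_blocks$onset[k] + shift + seq_len(window_volumes)
    rowMeans(series[, idx, drop = FALSE])
  }, numeric(nrow(series))))
  info <- tibble(run_id = exp_blocks$run_id, block = exp_blocks$block,
                 condition = exp_blocks$label)
  new_patterns(x, info)
}

#' Combine pattern sets from several runs
#'
#' @param ps_list list of `sd_patterns` with equal voxel counts and equal
#'   centering state.
#' @return A single `sd_patterns`.
#' @export
bind_patterns <- function(ps_list) {
  stopifnot(length(ps_list) > 0,
            all(vapply(ps_list, inherits, logical(1), "sd_patterns")))
  centered <- unique(vapply(ps_list, function(p) p$centered, logical(1)))
  if (length(centered) > 1) abort("cannot mix centered and uncentered sets")
  new_patterns(do.call(rbind, lapply(ps_list, function(p) p$x)),
               dplyr::bind_rows(lapply(ps_list, function(p) p$info)),
               centered = centered)
}

#' Subtract the mean pattern
#'
#' Removes global baseline differences across conditions and runs by
#' subtracting the mean of the patterns: with scope `"per_run"` (the
#' default) each run's mean pattern is removed from that run's patterns,
#' with `"global"` the grand mean pattern is removed from all. Centering is
#' idempotent; a single pattern in a scope group becomes the zero vector.
#'
#' @param ps an `sd_patterns`.
#' @param scope `"per_run"` or `"global"`.
#' @return The centered `sd_patterns` (`centered` flag set).
#' @export
center_patterns <- function(ps, scope = c("per_run", "global")) {
  scope <- match.arg(scope)
  stopifnot(inherits(ps, "sd_patterns"))
  x <- ps$x
  if (scope == "global") {
    x <- sweep(x, 2, colMeans(x))
  } else {
    for (r in unique(ps$info$run_id)) {
      i <- which(ps$info$run_id == r)
      x[i, ] <- sweep(x[i, , drop = FALSE], 2,
                      colMeans(x[i, , drop = FALSE]))
    }
  }
  new_patterns(x, ps$info, centered = TRUE, scope = scope)
}

#' @export
as_tibble.sd_patterns <- function(x, ...) {
  v <- as_tibble(x$x, .name_repair = ~ paste0("v", seq_along(.x)))
  dplyr::bind_cols(x$info, v)
}
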