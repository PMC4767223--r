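#' Experimental design specification for a block-design run
#'
#' Describes the block structure of one scanning run: four surface-property
#' conditions (glossy `G`, glossy-control `GC`, rough `R`, rough-control
#' `RC`) shown in 16-s blocks, four repeats of each per run, with 16-s
#' fixation blocks at the start and end of the run and interposed after the
#' 3rd, 5th, 8th, 11th and 13th stimulus blocks. At the defaults a run holds
#' 23 blocks spanning 368 s (184 volumes at TR = 2 s), preceded by four
#' dummy volumes that are discarded before analysis.
#'
#' @param tr repetition time in seconds.
#' @param block_len block length in seconds; must be divisible by `tr`.
#' @param n_dummy_volumes dummy volumes acquired at the start of the run and
#'   discarded before analysis. Block onsets are 0-based volume indices
#'   counted after dummy removal.
#' @param conditions ordered condition labels.
#' @param repeats_per_condition blocks per condition per run.
#' @param fixation_after 1-based indices of stimulus blocks after which a
#'   fixation block is interposed (leading and trailing fixation blocks are
#'   always added).
#' @param n_runs experimental runs per participant.
#' @param stimuli_per_block stimulus presentations per block (15 unique
#'   images plus one immediate repeat, the 1-back target).
#' @param stim_on_ms,stim_off_ms stimulus duration and inter-stimulus
#'   interval in milliseconds.
#'
#' @return An object of class `sd_design_spec`.
#' @export
#' @examples
#' spec <- design_spec()
#' spec$n_volumes    # 184
design_spec <- function(tr = 2, block_len = 16, n_dummy_volumes = 4,
                        conditions = c("G", "GC", "R", "RC"),
                        repeats_per_condition = 4,
                        fixation_after = c(3, 5, 8, 11, 13),
                        n_runs = 9, stimuli_per_block = 16,
                        stim_on_ms = 500, stim_off_ms = 500) {
  if (tr <= 0) abort("`tr` must be positive")
  if (block_len <= 0 || block_len %% tr != 0)
    abort("`block_len` must be a positive multiple of `tr`",
          class = "surfdecode_config_error")
  conditions <- as.character(conditions)
  if (length(conditions) < 1 || anyDuplicated(conditions))
    abort("`conditions` must be unique, non-empty labels")
  if ("FIX" %in% conditions)
    abort("'FIX' is reserved for fixation blocks")
  if (repeats_per_condition < 1) abort("`repeats_per_condition` must be >= 1")
  n_exp <- length(conditions) * repeats_per_condition
  fixation_after <- sort(unique(as.integer(fixation_after)))
  if (length(fixation_after) &&
      (min(fixation_after) < 1 || max(fixation_after) > n_exp))
    abort("`fixation_after` indices must lie in 1..number of stimulus blocks")

  vols_per_block <- as.integer(block_len / tr)
  n_blocks <- n_exp + length(fixation_after) + 2L
  spec <- list(
    tr = tr, block_len = block_len,
    n_dummy_volumes = as.integer(n_dummy_volumes),
    conditions = conditions,
    repeats_per_condition = as.integer(repeats_per_condition),
    fixation_after = fixation_after,
    n_runs = as.integer(n_runs),
    stimuli_per_block = as.integer(stimuli_per_block),
    stim_on_ms = stim_on_ms, stim_off_ms = stim_off_ms,
    n_experimental_blocks = as.integer(n_exp),
    volumes_per_block = vols_per_block,
    n_blocks = n_blocks,
    n_volumes = n_blocks * vols_per_block,
    duration_s = n_blocks * block_len
  )
  structure(spec, class = "sd_design_spec")
}

#' @export
print.sd_design_spec <- function(x, ...) {
  cat("<block-design spec>\n")
  cat(sprintf("  TR %gs, %d blocks of %gs (%d volumes, %gs per run)\n",
              x$tr, x$n_blocks, x$block_len, x$n_volumes, x$duration_s))
  cat(sprintf("  conditions: %s x %d repeats; %d runs; %d dummy volumes\n",
              paste(x$conditions, collapse = ", "),
              x$repeats_per_condition, x$n_runs, x$n_dummy_volumes))
  invisible(x)
}

new_schedule <- function(run_id, labels, vols_per_block, tr, n_dummy) {
  n <- length(labels)
  sched <- tibble(
    run_id = rep(run_id, n),
    block = seq_len(n),
    label = labels,
    onset = as.integer(cumsum(c(0L, rep(vols_per_block, n - 1L)))),
    n_vol = rep(as.integer(vols_per_block), n)
  )
  attr(sched, "tr") <- tr
  attr(sched, "n_dummy_volumes") <- as.integer(n_dummy)
  class(sched) <- c("sd_schedule", class(sched))
  sched
}

#' Build the block schedule of one run
#'
#' Lays out one run: leading fixation, the stimulus blocks in a
#' pseudo-random condition order (seeded), fixation blocks interposed at the
#' configured positions, and trailing fixation. Onsets are 0-based volume
#' indices counted after dummy removal.
#'
#' @param spec a [design_spec()].
#' @param run_id identifier stored with every block.
#' @param seed optional integer seed controlling the condition order.
#' @return A tibble of class `sd_schedule` with columns `run_id`, `block`,
#'   `label`, `onset` and `n_vol`, carrying `tr` and `n_dummy_volumes` as
#'   attributes.
#' @export
#' @examples
#' sched <- build_design(design_spec(), run_id = 1, seed = 1)
#' sum(sched$n_vol)   # 184 volumes = 368 s at TR 2
build_design <- function(spec, run_id = 1L, seed = NULL) {
  stopifnot(inherits(spec, "sd_design_spec"))
  order <- with_seed_opt(
    seed, sample(rep(spec$conditions, spec$repeats_per_condition)))
  labels <- "FIX"
  for (k in seq_along(order)) {
    labels <- c(labels, order[k])
    if (k %in% spec$fixation_after) labels <- c(labels, "FIX")
  }
  labels <- c(labels, "FIX")
  new_schedule(run_id, labels, spec$volumes_per_block, spec$tr,
               spec$n_dummy_volumes)
}

#' Build the somatosensory localiser schedule
#'
#' Twenty 16-s blocks alternating between air-puff stimulation (`AIR_ON`)
#' and rest (`AIR_OFF`), starting with stimulation.
#'
#' @param n_blocks total number of blocks (alternating, starting `AIR_ON`).
#' @param block_len,tr block length and repetition time in seconds.
#' @param n_dummy_volumes dummy volumes discarded before analysis.
#' @param run_id identifier stored with every block.
#' @return A `sd_schedule` tibble.
#' @export
localiser_design <- function(n_blocks = 20, block_len = 16, tr = 2,
                             n_dummy_volumes = 4, run_id = "loc") {
  if (block_len %% tr != 0)
    abort("`block_len` must be a multiple of `tr`",
          class = "surfdecode_config_error")
  labels <- rep(c("AIR_ON", "AIR_OFF"), length.out = n_blocks)
  new_schedule(run_id, labels, as.integer(block_len / tr), tr,
               n_dummy_volumes)
}

# labels modelled as baseline (no regressor, no extracted pattern)
is_baseline_label <- function(x) x %in% c("FIX", "AIR_OFF")

schedule_tr <- function(schedule, tr = NULL) {
  tr <- tr %||% attr(schedule, "tr")
  if (is.null(tr)) abort("`tr` not supplied and not stored on the schedule")
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
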