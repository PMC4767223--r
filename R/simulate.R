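#' Effect and noise specification for the BOLD simulator
#'
#' Collects the generative parameters of the synthetic voxel time series.
#' The signal model for voxel v at volume t is
#'
#'   signal = baseline * (1 + sum_c reg_c(t) * (shared + amp * P\[v,c\]) / 100)
#'            + drift(t) + AR(1) noise,
#'
#' where `reg_c` is the condition-c block boxcar convolved with the chosen
#' haemodynamic response, `P` holds unit-norm condition pattern vectors
#' (the multivoxel code that decoding recovers), `shared` is a percent
#' signal change common to all experimental blocks, and `amp` scales the
#' condition-specific pattern in percent signal change. With
#' `pattern_amplitude = 0` the condition labels carry no information and
#' decoding accuracy is at chance.
#'
#' Defaults emulate ordinary 3-T block-design data: ~1% voxel noise with
#' mild temporal autocorrelation, a slow scanner drift, and a modest global
#' task response, chosen so a default run's global-signal variance sits
#' comfortably below the 0.23 run-exclusion threshold (note that the
#' block-convolved response overshoots the nominal amplitude, since the
#' haemodynamic kernel has unit peak per impulse).
#'
#' @param n_voxels voxels simulated per region.
#' @param pattern_amplitude percent signal change scaling the
#'   condition-specific pattern vectors.
#' @param shared_amplitude percent signal change common to all experimental
#'   blocks (univariate task response).
#' @param noise_sd marginal standard deviation of the voxel noise, in signal
#'   units (baseline 100 makes this percent signal change).
#' @param ar1 lag-1 autocorrelation of the voxel noise, in `[0, 1)`.
#' @param drift_amplitude,drift_period amplitude (signal units) and period
#'   (seconds) of a sinusoidal global drift with seeded random phase.
#' @param baseline raw signal baseline.
#' @param hrf `"double_gamma"` for the canonical double-gamma response, or
#'   `"delay"` for a pure shift by `hrf_delay` seconds (useful to validate
#'   the pattern-extraction window exactly).
#' @param hrf_delay delay in seconds for the `"delay"` response shape.
#' @return An object of class `sd_effect_spec`.
#' @export
effect_spec <- function(n_voxels = 100, pattern_amplitude = 0.8,
                        shared_amplitude = 0.2, noise_sd = 1, ar1 = 0.3,
                        drift_amplitude = 0.3, drift_period = 128,
                        baseline = 100,
                        hrf = c("double_gamma", "delay"), hrf_delay = 4) {
  hrf <- match.arg(hrf)
  if (n_voxels < 1) abort("`n_voxels` must be >= 1")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (ar1 < 0 || ar1 >= 1) abort("`ar1` must lie in [0, 1)")
  if (baseline <= 0) abort("`baseline` must be positive")
  if (drift_period <= 0) abort("`drift_period` must be positive")
  structure(list(n_voxels = as.integer(n_voxels),
                 pattern_amplitude = pattern_amplitude,
                 shared_amplitude = shared_amplitude,
                 noise_sd = noise_sd, ar1 = ar1,
                 drift_amplitude = drift_amplitude,
                 drift_period = drift_period, baseline = baseline,
                 hrf = hrf, hrf_delay = hrf_delay),
            class = "sd_effect_spec")
}

#' Haemodynamic response kernel sampled at the TR
#'
#' The canonical double-gamma response (peak ~5 s, undershoot ~15 s,
#' normalised to unit peak) or a pure delay, which shifts the boxcar by
#' `delay_s` seconds without reshaping it.
#'
#' @param tr sampling interval, seconds.
#' @param shape `"double_gamma"` or `"delay"`.
#' @param delay_s delay for the `"delay"` shape; must be a multiple of `tr`.
#' @param duration_s support of the double-gamma kernel.
#' @return Numeric kernel; convolve block boxcars with it.
#' @export
hrf_kernel <- function(tr, shape = c("double_gamma", "delay"), delay_s = 4,
                       duration_s = 32) {
  shape <- match.arg(shape)
  if (shape == "delay") {
    if (delay_s %% tr != 0)
      abort("`delay_s` must be a multiple of `tr`",
            class = "surfdecode_config_error")
    return(c(rep(0, delay_s / tr), 1))
  }
  t <- seq(0, duration_s, by = tr)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Unit-norm condition pattern vectors
#'
#' Draws one random pattern vector per condition (standard normal entries,
#' normalised to unit length). Random vectors of this kind are linearly
#' independent with probability one; this is checked.
#'
#' @param n_voxels pattern length.
#' @param conditions condition labels used as column names.
#' @param seed optional integer seed.
#' @return A `n_voxels` x `length(conditions)` matrix with unit-norm columns.
#' @export
condition_patterns <- function(n_voxels, conditions, seed = NULL) {
  P <- with_seed_opt(seed,
                     matrix(rnorm(n_voxels * length(conditions)), n_voxels))
  P <- sweep(P, 2, sqrt(colSums(P^2)), "/")
  colnames(P) <- conditions
  if (qr(P)$rank < ncol(P))
    abort("generated pattern vectors are not linearly independent")
  P
}

# boxcar regressors (one column per non-baseline label), convolved with the
# response kernel; rows tile the full acquisition including dummy volumes
build_regressors <- function(schedule, kernel, n_dummy, conditions = NULL) {
  conds <- conditions %||%
    unique(schedule$label[!is_baseline_label(schedule$label)])
  n_vol <- sum(schedule$n_vol) + n_dummy
  reg <- matrix(0, n_vol, length(conds), dimnames = list(NULL, conds))
  for (k in seq_len(nrow(schedule))) {
    lab <- schedule$label[k]
    if (is_baseline_label(lab) || !(lab %in% conds)) next
    idx <- schedule$onset[k] + n_dummy + seq_len(schedule$n_vol[k])
    reg[idx, lab] <- 1
  }
  for (j in seq_along(conds)) {
    reg[, j] <- convolve(reg[, j], rev(kernel), type = "open")[seq_len(n_vol)]
  }
  reg
}

new_run <- function(signal, schedule, tr, participant_id, run_id, effects) {
  structure(list(signal = signal, schedule = schedule, tr = tr,
                 participant_id = participant_id, run_id = run_id,
                 effects = effects),
            class = "sd_run")
}

#' @export
print.sd_run <- function(x, ...) {
  cat(sprintf("<simulated run %s> %d voxels x %d volumes (TR %gs)\n",
              as.character(x$run_id), nrow(x$signal), ncol(x$signal), x$tr))
  invisible(x)
}

# shared simulation engine. eff is a voxels x conditions matrix of percent
# signal changes; draws (in order) one drift phase, then the noise
# innovations, so runs are bit-reproducible under a seed.
simulate_signal <- function(schedule, eff, effect, tr, n_dummy, seed,
                            participant_id, run_id) {
  n_vol <- sum(schedule$n_vol)
  total <- n_vol + n_dummy
  kernel <- hrf_kernel(tr, effect$hrf, effect$hrf_delay)
  reg <- build_regressors(schedule, kernel, n_dummy, colnames(eff))
  task <- eff %*% t(reg) / 100                     # voxels x total, fraction
  signal <- effect$baseline * (1 + task)

  with_seed_opt(seed, {
    phase <- runif(1, 0, 2 * pi)
    if (effect$drift_amplitude != 0) {
      tsec <- (seq_len(total) - 1) * tr
      drift <- effect$drift_amplitude *
        sin(2 * pi * tsec / effect$drift_period + phase)
      signal <- sweep(signal, 2, drift, "+")
    }
    if (effect$noise_sd > 0) {
      burn <- 50L
      innov_sd <- effect$noise_sd * sqrt(1 - effect$ar1^2)
      innov <- matrix(rnorm((total + burn) * nrow(eff), sd = innov_sd),
                      total + burn, nrow(eff))
      if (effect$ar1 > 0) {
        noise <- stats::filter(innov, effect$ar1, method = "recursive")
      } else {
        noise <- innov
      }
      signal <- signal + t(noise[burn + seq_len(total), , drop = FALSE])
    }
  })

  # dummies are generated, then discarded: analysis sees post-dummy volumes
  signal <- signal[, n_dummy + seq_len(n_vol), drop = FALSE]
  new_run(signal, schedule, tr, participant_id, run_id, eff)
}

#' Simulate one experimental run
#'
#' Generates a voxels x volumes signal matrix for one block schedule under
#' the model described in [effect_spec()]. Dummy volumes are simulated and
#' discarded, so the returned matrix aligns with the schedule's 0-based
#' post-dummy onsets.
#'
#' @param schedule a `sd_schedule` from [build_design()].
#' @param effect a [effect_spec()].
#' @param patterns optional voxels x conditions matrix of unit-norm pattern
#'   vectors (columns named by condition). Supply the same matrix for every
#'   run of a participant so the multivoxel code is stable across runs; if
#'   omitted, patterns are drawn from the seed.
#' @param seed optional integer seed; identical seeds give bit-identical runs.
#' @param participant_id stored with the run.
#' @param tr,n_dummy_volumes override the values stored on the schedule.
#' @return An object of class `sd_run`.
#' @export
simulate_run <- function(schedule, effect, patterns = NULL, seed = NULL,
                         participant_id = NA_integer_, tr = NULL,
                         n_dummy_volumes = NULL) {
  stopifnot(inherits(effect, "sd_effect_spec"))
  tr <- schedule_tr(schedule, tr)
  n_dummy <- n_dummy_volumes %||% attr(schedule, "n_dummy_volumes") %||% 4L
  conds <- unique(schedule$label[!is_baseline_label(schedule$label)])
  seeds <- derive_seeds(seed, 2)
  if (is.null(patterns)) {
    patterns <- condition_patterns(effect$n_voxels, conds, seeds[1])
  }
  if (nrow(patterns) != effect$n_voxels ||
      !all(conds %in% colnames(patterns)))
    abort("`patterns` does not match the effect spec / schedule conditions")
  eff <- effect$shared_amplitude +
    effect$pattern_amplitude * patterns[, conds, drop = FALSE]
  simulate_signal(schedule, eff, effect, tr, n_dummy,
                  if (is.null(seed)) NULL else seeds[2],
                  participant_id, schedule$run_id[1])
}

#' Simulate a somatosensory localiser run
#'
#' Alternating air-on / air-off blocks; a seeded random subset of voxels
#' responds to air-on with the given percent signal change. The indices of
#' the truly responsive voxels are stored in the returned run (element
#' `responsive`) for recovery checks.
#'
#' @param effect a [effect_spec()] providing noise, drift and baseline.
#' @param responsive_fraction fraction of voxels responding to `AIR_ON`.
#' @param response_amplitude percent signal change in responsive voxels.
#' @param n_blocks number of alternating blocks.
#' @param seed optional integer seed.
#' @param participant_id,run_id identifiers stored with the run.
#' @return An `sd_run` whose schedule alternates `AIR_ON` / `AIR_OFF`.
#' @export
simulate_localiser_run <- function(effect, responsive_fraction = 0.5,
                                   response_amplitude = 1.5, n_blocks = 20,
                                   seed = NULL,
                                   participant_id = NA_integer_,
                                   run_id = "loc") {
  stopifnot(inherits(effect, "sd_effect_spec"))
  schedule <- localiser_design(n_blocks = n_blocks, tr = 2,
                               run_id = run_id)
  seeds <- derive_seeds(seed, 2)
  n_resp <- round(responsive_fraction * effect$n_voxels)
  responsive <- with_seed_opt(seeds[1],
                              sort(sample.int(effect$n_voxels, n_resp)))
  eff <- matrix(0, effect$n_voxels, 1, dimnames = list(NULL, "AIR_ON"))
  eff[responsive, 1] <- response_amplitude
  run <- simulate_signal(schedule, eff, effect, schedule_tr(schedule),
                         attr(schedule, "n_dummy_volumes"),
                         if (is.null(seed)) NULL else seeds[2],
                         participant_id, run_id)
  run$responsive <- responsive
  run
}

#' Simulate a full study
#'
#' One dataset per participant: `n_runs` experimental runs sharing that
#' participant's condition pattern vectors, plus one somatosensory localiser
#' run. Participant-level seeds are derived deterministically from the
#' master seed, so different master seeds change the noise realisations but
#' never the design structure.
#'
#' @param design a [design_spec()].
#' @param effect a [effect_spec()].
#' @param n_participants number of simulated participants.
#' @param seed master seed.
#' @param localiser simulate the localiser run as well?
#' @param responsive_fraction,response_amplitude localiser ground truth, see
#'   [simulate_localiser_run()].
#' @return A list of class `sd_study`; each element is a `sd_participant`
#'   with elements `participant_id`, `runs`, `localiser` and `patterns`.
#' @export
#' @examples
#' study <- simulate_study(design_spec(), effect_spec(n_voxels = 20),
#'                         n_participants = 2, seed = 1)
#' length(study[[1]]$runs)   # 9
simulate_study <- function(design, effect, n_participants = 16, seed = NULL,
                           localiser = TRUE, responsive_fraction = 0.5,
                           response_amplitude = 1.5) {
  stopifnot(inherits(design, "sd_design_spec"),
            inherits(effect, "sd_effect_spec"))
  if (n_participants < 1) abort("`n_participants` must be >= 1")
  p_seeds <- derive_seeds(seed, n_participants)
  participants <- lapply(seq_len(n_participants), function(p) {
    seeds <- derive_seeds(p_seeds[p], design$n_runs + 2L)
    patterns <- condition_patterns(effect$n_voxels, design$conditions,
                                   seeds[1])
    runs <- lapply(seq_len(design$n_runs), function(r) {
      sched <- build_design(design, run_id = r, seed = seeds[1 + r])
      simulate_run(sched, effect, patterns = patterns,
                   seed = seeds[1 + r], participant_id = p)
    })
    loc <- NULL
    if (localiser) {
      loc <- simulate_localiser_run(effect, responsive_fraction,
                                    response_amplitude,
                                    seed = seeds[design$n_runs + 2L],
                                    participant_id = p)
    }
    structure(list(participant_id = p, runs = runs, localiser = loc,
                   patterns = patterns),
              class = "sd_participant")
  })
  structure(participants, class = "sd_study",
            design = design, effect = effect)
}

#' Behavioural specification for the 1-back task
#'
#' Each 16-s block presents 15 unique images with one immediate repeat, so a
#' block contributes 1 target and 14 non-target decisions. Responses follow
#' equal-variance signal detection: with sensitivity d' and criterion c,
#' P(hit) = pnorm(d'/2 - c) and P(false alarm) = pnorm(-d'/2 - c), i.e. the
#' criterion is measured from the midpoint between the noise and signal
#' distributions.
#'
#' @param true_dprime generative sensitivity (default matches well-practised
#'   observers).
#' @param criterion response criterion in z units (0 = unbiased).
#' @param targets_per_block,nontargets_per_block decision counts per block.
#' @return An object of class `sd_behavior_spec`.
#' @export
behavior_spec <- function(true_dprime = 2.07, criterion = 0,
                          targets_per_block = 1, nontargets_per_block = 14) {
  if (!is.finite(true_dprime)) abort("`true_dprime` must be finite")
  structure(list(true_dprime = true_dprime, criterion = criterion,
                 targets_per_block = as.integer(targets_per_block),
                 nontargets_per_block = as.integer(nontargets_per_block)),
            class = "sd_behavior_spec")
}

#' Simulate 1-back task outcomes
#'
#' @param spec a [behavior_spec()].
#' @param n_blocks number of stimulus blocks performed.
#' @param seed optional integer seed.
#' @return A one-row tibble with `hits`, `misses`, `false_alarms`,
#'   `correct_rejections`.
#' @export
#' @examples
#' counts <- simulate_behavior(behavior_spec(true_dprime = 2), 1000, seed = 1)
#' dprime(counts$hits, counts$misses, counts$false_alarms,
#'        counts$correct_rejections)
simulate_behavior <- function(spec, n_blocks, seed = NULL) {
  stopifnot(inherits(spec, "sd_behavior_spec"))
  n_t <- n_blocks * spec$targets_per_block
  n_n <- n_blocks * spec$nontargets_per_block
  p_hit <- pnorm(spec$true_dprime / 2 - spec$criterion)
  p_fa <- pnorm(-spec$true_dprime / 2 - spec$criterion)
  with_seed_opt(seed, {
    hits <- rbinom(1, n_t, p_hit)
    fas <- rbinom(1, n_n, p_fa)
    tibble(hits = hits, misses = n_t - hits, false_alarms = fas,
           correct_rejections = n_n - fas)
  })
}
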