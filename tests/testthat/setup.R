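# Shared, lazily computed fixtures. Heavy objects (null studies, permutation
# distributions) are built once per test session and reused across files.
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# 16 null participants x 9 runs under the main design (no condition
# information: pattern_amplitude 0)
main_null_prepared <- function() cached("main_null_prepared", {
  study <- simulate_study(design_spec(),
                          effect_spec(n_voxels = 100, pattern_amplitude = 0),
                          n_participants = 16, seed = 101, localiser = FALSE)
  prepare_study(study, selection = "task")
})

# 6 null participants x 10 runs under the control design
control_null_prepared <- function() cached("control_null_prepared", {
  study <- simulate_study(design_spec(n_runs = 10),
                          effect_spec(n_voxels = 100, pattern_amplitude = 0),
                          n_participants = 6, seed = 202, localiser = FALSE)
  prepare_study(study, selection = "task")
})

main_null <- function(contrast) cached(paste0("main_null_", contrast), {
  study_permutation_null(main_null_prepared(), contrast, n_perm = 1000,
                         seed = 303)
})

control_null <- function(contrast) cached(paste0("control_null_", contrast), {
  study_permutation_null(control_null_prepared(), contrast, n_perm = 1000,
                         seed = 404)
})

# a small fully simulated study with real condition information
small_study <- function() cached("small_study", {
  simulate_study(design_spec(), effect_spec(n_voxels = 40),
                 n_participants = 2, seed = 505)
})

# one run's worth of deterministic schedule for unit tests
unit_schedule <- function() cached("unit_schedule", {
  build_design(design_spec(), run_id = 1, seed = 1)
})

# hand-built sd_run around a given signal matrix
fake_run <- function(signal, schedule, tr = 2, run_id = 1) {
  structure(list(signal = signal, schedule = schedule, tr = tr,
                 participant_id = NA_integer_, run_id = run_id),
            class = "sd_run")
}
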