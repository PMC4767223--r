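#' Global-signal variance of a run
#'
#' The run-exclusion statistic: the global signal g(t) is the mean over
#' voxels at each volume, converted to percent signal change around its
#' temporal mean, and its variance over time (population convention, in
#' squared percent units) is returned. The statistic is invariant to
#' rescaling the raw signal by a positive constant.
#'
#' @param run an `sd_run` or a voxels x volumes matrix.
#' @return Variance of the percent-signal-change global time course (%^2).
#' @export
#' @examples
#' x <- matrix(100, 5, 10)
#' global_signal_variance(x)   # 0 for a constant signal
global_signal_variance <- function(run) {
  x <- if (inherits(run, "sd_run")) run$signal else run
  if (!is.matrix(x) || ncol(x) < 2)
    abort("need a voxels x volumes matrix with at least 2 volumes")
  g <- colMeans(x)
  m <- mean(g)
  if (m == 0)
    abort("global signal has zero mean; percent change undefined",
          class = "surfdecode_qc_error")
  pct <- 100 * (g - m) / m
  mean(pct^2)
}

#' Exclude runs by global-signal variance
#'
#' Runs whose global-signal variance exceeds the threshold are dropped from
#' further analysis; the report lists every run with its statistic and
#' exclusion flag.
#'
#' @param runs a list of `sd_run` objects.
#' @param threshold exclusion threshold in squared percent units (default
#'   0.23).
#' @return A list with `kept` (the retained runs) and `report`, a tibble
#'   with columns `run_id`, `global_signal_variance`, `threshold`,
#'   `excluded`.
#' @export
exclude_runs <- function(runs, threshold = 0.23) {
  if (inherits(runs, "sd_run")) runs <- list(runs)
  if (threshold <= 0) abort("`threshold` must be positive")
  gsv <- vapply(runs, global_signal_variance, numeric(1))
  ids <- vapply(runs, function(r) as.character(r$run_id %||% NA), character(1))
  excluded <- gsv > threshold
  if (all(excluded))
    abort("all runs exceed the global-signal-variance threshold",
          class = "surfdecode_qc_error")
  list(kept = runs[!excluded],
       report = tibble(run_id = ids, global_signal_variance = gsv,
                       threshold = threshold, excluded = excluded))
}
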