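#' Shuffle condition labels within runs
#'
#' Permutes the class labels of a decoding dataset independently within each
#' run, preserving per-run class counts (and hence the structure of the
#' cross-validation folds); the patterns themselves are untouched.
#'
#' @param dataset an `sd_dataset`.
#' @param seed optional integer seed.
#' @return The dataset with permuted labels.
#' @export
shuffle_labels <- function(dataset, seed = NULL) {
  stopifnot(inherits(dataset, "sd_dataset"))
  with_seed_opt(seed, {
    for (r in unique(dataset$run)) {
      i <- which(dataset$run == r)
      dataset$label[i] <- dataset$label[i][sample.int(length(i))]
    }
  })
  dataset
}

#' Permutation null distribution of group decoding accuracy
#'
#' For each of `n_perm` permutations, every participant's leave-one-run-out
#' decoding is rerun with the condition labels shuffled within runs,
#' independently for each test fold ("per test"). Per-fold shuffling makes
#' the fold outcomes mutually independent, so the group-mean null
#' distribution attains the binomial width implied by the total number of
#' test patterns (a single shuffle reused across all folds instead couples
#' the folds through their shared training runs and widens the null). The
#' participants' mean accuracies are averaged into one group value per
#' permutation, and the significance baseline is the upper `percentile`
#' (nearest-rank) of the resulting distribution of group means.
#'
#' @param datasets a single `sd_dataset` or a list with one per participant.
#' @param n_perm number of permutations (values below 100 give an unstable
#'   percentile and trigger a warning).
#' @param seed optional integer seed governing shuffles and balancing
#'   subsamples.
#' @param percentile upper percentile defining the baseline (one-tailed).
#' @param c_param,tol,max_iter SVM settings.
#' @return An object of class `sd_null`: the `n_perm` group-mean accuracies
#'   (`values`), the `boundary` (as a proportion), and bookkeeping fields.
#' @export
permutation_null <- function(datasets, n_perm = 1000, seed = NULL,
                             percentile = 95, c_param = 1, tol = 1e-3,
                             max_iter = 1e5) {
  if (inherits(datasets, "sd_dataset")) datasets <- list(datasets)
  stopifnot(all(vapply(datasets, inherits, logical(1), "sd_dataset")))
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  if (n_perm < 100)
    warn("fewer than 100 permutations give an unstable percentile boundary",
         class = "surfdecode_few_permutations")

  prep <- lapply(datasets, function(d) {
    fc <- run_fold_codes(d$run)
    list(K = tcrossprod(d$x),
         y01 = as.integer(d$label) - 1L,
         code = fc$code,
         balance = d$contrast$balance_training)
  })
  max_iter <- as.integer(max_iter)

  values <- with_seed_opt(seed, {
    vapply(seq_len(n_perm), function(p) {
      mean(vapply(prep, function(d) {
        mean(loro_null_accuracy_cpp(d$K, d$y01, d$code, d$balance, c_param,
                                    tol, max_iter))
      }, numeric(1)))
    }, numeric(1))
  })

  structure(list(values = values,
                 boundary = nearest_rank_percentile(values, percentile),
                 percentile = percentile, n_perm = n_perm,
                 n_participants = length(datasets),
                 contrast = datasets[[1]]$contrast$name),
            class = "sd_null")
}

#' @export
print.sd_null <- function(x, ...) {
  cat(sprintf(
    "<permutation null> %s: %d permutations x %d participant(s)\n",
    x$contrast, x$n_perm, x$n_participants))
  cat(sprintf("  mean %.4f, upper %g%% boundary %.4f (%.2f%%)\n",
              mean(x$values), x$percentile, x$boundary, 100 * x$boundary))
  invisible(x)
}

#' Average null boundaries across regions of interest
#'
#' The per-region upper-percentile baselines are combined by their
#' arithmetic mean, giving the single dotted-line baseline drawn across a
#' group accuracy figure.
#'
#' @param nulls a list of `sd_null` objects (or numeric boundaries).
#' @return The averaged boundary as a proportion.
#' @export
average_boundaries <- function(nulls) {
  if (inherits(nulls, "sd_null")) nulls <- list(nulls)
  b <- vapply(nulls, function(x) {
    if (inherits(x, "sd_null")) x$boundary else as.numeric(x)
  }, numeric(1))
  if (!length(b)) abort("need at least one boundary")
  mean(b)
}
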