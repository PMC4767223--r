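#' Tidy a decoding result
#'
#' @param x an `sd_decoding` from [loro_cv()].
#' @param ... unused.
#' @return Per-fold tibble: `participant_id`, `contrast`, `run`,
#'   `n_train_a`, `n_train_b`, `n_test`, `accuracy`.
#' @export
tidy.sd_decoding <- function(x, ...) {
  dplyr::mutate(x$folds, participant_id = x$participant_id,
                contrast = x$contrast, .before = 1)
}

#' Summarise a decoding result
#'
#' @param x an `sd_decoding`.
#' @param ... unused.
#' @return One-row tibble: `participant_id`, `contrast`, `mean_accuracy`,
#'   `n_folds`.
#' @export
glance.sd_decoding <- function(x, ...) {
  tibble(participant_id = x$participant_id, contrast = x$contrast,
         mean_accuracy = x$mean_accuracy, n_folds = x$n_folds)
}

#' Tidy a permutation null distribution
#'
#' @param x an `sd_null` from [permutation_null()].
#' @param ... unused.
#' @return A tibble with one row per permutation: `contrast`, `permutation`,
#'   `accuracy`.
#' @export
tidy.sd_null <- function(x, ...) {
  tibble(contrast = x$contrast, permutation = seq_along(x$values),
         accuracy = x$values)
}

#' Summarise a permutation null distribution
#'
#' @param x an `sd_null`.
#' @param ... unused.
#' @return One-row tibble: `contrast`, `n_perm`, `n_participants`,
#'   `mean`, `percentile`, `boundary`.
#' @export
glance.sd_null <- function(x, ...) {
  tibble(contrast = x$contrast, n_perm = x$n_perm,
         n_participants = x$n_participants, mean = mean(x$values),
         percentile = x$percentile, boundary = x$boundary)
}

#' Tidy a repeated-measures ANOVA
#'
#' @param x an `sd_anova` from [rm_anova_two_way()].
#' @param ... unused.
#' @return The effect table as a plain tibble (`term`, `df1`, `df2`,
#'   `statistic`, `p.value`).
#' @export
tidy.sd_anova <- function(x, ...) {
  out <- x
  attributes(out)[c("ms_error", "df_error", "data")] <- NULL
  class(out) <- setdiff(class(out), "sd_anova")
  as_tibble(out)
}

#' @export
print.sd_anova <- function(x, ...) {
  cat("<two-way repeated-measures ANOVA>\n")
  print(tidy(x))
  invisible(x)
}
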