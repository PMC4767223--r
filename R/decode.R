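#' Define a binary decoding contrast
#'
#' A contrast names two disjoint sets of conditions; patterns from all
#' member conditions are pooled into each class. The pooled "Matte" class is
#' the union of the two control conditions (`GC` + `RC`), so a Matte test
#' fold holds 8 patterns against 4 for the single-condition class. With
#' `balance_training = TRUE` (the default) the majority class of each
#' training fold is randomly subsampled to the minority size, stratified by
#' run so every run contributes equally after balancing; test folds are
#' never subsampled.
#'
#' @param name contrast label.
#' @param class_a,class_b disjoint, non-empty condition sets.
#' @param balance_training subsample the majority training class?
#' @return An object of class `sd_contrast`.
#' @export
contrast_spec <- function(name, class_a, class_b, balance_training = TRUE) {
  class_a <- as.character(class_a); class_b <- as.character(class_b)
  if (!length(class_a) || !length(class_b))
    abort("both classes must be non-empty")
  if (length(intersect(class_a, class_b)))
    abort("contrast classes must be disjoint")
  structure(list(name = name, class_a = class_a, class_b = class_b,
                 balance_training = isTRUE(balance_training)),
            class = "sd_contrast")
}

#' Standard contrasts by name
#'
#' Accepts `"G_vs_R"`, `"GC_vs_RC"`, `"G_vs_M"`, `"R_vs_M"` and, in general,
#' any `"<x>_vs_<y>"` string where `M` expands to the pooled Matte class
#' `GC + RC`.
#'
#' @param name contrast name.
#' @param balance_training see [contrast_spec()].
#' @return An `sd_contrast`.
#' @export
#' @examples
#' decoding_contrast("G_vs_M")
decoding_contrast <- function(name, balance_training = TRUE) {
  parts <- strsplit(name, "_vs_", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    abort("contrast name must look like '<classA>_vs_<classB>'")
  expand <- function(x) if (x == "M") c("GC", "RC") else x
  contrast_spec(name, expand(parts[1]), expand(parts[2]), balance_training)
}

#' Assemble a labelled dataset for one contrast
#'
#' Selects the patterns belonging to the contrast's classes, labels them,
#' and keeps the run grouping for leave-one-run-out cross-validation.
#' Pooled classes keep all their patterns, so test folds may be unbalanced.
#'
#' @param ps a centered `sd_patterns`.
#' @param contrast an `sd_contrast` or a contrast name understood by
#'   [decoding_contrast()].
#' @return An object of class `sd_dataset` with elements `x` (patterns x
#'   voxels), `label` (factor, class A first), `run` and `contrast`.
#' @export
assemble_dataset <- function(ps, contrast) {
  stopifnot(inherits(ps, "sd_patterns"))
  if (is.character(contrast)) contrast <- decoding_contrast(contrast)
  stopifnot(inherits(contrast, "sd_contrast"))
  if (!isTRUE(ps$centered))
    abort("patterns must be centered before decoding (see center_patterns)")
  lev <- c(paste(contrast$class_a, collapse = "+"),
           paste(contrast$class_b, collapse = "+"))
  in_a <- ps$info$condition %in% contrast$class_a
  in_b <- ps$info$condition %in% contrast$class_b
  keep <- in_a | in_b
  if (!any(in_a) || !any(in_b))
    abort("a contrast class has no patterns")
  label <- factor(ifelse(in_a[keep], lev[1], lev[2]), levels = lev)
  run <- ps$info$run_id[keep]
  counts <- table(run, label)
  if (any(counts == 0))
    abort(paste0("run(s) missing a class: ",
                 paste(rownames(counts)[rowSums(counts == 0) > 0],
                       collapse = ", ")),
          class = "surfdecode_missing_class")
  structure(list(x = ps$x[keep, , drop = FALSE], label = label, run = run,
                 contrast = contrast),
            class = "sd_dataset")
}

#' Train a linear support-vector classifier
#'
#' Hard-margin-in-the-limit linear SVM with hinge loss and box constraint
#' `c_param`, solved in the dual by sequential minimal optimisation with
#' second-order working-set selection. Deterministic given the data.
#'
#' @param x samples x features matrix.
#' @param y two-level factor (or vector coercible to one).
#' @param c_param regularisation parameter C.
#' @param tol KKT-gap convergence tolerance.
#' @param max_iter iteration cap.
#' @return An object of class `sd_svm` with weight vector `w`, bias `b` and
#'   the factor `levels` (decision value > 0 predicts the second level).
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(20, -2), 10), matrix(rnorm(20, 2), 10))
#' y <- rep(c("a", "b"), each = 10)
#' fit <- train_linear_classifier(x, y)
#' predict(fit, x)
train_linear_classifier <- function(x, y, c_param = 1, tol = 1e-4,
                                    max_iter = 1e6) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2)
    abort("training data contain a single class",
          class = "surfdecode_single_class")
  if (nlevels(y) != 2) abort("only binary classification is supported")
  ypm <- as.integer(2L * (as.integer(y) - 1L) - 1L)   # level1 -> -1, level2 -> +1
  fit <- svc_train_cpp(t(x), ypm, c_param, tol, as.integer(max_iter))
  structure(list(w = fit$w, b = fit$b, levels = levels(y),
                 c_param = c_param, iterations = fit$iterations,
                 n_support = sum(fit$alpha > 0)),
            class = "sd_svm")
}

#' @export
print.sd_svm <- function(x, ...) {
  cat(sprintf("<linear SVM> %d features, %d support vectors, C = %g\n",
              length(x$w), x$n_support, x$c_param))
  invisible(x)
}

#' Predict from a linear SVM
#'
#' @param object an `sd_svm`.
#' @param newdata samples x features matrix.
#' @param type `"class"` for labels, `"decision"` for decision values.
#' @param ... unused.
#' @return A factor of predicted labels, or decision values.
#' @export
predict.sd_svm <- function(object, newdata, type = c("class", "decision"),
                           ...) {
  type <- match.arg(type)
  dec <- drop(as.matrix(newdata) %*% object$w + object$b)
  if (type == "decision") return(dec)
  factor(object$levels[ifelse(dec > 0, 2L, 1L)], levels = object$levels)
}

# internal: 0-based fold codes in run-id order
run_fold_codes <- function(run) {
  runs <- sort(unique(run))
  list(runs = runs, code = as.integer(match(run, runs) - 1L))
}

#' Leave-one-run-out cross-validated decoding
#'
#' Each run in turn is the test set and the classifier is trained on all
#' other runs (with the majority training class subsampled to the minority
#' size, stratified by run, when the contrast requests balancing). Fold
#' accuracy is the fraction
#' of correctly classified test patterns; the decoding accuracy is the mean
#' over folds.
#'
#' @param dataset an `sd_dataset` from [assemble_dataset()].
#' @param c_param,tol,max_iter SVM settings, see
#'   [train_linear_classifier()].
#' @param seed optional integer seed for the balancing subsample.
#' @param participant_id stored with the result.
#' @return An object of class `sd_decoding`: per-fold tibble `folds`
#'   (`run`, `n_train_a`, `n_train_b`, `n_test`, `accuracy`),
#'   `mean_accuracy`, `n_folds`, and the contrast name.
#' @export
loro_cv <- function(dataset, c_param = 1, tol = 1e-3, max_iter = 1e5,
                    seed = NULL, participant_id = NA) {
  stopifnot(inherits(dataset, "sd_dataset"))
  fc <- run_fold_codes(dataset$run)
  if (length(fc$runs) < 2)
    abort("leave-one-run-out needs at least 2 runs")
  y01 <- as.integer(dataset$label) - 1L
  K <- tcrossprod(dataset$x)
  balance <- dataset$contrast$balance_training
  acc <- with_seed_opt(seed,
    loro_accuracy_cpp(K, y01, fc$code, balance, c_param, tol,
                      as.integer(max_iter)))

  cnt <- table(factor(dataset$run, levels = fc$runs), dataset$label)
  n_a <- colSums(cnt)[1] - cnt[, 1]         # class-A training count per fold
  n_b <- colSums(cnt)[2] - cnt[, 2]
  if (balance) {
    # run-stratified balancing keeps each training run's minority count
    rowmin <- pmin(cnt[, 1], cnt[, 2])
    m <- sum(rowmin) - rowmin
    n_a <- m; n_b <- m
  }
  folds <- tibble(run = fc$runs,
                  n_train_a = as.integer(n_a), n_train_b = as.integer(n_b),
                  n_test = as.integer(rowSums(cnt)),
                  accuracy = as.numeric(acc))
  structure(list(folds = folds, mean_accuracy = mean(acc),
                 n_folds = length(fc$runs),
                 contrast = dataset$contrast$name,
                 participant_id = participant_id),
            class = "sd_decoding")
}

#' @export
print.sd_decoding <- function(x, ...) {
  cat(sprintf("<decoding result> %s: mean accuracy %.3f over %d folds\n",
              x$contrast, x$mean_accuracy, x$n_folds))
  invisible(x)
}
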