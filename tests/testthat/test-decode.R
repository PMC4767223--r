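test_that("contrast parsing pools Matte and keeps classes disjoint", {
  gm <- decoding_contrast("G_vs_M")
  expect_equal(gm$class_a, "G")
  expect_equal(gm$class_b, c("GC", "RC"))
  gr <- decoding_contrast("G_vs_R")
  expect_equal(gr$class_b, "R")
  expect_error(contrast_spec("x", "G", "G"), "disjoint")
  expect_error(contrast_spec("x", character(), "G"), "non-empty")
  expect_error(decoding_contrast("G_R"), "_vs_")
})

test_that("the linear SVM recovers the maximum-margin separator", {
  # [DERIVED] 1-D geometry: classes at x = -2,-1 and +1,+2; the max-margin
  # hyperplane is x = 0 with |w| = 1 (support vectors at +/-1, margin 1)
  x <- cbind(c(-2, -1, 1, 2), 0)
  y <- factor(c("a", "a", "b", "b"))
  fit <- train_linear_classifier(x, y, tol = 1e-8)
  expect_equal(fit$w, c(1, 0), tolerance = 1e-6)
  expect_equal(fit$b, 0, tolerance = 1e-6)
  expect_equal(predict(fit, x), y)
  expect_equal(predict(fit, x, type = "decision"), c(-2, -1, 1, 2),
               tolerance = 1e-6)
})

test_that("the SVM matches e1071's solution on random problems", {
  skip_if_not_installed("e1071")
  set.seed(21)
  # primal objective oracle: 0.5*||w||^2 + C * sum hinge; both solvers
  # should reach the same optimum of this convex objective
  primal <- function(w, b, x, ypm, C = 1) {
    f <- drop(x %*% w + b)
    0.5 * sum(w^2) + C * sum(pmax(0, 1 - ypm * f))
  }
  for (rep in 1:5) {
    n <- 40; d <- 6
    x <- matrix(rnorm(n * d), n) +
      matrix(rep(c(-0.7, 0.7), each = n / 2), n, d)
    y <- factor(rep(c("a", "b"), each = n / 2))
    ypm <- ifelse(y == "a", -1, 1)
    ours <- train_linear_classifier(x, y, tol = 1e-8)
    ref <- e1071::svm(x, y, kernel = "linear", cost = 1, scale = FALSE)
    w_ref <- drop(t(ref$coefs) %*% ref$SV)
    b_ref <- -ref$rho
    # orient e1071's separator to our convention (level 2 positive)
    if (cor(drop(x %*% w_ref + b_ref), ypm) < 0) {
      w_ref <- -w_ref; b_ref <- -b_ref
    }
    p_ours <- primal(ours$w, ours$b, x, ypm)
    p_ref <- primal(w_ref, b_ref, x, ypm)
    # both optimise the same convex objective; at tol 1e-8 our optimum may
    # be marginally lower than e1071's (its default tolerance is 1e-3), so
    # require agreement to ~1e-3 and never a worse objective than e1071
    expect_lte(p_ours, p_ref * (1 + 1e-8))
    expect_equal(p_ours, p_ref, tolerance = 1e-3)
    expect_equal(ours$w, unname(w_ref), tolerance = 0.05)
    agree <- mean(predict(ours, x) == predict(ref, x))
    expect_gte(agree, 0.95)
  }
})

test_that("single-class training data raise a classed error", {
  x <- matrix(rnorm(10), 5)
  expect_error(train_linear_classifier(x, rep("a", 5)),
               class = "surfdecode_single_class")
})

test_that("assemble_dataset labels, pools and validates runs", {
  study <- small_study()
  prep <- participant_patterns(study[[1]], selection = "task", n_voxels = 20)
  ds <- assemble_dataset(prep$patterns, "G_vs_M")
  expect_s3_class(ds, "sd_dataset")
  expect_equal(levels(ds$label), c("G", "GC+RC"))
  expect_equal(unname(table(ds$label)), c(36L, 72L), ignore_attr = TRUE)
  expect_equal(nrow(ds$x), 108L)
  # uncentered patterns are rejected
  raw <- extract_block_patterns(
    matrix(rnorm(3 * 184), 3), unit_schedule())
  expect_error(assemble_dataset(raw, "G_vs_R"), "centered")
})

test_that("leave-one-run-out folds have the documented structure", {
  study <- small_study()
  prep <- participant_patterns(study[[1]], selection = "task", n_voxels = 20)
  ds <- assemble_dataset(prep$patterns, "G_vs_M")
  dec <- loro_cv(ds, seed = 1)
  expect_equal(dec$n_folds, 9L)
  expect_equal(nrow(dec$folds), 9L)
  # pooled contrast: 12 test patterns per fold, training balanced 32 vs 32
  expect_true(all(dec$folds$n_test == 12L))
  expect_true(all(dec$folds$n_train_a == 32L))
  expect_true(all(dec$folds$n_train_b == 32L))
  expect_equal(dec$mean_accuracy, mean(dec$folds$accuracy))
  # balanced contrast: 8 tests per fold, 32 vs 32 training without subsampling
  dec2 <- loro_cv(assemble_dataset(prep$patterns, "G_vs_R"), seed = 1)
  expect_true(all(dec2$folds$n_test == 8L))
  expect_true(all(dec2$folds$n_train_a == 32L))
})

test_that("decoding with informative patterns beats chance; accuracy is seeded", {
  study <- small_study()
  prep <- participant_patterns(study[[1]], selection = "task", n_voxels = 20)
  ds <- assemble_dataset(prep$patterns, "G_vs_R")
  a <- loro_cv(ds, seed = 9)
  b <- loro_cv(ds, seed = 9)
  expect_identical(a$folds, b$folds)
  expect_gt(a$mean_accuracy, 0.8)
})

test_that("tidy and glance summarise decoding results", {
  study <- small_study()
  prep <- participant_patterns(study[[1]], selection = "task", n_voxels = 20)
  dec <- loro_cv(assemble_dataset(prep$patterns, "G_vs_R"), seed = 1,
                 participant_id = 1)
  td <- tidy(dec)
  expect_equal(nrow(td), 9L)
  expect_true(all(c("participant_id", "contrast", "run", "accuracy")
                  %in% names(td)))
  gl <- glance(dec)
  expect_equal(gl$mean_accuracy, dec$mean_accuracy)
  expect_equal(gl$contrast, "G_vs_R")
})
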