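test_that("GLM betas and contrast t equal the normal-equations / lm oracle", {
  sched <- unit_schedule()
  set.seed(11)
  n_vox <- 5
  sig <- matrix(rnorm(n_vox * 184, 100, 1), n_vox, 184)
  run <- fake_run(sig, sched)
  glm <- fit_glm(run)

  # independent oracle: rebuild the design with lm() per voxel
  kern <- hrf_kernel(2, "double_gamma")
  conds <- glm$conditions
  X <- matrix(0, 184, length(conds))
  for (j in seq_along(conds)) {
    box <- numeric(184)
    for (k in which(sched$label == conds[j]))
      box[sched$onset[k] + 1:8] <- 1
    X[, j] <- convolve(box, rev(kern), type = "open")[1:184]
  }
  cvec <- rep(1 / length(conds), length(conds))
  for (v in seq_len(n_vox)) {
    fit <- lm(sig[v, ] ~ X)
    expect_equal(unname(glm$betas[v, seq_along(conds)]),
                 unname(coef(fit)[-1]), tolerance = 1e-8)
    # t for the average-condition contrast via lm's vcov
    est <- sum(cvec * coef(fit)[-1])
    se <- sqrt(drop(t(cvec) %*% vcov(fit)[-1, -1] %*% cvec))
    tm <- t_contrast(glm, "task_vs_baseline")
    expect_equal(tm$t[v], est / se, tolerance = 1e-8)
  }
  expect_equal(glm$dof, 184 - length(conds) - 1)
})

test_that("multi-run GLM gets one intercept per run and pooled dof", {
  set.seed(12)
  scheds <- lapply(1:3, function(r) build_design(design_spec(), r, seed = r))
  runs <- lapply(scheds, function(s)
    fake_run(matrix(rnorm(2 * 184, 100), 2, 184), s, run_id = s$run_id[1]))
  glm <- fit_glm(runs)
  expect_equal(glm$n_volumes, 3 * 184)
  expect_equal(length(glm$terms), 4 + 3)
  expect_equal(glm$dof, 3 * 184 - 7)
  expect_true(all(paste0("run_", 1:3) %in% glm$terms))
})

test_that("rank-deficient designs raise a classed error", {
  # every block labelled G with a zero-delay unit kernel makes the G
  # regressor an all-ones column, collinear with the run intercept
  all_task <- unit_schedule()
  all_task$label[] <- "G"
  run <- fake_run(matrix(rnorm(184, 100), 1), all_task)
  expect_error(fit_glm(run, hrf = "delay", hrf_delay = 0),
               class = "surfdecode_design_error")
})

test_that("t_contrast validates contrast names and weights", {
  sched <- unit_schedule()
  run <- fake_run(matrix(rnorm(2 * 184, 100), 2), sched)
  glm <- fit_glm(run)
  expect_error(t_contrast(glm, "air"), "AIR_ON")
  expect_error(t_contrast(glm, c(bogus = 1)), "named after design regressors")
  # a named G - R contrast matches the direct computation
  tm <- t_contrast(glm, c(G = 1, R = -1))
  expect_equal(tm$estimate, unname(glm$betas[, "G"] - glm$betas[, "R"]))
})

test_that("top-positive selection keeps at most n voxels with t > 0, ranked", {
  tmap <- tibble::tibble(voxel = 1:6, estimate = 0,
                         t = c(2.5, -1, 0.5, 3.5, 0, 0.5))
  sel <- select_voxels(tmap, "top_positive", n = 3, roi_name = "v")
  expect_equal(sel$voxel, c(4L, 1L, 3L))   # tie at t=0.5 broken by index
  expect_equal(sel$rank, 1:3)
  expect_true(all(sel$t > 0))
  # fewer positive voxels than the cap: all of them are used
  sel_all <- select_voxels(tmap, "top_positive", n = 250)
  expect_equal(nrow(sel_all), 4L)
})

test_that("significant-mode selection applies the two-sided t threshold", {
  dof <- 30
  tcrit <- qt(0.975, dof)
  tmap <- tibble::tibble(voxel = 1:4, estimate = 0,
                         t = c(tcrit + 0.01, tcrit - 0.01, -(tcrit + 0.5), 10))
  attr(tmap, "dof") <- dof
  sel <- select_voxels(tmap, "significant", n = 250)
  expect_setequal(sel$voxel, c(1L, 3L, 4L))
  expect_equal(sel$voxel[1], 4L)           # ranked by descending t
  no_dof <- tibble::tibble(voxel = 1, t = 1)
  expect_error(select_voxels(no_dof, "significant"), "dof")
})

test_that("empty selections warn with a classed condition", {
  tmap <- tibble::tibble(voxel = 1:3, estimate = 0, t = c(-1, -2, 0))
  expect_warning(sel <- select_voxels(tmap, "top_positive"),
                 class = "surfdecode_empty_selection")
  expect_equal(nrow(sel), 0L)
})
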