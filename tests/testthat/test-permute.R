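test_that("shuffling permutes labels within runs only", {
  study <- small_study()
  prep <- participant_patterns(study[[1]], selection = "task", n_voxels = 20)
  ds <- assemble_dataset(prep$patterns, "G_vs_M")
  sh <- shuffle_labels(ds, seed = 1)
  expect_identical(sh$x, ds$x)
  expect_identical(sh$run, ds$run)
  # per-run class counts (and hence fold structure) are preserved
  expect_equal(table(sh$run, sh$label), table(ds$run, ds$label))
  expect_false(identical(sh$label, ds$label))
  expect_identical(shuffle_labels(ds, seed = 1)$label, sh$label)
})

test_that("nearest-rank percentile matches its definition", {
  # [DERIVED] values 1..100: upper 95th percentile is the 95th order stat
  x <- sample(1:100)
  expect_equal(surfdecode:::nearest_rank_percentile(x, 95), 95)
  expect_equal(surfdecode:::nearest_rank_percentile(1:10, 95), 10)
  expect_equal(surfdecode:::nearest_rank_percentile(1:10, 91), 10)
  expect_equal(surfdecode:::nearest_rank_percentile(1:10, 90), 9)
  expect_equal(surfdecode:::nearest_rank_percentile(5, 95), 5)
})

test_that("single-participant null accuracies follow the binomial law", {
  # one null participant, G_vs_R: each permutation's accuracy is a mean of
  # 72 Bernoulli(0.5) tests; compare the shuffle distribution to
  # Binomial(72, 0.5)/72 with a KS test over 300 permutations
  study <- simulate_study(design_spec(),
                          effect_spec(n_voxels = 30, pattern_amplitude = 0),
                          n_participants = 1, seed = 31, localiser = FALSE)
  prep <- participant_patterns(study[[1]], selection = "task", n_voxels = 30)
  ds <- assemble_dataset(prep$patterns, "G_vs_R")
  nul <- permutation_null(ds, n_perm = 300, seed = 32)
  expect_length(nul$values, 300)
  set.seed(33)
  ref <- rbinom(3000, 72, 0.5) / 72
  ks <- suppressWarnings(ks.test(nul$values, ref))
  expect_gt(ks$p.value, 0.001)
  expect_equal(mean(nul$values), 0.5, tolerance = 3 * sd(nul$values) / sqrt(300))
})

test_that("the null boundary narrows as group size grows", {
  # with N participants the group-mean SD scales as 1/sqrt(N), so the upper
  # boundary must decrease from 1 to 4 participants
  study <- simulate_study(design_spec(),
                          effect_spec(n_voxels = 30, pattern_amplitude = 0),
                          n_participants = 4, seed = 41, localiser = FALSE)
  prep <- prepare_study(study, selection = "task", n_voxels = 30)
  ds <- study_datasets(prep, "G_vs_R")
  n1 <- permutation_null(ds[1], n_perm = 300, seed = 42)
  n4 <- permutation_null(ds, n_perm = 300, seed = 42)
  expect_lt(n4$boundary, n1$boundary)
  expect_lt(sd(n4$values), sd(n1$values))
  expect_equal(n4$n_participants, 4)
})

test_that("permutation_null is reproducible and warns on tiny n_perm", {
  study <- small_study()
  prep <- participant_patterns(study[[1]], selection = "task", n_voxels = 20)
  ds <- assemble_dataset(prep$patterns, "G_vs_R")
  expect_warning(permutation_null(ds, n_perm = 10, seed = 1),
                 class = "surfdecode_few_permutations")
  a <- suppressWarnings(permutation_null(ds, n_perm = 50, seed = 2))
  b <- suppressWarnings(permutation_null(ds, n_perm = 50, seed = 2))
  expect_identical(a$values, b$values)
  expect_equal(a$boundary,
               surfdecode:::nearest_rank_percentile(a$values, 95))
})

test_that("average_boundaries averages across nulls", {
  expect_equal(average_boundaries(list(0.52, 0.54)), 0.53)
  expect_error(average_boundaries(list()), "at least one")
})

test_that("tidy and glance summarise null distributions", {
  study <- small_study()
  prep <- participant_patterns(study[[1]], selection = "task", n_voxels = 20)
  ds <- assemble_dataset(prep$patterns, "G_vs_R")
  nul <- suppressWarnings(permutation_null(ds, n_perm = 50, seed = 3))
  td <- tidy(nul)
  expect_equal(nrow(td), 50L)
  expect_named(td, c("contrast", "permutation", "accuracy"))
  gl <- glance(nul)
  expect_equal(gl$boundary, nul$boundary)
  expect_equal(gl$n_perm, 50L)
})
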