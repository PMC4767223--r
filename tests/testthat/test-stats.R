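test_that("one-tailed t-test matches t.test and the frozen oracle", {
  # [DERIVED] mean 0.7, sd 0.1, n 3 vs 0.5: t = 0.2 / (0.1/sqrt(3)) = 3.4641
  res <- one_sample_t_one_tailed(c(0.6, 0.7, 0.8), baseline = 0.5)
  expect_equal(res$t, 3.464101615137754, tolerance = 1e-12)
  expect_equal(res$dof, 2)
  ref <- t.test(c(0.6, 0.7, 0.8), mu = 0.5, alternative = "greater")
  expect_equal(res$p_one_tailed, unname(ref$p.value), tolerance = 1e-12)
  # Bonferroni: same p, smaller alpha
  res10 <- one_sample_t_one_tailed(c(0.6, 0.7, 0.8), m_tests = 10)
  expect_equal(res10$alpha_corrected, 0.005)
  expect_equal(res10$p_one_tailed, res$p_one_tailed)
  expect_false(res10$significant)
})

test_that("two-way rm-ANOVA matches the hand sums-of-squares oracle", {
  # [DERIVED] 2x2 within-subject toy, 4 subjects, decomposed by hand below
  d <- expand.grid(S = factor(1:4), A = c("a1", "a2"), B = c("b1", "b2"))
  set.seed(8)
  d$y <- round(rnorm(16, 10, 2) + (d$A == "a2") * 1.5 +
                 (d$B == "b2") * 0.5, 2)
  fit <- rm_anova_two_way(d, y, S, A, B)
  td <- tidy(fit)

  # oracle: classical within-subject decomposition
  gm <- mean(d$y)
  mS <- tapply(d$y, d$S, mean); mA <- tapply(d$y, d$A, mean)
  mB <- tapply(d$y, d$B, mean)
  mSA <- tapply(d$y, list(d$S, d$A), mean)
  mSB <- tapply(d$y, list(d$S, d$B), mean)
  mAB <- tapply(d$y, list(d$A, d$B), mean)
  ssA <- 8 * sum((mA - gm)^2)
  ssB <- 8 * sum((mB - gm)^2)
  ssSA <- 2 * sum((mSA - outer(mS, mA, `+`) + gm)^2)
  ssSB <- 2 * sum((mSB - outer(mS, mB, `+`) + gm)^2)
  ssAB <- 4 * sum((mAB - outer(mA, mB, `+`) + gm)^2)
  ssSAB <- sum((d$y - mSA[cbind(d$S, d$A)] - mSB[cbind(d$S, d$B)] -
                  mAB[cbind(d$A, d$B)] + mS[d$S] + mA[d$A] + mB[d$B] - gm)^2)
  fA <- (ssA / 1) / (ssSA / 3)
  fB <- (ssB / 1) / (ssSB / 3)
  fAB <- (ssAB / 1) / (ssSAB / 3)
  expect_equal(td$statistic, c(fA, fB, fAB), tolerance = 1e-8)
  expect_equal(td$df1, c(1, 1, 1))
  expect_equal(td$df2, c(3, 3, 3))
  expect_equal(td$p.value, pf(c(fA, fB, fAB), 1, 3, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("rm-ANOVA validates its input layout", {
  d <- expand.grid(S = 1:3, A = c("a1", "a2"), B = c("b1", "b2"))
  d$y <- rnorm(12)
  expect_error(rm_anova_two_way(d[-1, ], y, S, A, B),
               class = "surfdecode_design_error")
})

test_that("Tukey HSD reduces to the paired comparison at two levels", {
  # [DERIVED] with 2 levels, q = sqrt(2) * |t| and the ptukey p equals the
  # ANOVA main-effect p
  d <- expand.grid(S = factor(1:6), A = c("a1", "a2"), B = c("b1", "b2"))
  set.seed(9)
  d$y <- rnorm(24) + (d$A == "a2") * 0.9
  fit <- rm_anova_two_way(d, y, S, A, B)
  hsd <- tukey_hsd(fit, "A")
  td <- tidy(fit)
  expect_equal(nrow(hsd), 1L)
  expect_equal(hsd$q^2 / 2, td$statistic[td$term == "A"], tolerance = 1e-8)
  expect_equal(hsd$p.value, td$p.value[td$term == "A"], tolerance = 1e-8)
  expect_equal(hsd$estimate,
               unname(diff(tapply(d$y, d$A, mean))), tolerance = 1e-12)
})

test_that("Wilcoxon signed-rank matches the exact oracle and wilcox.test", {
  # [DERIVED] n = 7, all differences positive and tie-free:
  # two-tailed exact p = 2 / 2^7 = 0.015625
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6, 7))
  expect_equal(res$p.value, 0.015625, tolerance = 1e-12)
  expect_equal(res$statistic, 28)
  expect_equal(res$method, "exact")
  ref <- wilcox.test(c(1, 2, 3, 4, 5, 6, 7), exact = TRUE)
  expect_equal(res$p.value, unname(ref$p.value), tolerance = 1e-12)
  # ties force the corrected normal approximation, matching wilcox.test
  x <- c(2, 2, -1, 3, 5, 5, -4, 6, 1, -1, 7, 3)
  res2 <- wilcoxon_signed_rank(x)
  ref2 <- wilcox.test(x, exact = FALSE, correct = TRUE)
  expect_equal(res2$method, "normal-approximation")
  expect_equal(res2$p.value, unname(ref2$p.value), tolerance = 1e-10)
  expect_equal(res2$statistic, unname(ref2$statistic))
  # paired form (tie-free positive differences 1:7 -> exact p = 1/2^6)
  expect_equal(wilcoxon_signed_rank(c(2, 4, 6, 8, 10, 12, 14),
                                    c(1, 2, 3, 4, 5, 6, 7))$p.value, 0.015625)
  expect_error(wilcoxon_signed_rank(rep(0, 5)),
               class = "surfdecode_degenerate")
})

test_that("d-prime matches the quantile-difference oracle", {
  # [DERIVED] hit rate 0.84, FA 0.16: d' = 2 * qnorm(0.84) = 1.9891
  res <- dprime(84, 16, 16, 84)
  expect_equal(res$d_prime, 2 * qnorm(0.84), tolerance = 1e-12)
  expect_equal(res$criterion, 0, tolerance = 1e-12)
  expect_false(res$corrected)
  # perfect rates get the log-linear correction and stay finite
  res2 <- dprime(10, 0, 0, 10)
  expect_true(res2$corrected)
  expect_true(is.finite(res2$d_prime))
  expect_equal(res2$hit_rate, 10.5 / 11)
  expect_error(dprime(0, 0, 1, 1), class = "surfdecode_degenerate")
})
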