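#' One-tailed one-sample t-test against a baseline, Bonferroni corrected
#'
#' Tests whether group values (e.g. per-participant decoding accuracies)
#' exceed a baseline: t = (mean - baseline) / (sd / sqrt(n)) with upper-tail
#' p. With `m_tests` simultaneous tests the significance level is
#' Bonferroni-corrected to `alpha / m_tests`. Zero-variance input gives
#' t = +/-Inf (p = 0 or 1), or t = 0 and p = 0.5 when all values equal the
#' baseline.
#'
#' @param values numeric vector, n >= 2.
#' @param baseline chance level tested against (0.5 for binary decoding).
#' @param m_tests number of simultaneous tests.
#' @param alpha family-wise significance level.
#' @return A one-row tibble: `estimate`, `baseline`, `t`, `dof`,
#'   `p_one_tailed`, `alpha_corrected`, `significant`.
#' @export
#' @examples
#' one_sample_t_one_tailed(c(0.6, 0.7, 0.8), baseline = 0.5, m_tests = 10)
one_sample_t_one_tailed <- function(values, baseline = 0.5, m_tests = 1,
                                    alpha = 0.05) {
  n <- length(values)
  if (n < 2) abort("need at least 2 values")
  if (m_tests < 1) abort("`m_tests` must be >= 1")
  m <- mean(values)
  s <- sd(values)
  if (s == 0) {
    t <- if (m > baseline) Inf else if (m < baseline) -Inf else 0
    p <- if (m > baseline) 0 else if (m < baseline) 1 else 0.5
  } else {
    t <- (m - baseline) / (s / sqrt(n))
    p <- pt(t, n - 1, lower.tail = FALSE)
  }
  tibble(estimate = m, baseline = baseline, t = t, dof = n - 1,
         p_one_tailed = p, alpha_corrected = alpha / m_tests,
         significant = p <= alpha / m_tests)
}

#' Two-way repeated-measures ANOVA
#'
#' Fully within-subject two-factor ANOVA on one observation (cell mean) per
#' subject x A x B cell, with each effect tested against its own
#' subject-interaction error term (A against A x subject, B against
#' B x subject, A:B against A x B x subject). Used for the contrast x ROI
#' comparisons of group decoding accuracy.
#'
#' @param data a data frame in long format.
#' @param response,subject,factor_a,factor_b bare column names.
#' @return An object of class `sd_anova`: a tibble with columns `term`,
#'   `df1`, `df2`, `statistic` (F) and `p.value`, carrying the error-term
#'   mean squares and cell structure as attributes for [tukey_hsd()].
#' @export
rm_anova_two_way <- function(data, response, subject, factor_a, factor_b) {
  d <- tibble(
    y = dplyr::pull(data, {{ response }}),
    S = factor(dplyr::pull(data, {{ subject }})),
    A = factor(dplyr::pull(data, {{ factor_a }})),
    B = factor(dplyr::pull(data, {{ factor_b }}))
  )
  counts <- table(d$S, d$A, d$B)
  if (any(counts != 1))
    abort("need exactly one observation per subject x A x B cell",
          class = "surfdecode_design_error")
  if (nlevels(d$S) < 2) abort("need at least 2 subjects")

  fit <- aov(y ~ A * B + Error(S / (A * B)), data = d)
  sm <- summary(fit)
  grab <- function(stratum, effect) {
    tab <- sm[[stratum]][[1]]
    rn <- trimws(rownames(tab))
    i <- match(effect, rn)
    j <- match("Residuals", rn)
    list(df1 = tab$Df[i], df2 = tab$Df[j], f = tab$`F value`[i],
         p = tab$`Pr(>F)`[i], ms_err = tab$`Mean Sq`[j])
  }
  ra <- grab("Error: S:A", "A")
  rb <- grab("Error: S:B", "B")
  rab <- grab("Error: S:A:B", "A:B")

  out <- tibble(
    term = c("A", "B", "A:B"),
    df1 = c(ra$df1, rb$df1, rab$df1),
    df2 = c(ra$df2, rb$df2, rab$df2),
    statistic = c(ra$f, rb$f, rab$f),
    p.value = c(ra$p, rb$p, rab$p)
  )
  attr(out, "ms_error") <- c(A = ra$ms_err, B = rb$ms_err, `A:B` = rab$ms_err)
  attr(out, "df_error") <- c(A = ra$df2, B = rb$df2, `A:B` = rab$df2)
  attr(out, "data") <- d
  class(out) <- c("sd_anova", class(out))
  out
}

#' Tukey HSD post-hoc comparisons for a within-subject factor
#'
#' Pairwise comparisons of one factor's marginal means using the studentized
#' range with that factor's subject-interaction mean square as the error
#' term (the repeated-measures analogue of the classical HSD).
#'
#' @param fit an `sd_anova` from [rm_anova_two_way()].
#' @param which `"A"` or `"B"`, the factor to compare.
#' @param alpha significance level.
#' @return A tibble with one row per unordered level pair: `level_1`,
#'   `level_2`, `estimate` (mean difference), `q`, `p.value`, `significant`.
#'   Empty for a single-level factor.
#' @export
tukey_hsd <- function(fit, which = c("A", "B"), alpha = 0.05) {
  which <- match.arg(which)
  stopifnot(inherits(fit, "sd_anova"))
  d <- attr(fit, "data")
  f <- d[[which]]
  lev <- levels(f)
  if (length(lev) < 2) {
    return(tibble(level_1 = character(), level_2 = character(),
                  estimate = numeric(), q = numeric(), p.value = numeric(),
                  significant = logical()))
  }
  means <- tapply(d$y, f, mean)
  n_per_mean <- nrow(d) / length(lev)      # subjects x other-factor levels
  ms <- attr(fit, "ms_error")[[which]]
  dfe <- attr(fit, "df_error")[[which]]
  se <- sqrt(ms / n_per_mean)
  pairs <- utils::combn(lev, 2)
  est <- means[pairs[2, ]] - means[pairs[1, ]]
  q <- abs(est) / se
  p <- ptukey(q, nmeans = length(lev), df = dfe, lower.tail = FALSE)
  tibble(level_1 = pairs[1, ], level_2 = pairs[2, ],
         estimate = as.numeric(est), q = as.numeric(q),
         p.value = as.numeric(p), significant = p < alpha)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Exact null distribution (via the signed-rank distribution) for n <= 12
#' when the absolute differences are free of ties and zeros; otherwise the
#' normal approximation with tie correction and a 0.5 continuity correction.
#' The standardized statistic Z is reported in both cases. Zero differences
#' are dropped; if all differences are zero the test is undefined and an
#' error is raised.
#'
#' @param x,y paired samples (`y` omitted: `x` are the differences).
#' @param two_tailed if `FALSE`, the upper-tailed alternative (x > y).
#' @return A one-row tibble: `statistic` (V, the positive-rank sum), `z`,
#'   `p.value`, `n` (non-zero pairs), `method`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 1, 4, 2, 5, 3), rep(0, 7))
wilcoxon_signed_rank <- function(x, y = NULL, two_tailed = TRUE) {
  d <- if (is.null(y)) x else x - y
  if (!is.null(y) && length(x) != length(y)) abort("samples must be paired")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    abort("all differences are zero; the signed-rank test is undefined",
          class = "surfdecode_degenerate")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))

  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- if (v == mu) 0 else (v - mu - 0.5 * sign(v - mu)) / sqrt(sig2)

  if (n <= 12 && !ties) {
    p_up <- psignrank(v - 1, n, lower.tail = FALSE)
    p_lo <- psignrank(v, n)
    p <- if (two_tailed) min(1, 2 * min(p_up, p_lo)) else p_up
    method <- "exact"
  } else {
    p <- if (two_tailed) 2 * pnorm(-abs(z)) else pnorm(z, lower.tail = FALSE)
    method <- "normal-approximation"
  }
  tibble(statistic = v, z = z, p.value = p, n = n, method = method)
}

#' Sensitivity index d-prime from response counts
#'
#' d' = qnorm(hit rate) - qnorm(false-alarm rate) under equal-variance
#' signal detection. When any rate is 0 or 1 the log-linear correction is
#' applied (0.5 added to every cell count, 1 to every denominator) so the
#' index stays finite; the `corrected` flag records this.
#'
#' @param hits,misses,false_alarms,correct_rejections non-negative counts.
#' @return A one-row tibble: `d_prime`, `hit_rate`, `fa_rate`, `criterion`,
#'   `corrected`.
#' @export
#' @examples
#' dprime(84, 16, 16, 84)   # ~1.989
dprime <- function(hits, misses, false_alarms, correct_rejections) {
  cnt <- c(hits, misses, false_alarms, correct_rejections)
  if (any(cnt < 0)) abort("counts must be non-negative")
  n_sig <- hits + misses
  n_noise <- false_alarms + correct_rejections
  if (n_sig == 0 || n_noise == 0)
    abort("need at least one signal and one noise trial",
          class = "surfdecode_degenerate")
  hr <- hits / n_sig
  far <- false_alarms / n_noise
  corrected <- hr %in% c(0, 1) || far %in% c(0, 1)
  if (corrected) {
    hr <- (hits + 0.5) / (n_sig + 1)
    far <- (false_alarms + 0.5) / (n_noise + 1)
  }
  zh <- qnorm(hr); zf <- qnorm(far)
  tibble(d_prime = zh - zf, hit_rate = hr, fa_rate = far,
         criterion = -(zh + zf) / 2, corrected = corrected)
}
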