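#' Fit a per-voxel GLM to one or more runs
#'
#' Ordinary least squares on HRF-convolved block regressors (one per
#' non-baseline condition, fitted to the runs concatenated in time) plus one
#' intercept per run, which absorbs run-level baseline differences. Fixation
#' (and air-off) blocks form the implicit baseline.
#'
#' @param runs an `sd_run` or list of `sd_run` sharing the same voxel grid.
#' @param hrf,hrf_delay response shape used to build the regressors, see
#'   [hrf_kernel()].
#' @return An object of class `sd_glm` with per-voxel coefficients
#'   (`betas`, voxels x regressors), residual variances (`sigma2`), the
#'   residual degrees of freedom (`dof`), and the design's
#'   \eqn{(X'X)^{-1}} for contrast t-maps.
#' @export
fit_glm <- function(runs, hrf = c("double_gamma", "delay"), hrf_delay = 4) {
  hrf <- match.arg(hrf)
  if (inherits(runs, "sd_run")) runs <- list(runs)
  if (!length(runs)) abort("no runs to fit")
  n_vox <- nrow(runs[[1]]$signal)
  if (!all(vapply(runs, function(r) nrow(r$signal) == n_vox, logical(1))))
    abort("runs do not share a voxel grid")

  conds <- unique(unlist(lapply(runs, function(r) {
    r$schedule$label[!is_baseline_label(r$schedule$label)]
  })))
  kernel <- hrf_kernel(runs[[1]]$tr, hrf, hrf_delay)

  blocks_x <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    nv <- ncol(r$signal)
    # regressors are built on the post-dummy timeline the data lives on
    reg <- build_regressors(r$schedule, kernel, n_dummy = 0L,
                            conditions = conds)[seq_len(nv), , drop = FALSE]
    ints <- matrix(0, nv, length(runs))
    ints[, i] <- 1
    blocks_x[[i]] <- cbind(reg, ints)
  }
  X <- do.call(rbind, blocks_x)
  run_ids <- vapply(seq_along(runs), function(i)
    as.character(runs[[i]]$run_id %||% i), character(1))
  colnames(X) <- make.unique(c(conds, paste0("run_", run_ids)))

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; collinear columns: ",
                 paste(dropped, collapse = ", ")),
          class = "surfdecode_design_error")
  }

  Y <- do.call(rbind, lapply(runs, function(r) t(r$signal)))
  xtx_inv <- solve(crossprod(X))
  B <- xtx_inv %*% crossprod(X, Y)                     # p x voxels
  res <- Y - X %*% B
  dof <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / dof
  structure(list(betas = t(B), sigma2 = sigma2, dof = dof,
                 xtx_inv = xtx_inv, terms = colnames(X),
                 conditions = conds, n_volumes = nrow(X),
                 n_runs = length(runs)),
            class = "sd_glm")
}

#' @export
print.sd_glm <- function(x, ...) {
  cat(sprintf("<voxelwise GLM> %d voxels, %d volumes, %d regressors (%s), dof %d\n",
              nrow(x$betas), x$n_volumes, length(x$terms),
              paste(x$conditions, collapse = "/"), x$dof))
  invisible(x)
}

#' Contrast t-map from a fitted GLM
#'
#' Computes t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c) per voxel. Two named
#' contrasts cover the pipeline's needs: `"task_vs_baseline"` weights every
#' condition regressor equally against the implicit fixation baseline, and
#' `"air"` is the air-on vs air-off localiser contrast. A named numeric
#' vector over regressor names may be given instead.
#'
#' @param glm an `sd_glm`.
#' @param contrast `"task_vs_baseline"`, `"air"`, or a named numeric vector.
#' @return A tibble with columns `voxel`, `estimate`, `t`; the residual
#'   degrees of freedom are stored in attribute `"dof"`.
#' @export
t_contrast <- function(glm, contrast = "task_vs_baseline") {
  stopifnot(inherits(glm, "sd_glm"))
  cvec <- setNames(numeric(length(glm$terms)), glm$terms)
  if (is.character(contrast) && length(contrast) == 1) {
    if (contrast == "task_vs_baseline") {
      cvec[glm$conditions] <- 1 / length(glm$conditions)
    } else if (contrast == "air") {
      if (!"AIR_ON" %in% glm$terms)
        abort("GLM has no AIR_ON regressor; fit it on a localiser run")
      cvec["AIR_ON"] <- 1
    } else {
      abort(paste0("unknown contrast '", contrast, "'"))
    }
  } else {
    if (is.null(names(contrast)) || !all(names(contrast) %in% glm$terms))
      abort("contrast weights must be named after design regressors")
    cvec[names(contrast)] <- contrast
  }
  est <- drop(glm$betas %*% cvec)
  qf <- drop(t(cvec) %*% glm$xtx_inv %*% cvec)
  t <- est / sqrt(glm$sigma2 * qf)
  out <- tibble(voxel = seq_along(est), estimate = est, t = t)
  attr(out, "dof") <- glm$dof
  out
}

#' Select voxels for decoding from a contrast t-map
#'
#' Two selection modes: `"top_positive"` keeps up to `n` voxels with t > 0,
#' ranked by descending t (the visual-area rule: if fewer than `n` voxels
#' have positive t, all of them are used); `"significant"` keeps voxels
#' passing a two-sided t-test at level `alpha`, then the top `n` by t (the
#' somatosensory rule for the air-on vs air-off contrast). Ties in t are
#' broken by voxel index, so selection is deterministic and invariant to
#' input ordering.
#'
#' @param tmap a tibble from [t_contrast()] (columns `voxel`, `t`; attribute
#'   `"dof"` needed for `"significant"` mode unless `dof` is given).
#' @param mode `"top_positive"` or `"significant"`.
#' @param n maximum voxels selected.
#' @param alpha two-sided significance level for `"significant"` mode.
#' @param roi_name label stored in the result.
#' @param dof residual degrees of freedom (defaults to the t-map attribute).
#' @return A tibble with columns `roi`, `rank`, `voxel`, `t`. Zero rows
#'   (with a warning) when no voxel satisfies the criterion.
#' @export
select_voxels <- function(tmap, mode = c("top_positive", "significant"),
                          n = 250, alpha = 0.05, roi_name = "ROI",
                          dof = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c("voxel", "t") %in% names(tmap)))
  tv <- tmap$t
  if (mode == "top_positive") {
    keep <- which(tv > 0)
  } else {
    dof <- dof %||% attr(tmap, "dof")
    if (is.null(dof)) abort("`dof` needed for significant-mode selection")
    p <- 2 * pt(-abs(tv), dof)
    keep <- which(p < alpha)
  }
  if (!length(keep)) {
    warn("no voxels satisfy the selection criterion; empty selection",
         class = "surfdecode_empty_selection")
    return(tibble(roi = character(), rank = integer(), voxel = integer(),
                  t = numeric()))
  }
  ord <- keep[order(-tv[keep], tmap$voxel[keep])]
  ord <- ord[seq_len(min(n, length(ord)))]
  tibble(roi = roi_name, rank = seq_along(ord),
         voxel = tmap$voxel[ord], t = tv[ord])
}
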