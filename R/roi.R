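#' Condition-level GLM across runs
#'
#' Fits one HRF-convolved regressor per condition (images and mapping
#' checkerboards; fixation periods form the implicit baseline), with per-run
#' intercept and linear-trend confounds, to the high-pass-filtered
#' concatenated runs. Provides the sufficient statistics for t contrasts.
#'
#' @param session A `"sim_session"` (or compatible list).
#' @param cutoff_hz High-pass cutoff in Hz.
#' @param collapse_images Model all image conditions as a single regressor?
#'   Used for the feedback localiser, which must not see the image labels:
#'   with collapsing, the fit is exactly invariant to any relabelling of the
#'   image trials.
#' @return Object of class `"condition_glm"` with coefficients, residual
#'   variances, and `(X'X)^{-1}`.
#' @export
fit_condition_glm <- function(session, cutoff_hz = 0.006,
                              collapse_images = FALSE) {
  design <- session$design
  conds <- c(if (collapse_images) "image" else image_conditions(design),
             design$mapping_conditions)
  drop_n <- design$n_discard_vols
  kernel <- canonical_hrf(design$tr_s)
  n_runs <- length(session$runs)
  task_blocks <- vector("list", n_runs)
  conf_blocks <- vector("list", n_runs)
  Y <- NULL
  all_cond <- character(0)
  for (r in seq_len(n_runs)) {
    y <- session$runs[[r]][, (drop_n + 1L):ncol(session$runs[[r]]), drop = FALSE]
    y <- highpass_and_detrend(y, design$tr_s, cutoff_hz, keep_mean = FALSE)
    n_vols <- ncol(y)
    ev <- session$events[session$events$run == r, , drop = FALSE]
    ev$onset_s <- ev$onset_s - drop_n * design$tr_s
    Xt <- matrix(0, n_vols, length(conds), dimnames = list(NULL, conds))
    Rtr <- trial_regressor_matrix(ev$onset_s, ev$duration_s, n_vols,
                                  design$tr_s, kernel)
    cond_of <- if (collapse_images) {
      ifelse(ev$trial_type == "image", "image", ev$condition)
    } else {
      ev$condition
    }
    for (k in seq_len(nrow(ev))) {
      Xt[, cond_of[k]] <- Xt[, cond_of[k]] + Rtr[, k]
    }
    all_cond <- c(all_cond, cond_of)
    tt <- seq_len(n_vols)
    # filter the task regressors with the data (unbiased condition betas)
    task_blocks[[r]] <- t(highpass_and_detrend(t(Xt), design$tr_s, cutoff_hz,
                                               keep_mean = FALSE))
    conf_blocks[[r]] <- cbind(1, tt - mean(tt))
    Y <- cbind(Y, y)
  }
  # shared condition columns; run-specific confound columns
  conf <- matrix(0, sum(vapply(conf_blocks, nrow, 1L)), 2L * n_runs)
  off <- 0L
  for (r in seq_len(n_runs)) {
    nr <- nrow(conf_blocks[[r]])
    conf[off + seq_len(nr), 2L * r - 1:0] <- conf_blocks[[r]]
    off <- off + nr
  }
  X <- cbind(do.call(rbind, task_blocks), conf)
  colnames(X) <- c(conds, paste0(rep(c("intercept", "trend"), n_runs),
                                 rep(seq_len(n_runs), each = 2)))
  dec <- qr(X)
  if (dec$rank < ncol(X)) stop("condition design is rank deficient", call. = FALSE)
  coefs <- qr.coef(dec, t(Y))                       # regressor x voxel
  res <- t(Y) - X %*% coefs
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  structure(list(
    coefs = coefs, sigma2 = sigma2, xtx_inv = chol2inv(chol(crossprod(X))),
    regressors = colnames(X), conditions = conds, df = df,
    n_trials = table(all_cond)
  ), class = "condition_glm")
}

#' Per-voxel t statistic for a condition contrast
#'
#' `t = c'beta / sqrt(sigma^2 c'(X'X)^{-1} c)` under OLS, for the contrast
#' `condA - condB`, or `condA` against the fixation baseline when `condB` is
#' `NULL`.
#'
#' @param fit A [fit_condition_glm()] object.
#' @param condA,condB Condition labels; `condB = NULL` contrasts against
#'   baseline.
#' @return Numeric vector of t statistics, one per voxel.
#' @export
contrast_t <- function(fit, condA, condB = NULL) {
  stopifnot(inherits(fit, "condition_glm"))
  for (cond in c(condA, condB)) {
    if (!cond %in% fit$conditions) {
      stop("condition '", cond, "' not in the fitted model", call. = FALSE)
    }
    if (is.na(fit$n_trials[cond]) || fit$n_trials[cond] < 2) {
      stop("condition '", cond, "' has fewer than 2 trials", call. = FALSE)
    }
  }
  cvec <- numeric(length(fit$regressors))
  names(cvec) <- fit$regressors
  cvec[condA] <- 1
  if (!is.null(condB)) cvec[condB] <- -1
  est <- drop(crossprod(cvec, fit$coefs))
  se <- sqrt(fit$sigma2 * drop(crossprod(cvec, fit$xtx_inv %*% cvec)))
  est / se
}

roi_mask <- function(voxels, source_contrast, threshold) {
  structure(list(voxels = sort(unique(as.integer(voxels))),
                 source_contrast = source_contrast,
                 threshold = threshold,
                 n_voxels = length(unique(voxels))),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d voxels  [%s, t > %s]\n",
              x$n_voxels, x$source_contrast, format(x$threshold)))
  invisible(x)
}

#' Select the non-stimulated (feedback) region of interest
#'
#' Voxels whose response to the `target` checkerboard exceeds the near
#' surround (`surround1`) at `t > threshold`, excluding voxels responsive to
#' either surround checkerboard versus baseline at the same threshold (to
#' minimise lateral spillover from stimulated cortex).
#'
#' @param fit A [fit_condition_glm()] object (mapping conditions fitted).
#' @param threshold t-statistic threshold (uncorrected).
#' @return A `"roi_mask"`; warns if empty (decoding will then error).
#' @export
select_feedback_roi <- function(fit, threshold = 3) {
  t_target <- contrast_t(fit, "target", "surround1")
  t_s1 <- contrast_t(fit, "surround1")
  t_s2 <- contrast_t(fit, "surround2")
  keep <- which(t_target > threshold & t_s1 <= threshold & t_s2 <= threshold)
  if (length(keep) == 0) {
    warning("feedback ROI selection is empty at t > ", threshold, call. = FALSE)
  }
  roi_mask(keep, "target > surround1, surround-responsive excluded", threshold)
}

#' Select the stimulated (feedforward+) region of interest
#'
#' Conjunction across all image conditions: a voxel is included iff its
#' response versus the fixation baseline exceeds `threshold` for every one of
#' the six image conditions.
#'
#' @inheritParams select_feedback_roi
#' @param conditions Image condition labels (defaults to all six).
#' @return A `"roi_mask"`; warns if empty.
#' @export
select_feedforward_roi <- function(fit, threshold = 3,
                                   conditions = grep("^img", fit$conditions,
                                                     value = TRUE)) {
  if (length(conditions) == 0) stop("no image conditions fitted", call. = FALSE)
  tmat <- vapply(conditions, function(cond) contrast_t(fit, cond),
                 numeric(length(fit$sigma2)))
  keep <- which(apply(tmat > threshold, 1, all))
  if (length(keep) == 0) {
    warning("feedforward ROI selection is empty at t > ", threshold, call. = FALSE)
  }
  roi_mask(keep, sprintf("conjunction over %d image conditions vs baseline",
                         length(conditions)), threshold)
}

#' Ground-truth ROI masks of a simulated session
#'
#' @param session A `"sim_session"`.
#' @return List with `feedback` and `feedforward` `"roi_mask"` objects taken
#'   from the generator's layout.
#' @export
truth_roi_masks <- function(session) {
  list(feedback = roi_mask(session$rois$feedback, "ground truth", NA_real_),
       feedforward = roi_mask(session$rois$feedforward, "ground truth", NA_real_))
}

#' Estimate both ROIs from the mapping/localiser responses
#'
#' @param session A `"sim_session"`.
#' @param threshold t threshold for both selections.
#' @param cutoff_hz High-pass cutoff for the condition GLM.
#' @return List with `feedback` and `feedforward` masks.
#' @export
select_rois <- function(session, threshold = 3, cutoff_hz = 0.006) {
  # feedback localiser: image conditions collapsed, so the mask cannot be
  # influenced by the decoding labels
  fit_map <- fit_condition_glm(session, cutoff_hz, collapse_images = TRUE)
  fit_img <- fit_condition_glm(session, cutoff_hz)
  list(feedback = select_feedback_roi(fit_map, threshold),
       feedforward = select_feedforward_roi(fit_img, threshold))
}
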