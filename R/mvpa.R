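#' Train a linear support vector machine on trial patterns
#'
#' Features are z-scored with statistics computed on the training data only;
#' the stored statistics are re-applied to any test data so no test
#' information leaks into training. Ties at the decision boundary are broken
#' deterministically towards the first class level.
#'
#' @param x Trial-by-voxel numeric matrix.
#' @param y Class labels (two classes; coerced to factor).
#' @param cost SVM regularisation parameter C.
#' @param zscore Z-score features using training statistics?
#' @return Object of class `"linear_svm"` with the fitted model, the scaling
#'   statistics, and the class levels.
#' @export
train_linear_svm <- function(x, y, cost = 1, zscore = TRUE) {
  y <- factor(y)
  if (nlevels(y) < 2) stop("training data contain a single class", call. = FALSE)
  if (ncol(x) < 1) stop("no features (empty ROI?)", call. = FALSE)
  if (zscore) {
    center <- colMeans(x)
    scale_ <- apply(x, 2, stats::sd)
    scale_[scale_ < 1e-12] <- 1
    x <- sweep(sweep(x, 2, center), 2, scale_, "/")
  } else {
    center <- rep(0, ncol(x))
    scale_ <- rep(1, ncol(x))
  }
  fit <- e1071::svm(x = x, y = y, kernel = "linear", cost = cost,
                    scale = FALSE, type = "C-classification")
  structure(list(fit = fit, center = center, scale = scale_,
                 levels = levels(y)), class = "linear_svm")
}

#' Decision values and class predictions of a linear SVM
#'
#' @param object A `"linear_svm"`.
#' @param newdata Trial-by-voxel matrix.
#' @param ... Unused.
#' @return List with `decision` (signed distance, positive for the first
#'   class level) and `class` (predicted labels; exact zeros go to the first
#'   level).
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  z <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  dv <- attr(stats::predict(object$fit, z, decision.values = TRUE),
             "decision.values")
  # e1071 orients decision values positive for the level named first in
  # the "A/B" column header
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  d <- unname(drop(dv))
  if (first != object$levels[1]) d <- -d
  cls <- ifelse(d >= 0, object$levels[1], object$levels[2])
  list(decision = d, class = unname(cls))
}

#' Hyperplane weights of a linear SVM (in z-scored feature space)
#'
#' @param object A `"linear_svm"`.
#' @return List with `w` and `b` such that the decision value is `w'x + b`,
#'   positive for the first class level.
#' @export
svm_hyperplane <- function(object) {
  stopifnot(inherits(object, "linear_svm"))
  w <- drop(crossprod(object$fit$coefs, object$fit$SV))
  b <- -object$fit$rho
  # orient towards the first level (same convention as predict.linear_svm)
  probe <- matrix(0, 1, length(w))
  colnames(probe) <- colnames(object$fit$SV)
  dv <- attr(stats::predict(object$fit, probe, decision.values = TRUE),
             "decision.values")
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  if (first != object$levels[1]) {
    w <- -w; b <- -b
  }
  list(w = w, b = b)
}

# --- internal helpers for decoding -----------------------------------------

image_trial_betas <- function(tb, roi) {
  stopifnot(inherits(tb, "trial_betas"), inherits(roi, "roi_mask"))
  if (roi$n_voxels == 0) {
    stop("cannot decode from an empty ROI (", roi$source_contrast, ")",
         call. = FALSE)
  }
  keep <- tb$labels$trial_type == "image"
  list(x = tb$betas[keep, roi$voxels, drop = FALSE],
       labels = tb$labels[keep, , drop = FALSE])
}

# accuracy of a trained model on test patterns; mode "ST" scores each trial,
# "AB" averages patterns per image within the held-out run first
score_fold <- function(model, x_test, img_test, mode) {
  if (mode == "AB") {
    imgs <- sort(unique(img_test))
    x_test <- t(vapply(imgs, function(i) {
      colMeans(x_test[img_test == i, , drop = FALSE])
    }, numeric(ncol(x_test))))
    img_test <- imgs
  }
  pred <- predict.linear_svm(model, x_test)$class
  c(accuracy = mean(pred == as.character(img_test)), n_test = length(img_test))
}

#' Leave-one-run-out (cross-)classification for one decoding specification
#'
#' Per fold, the classifier is trained on the `train_shift` trials of the
#' remaining runs (single-trial patterns, both images) and tested on the
#' `test_shift` trials of the held-out run. Mode `"ST"` scores every test
#' trial; mode `"AB"` first averages the held-out run's patterns per image.
#' When `train_shift != test_shift` the fold accuracy is the mean over both
#' train/test directions, so each delta is summarised by a single number.
#'
#' @param tb A `"trial_betas"` object (all runs).
#' @param roi A `"roi_mask"`.
#' @param train_shift,test_shift Shifts in degrees (must exist in the data).
#' @param mode `"ST"` (single trial) or `"AB"` (average block).
#' @param cost SVM cost.
#' @param average_directions Average the two train/test directions for
#'   cross-shift specifications?
#' @return Object of class `"decoding_result"`: list with `spec` and a
#'   data.frame `folds` (`fold`, `accuracy`, `n_test`).
#' @export
loro_crossclassify <- function(tb, roi, train_shift, test_shift,
                               mode = c("ST", "AB"), cost = 1,
                               average_directions = TRUE) {
  mode <- match.arg(mode)
  dat <- image_trial_betas(tb, roi)
  shifts <- unique(dat$labels$shift_deg)
  for (s in c(train_shift, test_shift)) {
    if (!any(abs(shifts - s) < 1e-9)) {
      stop("shift ", s, " deg not present in the session", call. = FALSE)
    }
  }
  runs <- sort(unique(dat$labels$run))
  directions <- if (abs(train_shift - test_shift) < 1e-9 || !average_directions) {
    list(c(train_shift, test_shift))
  } else {
    list(c(train_shift, test_shift), c(test_shift, train_shift))
  }
  folds <- lapply(runs, function(r) {
    acc <- 0; n <- 0
    for (d in directions) {
      tr <- dat$labels$run != r & abs(dat$labels$shift_deg - d[1]) < 1e-9
      te <- dat$labels$run == r & abs(dat$labels$shift_deg - d[2]) < 1e-9
      if (!any(tr) || !any(te)) {
        stop("no trials for fold with held-out run ", r, call. = FALSE)
      }
      model <- train_linear_svm(dat$x[tr, , drop = FALSE],
                                dat$labels$image[tr], cost = cost)
      sc <- score_fold(model, dat$x[te, , drop = FALSE],
                       dat$labels$image[te], mode)
      acc <- acc + sc[["accuracy"]]; n <- n + sc[["n_test"]]
    }
    c(accuracy = acc / length(directions), n_test = n)
  })
  folds <- as.data.frame(do.call(rbind, folds))
  folds$fold <- runs
  structure(list(
    spec = list(train_shift = train_shift, test_shift = test_shift,
                delta = abs(train_shift - test_shift), mode = mode,
                roi = roi$source_contrast),
    folds = folds[, c("fold", "accuracy", "n_test")]
  ), class = "decoding_result")
}

#' Full decoding profile of one subject across shifts, modes and ROIs
#'
#' Computes, for each ROI and test mode, within-shift cross-validated
#' decoding for every shift level (`kind = "within"`) and cross-shift
#' decoding for every pair of shifts (`kind = "cross"`, fold accuracies
#' averaged over both directions). Trained models are shared across the
#' conditions that reuse them. The delta reported for group analysis is 0
#' for the within-decoding of the unshifted condition and `|s1 - s2|` for
#' cross pairs; within-decoding of shifted conditions is retained with
#' `kind = "within"` for quality control.
#'
#' @param tb A `"trial_betas"` object.
#' @param rois Named list of `"roi_mask"` objects (e.g. `feedback`,
#'   `feedforward`).
#' @param design The session's [experiment_design()].
#' @param modes Test modes to evaluate.
#' @param cost SVM cost.
#' @return Data.frame with columns `roi`, `mode`, `kind`, `train_shift`,
#'   `test_shift`, `delta`, `fold`, `accuracy`, `n_test`.
#' @export
shift_profile <- function(tb, rois, design, modes = c("ST", "AB"), cost = 1) {
  stopifnot(length(rois) >= 1, !is.null(names(rois)))
  shifts <- design$shift_levels_deg
  out <- list()
  for (roi_name in names(rois)) {
    roi <- rois[[roi_name]]
    dat <- image_trial_betas(tb, roi)
    runs <- sort(unique(dat$labels$run))
    # cache one model per (fold, train_shift)
    for (r in runs) {
      models <- lapply(shifts, function(s) {
        tr <- dat$labels$run != r & abs(dat$labels$shift_deg - s) < 1e-9
        train_linear_svm(dat$x[tr, , drop = FALSE], dat$labels$image[tr],
                         cost = cost)
      })
      names(models) <- paste0("s", shifts)
      score <- function(train_s, test_s, mode) {
        te <- dat$labels$run == r & abs(dat$labels$shift_deg - test_s) < 1e-9
        score_fold(models[[paste0("s", train_s)]],
                   dat$x[te, , drop = FALSE], dat$labels$image[te], mode)
      }
      for (mode in modes) {
        for (s in shifts) {
          sc <- score(s, s, mode)
          out[[length(out) + 1L]] <- data.frame(
            roi = roi_name, mode = mode, kind = "within",
            train_shift = s, test_shift = s, delta = 0,
            fold = r, accuracy = sc[["accuracy"]], n_test = sc[["n_test"]])
        }
        pairs <- utils::combn(shifts, 2)
        for (k in seq_len(ncol(pairs))) {
          s1 <- pairs[1, k]; s2 <- pairs[2, k]
          a <- score(s1, s2, mode); b <- score(s2, s1, mode)
          out[[length(out) + 1L]] <- data.frame(
            roi = roi_name, mode = mode, kind = "cross",
            train_shift = s1, test_shift = s2, delta = abs(s2 - s1),
            fold = r, accuracy = (a[["accuracy"]] + b[["accuracy"]]) / 2,
            n_test = a[["n_test"]] + b[["n_test"]])
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Reported delta of each profile row
#'
#' The delta used in the group tables: 0 for within-decoding of the
#' unshifted condition, `|s1 - s2|` for cross pairs, and `NA` for the
#' within-decoding of shifted conditions (retained for QC only).
#'
#' @param profile A [shift_profile()] data.frame.
#' @return Numeric vector aligned with the rows of `profile`.
#' @export
reported_delta <- function(profile) {
  ifelse(profile$kind == "cross", profile$delta,
         ifelse(profile$train_shift == 0, 0, NA_real_))
}
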