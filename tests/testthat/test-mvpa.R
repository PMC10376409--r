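test_that("a separable two-point problem is classified perfectly", {
  x <- rbind(c(0, 0), c(1, 1))
  m <- train_linear_svm(x, c("1", "2"), zscore = FALSE)
  p <- predict(m, x)
  expect_identical(p$class, c("1", "2"))
  expect_error(train_linear_svm(x, c("1", "1")), "single class")
})

test_that("linear SVM matches a brute-force maximum-margin oracle on small 2-D sets", {
  set.seed(7)
  for (rep in 1:8) {
    n <- sample(4:8, 1)
    y <- c("1", "2")[c(1, 2, sample(1:2, n - 2, replace = TRUE))]
    repeat {
      x <- matrix(rnorm(2 * n), n, 2)
      x[y == "2", 1] <- x[y == "2", 1] + 4   # separable by construction
      if (length(unique(y)) == 2) break
    }
    oracle <- brute_force_margin(x, y)
    m <- train_linear_svm(x, y, cost = 1e8, zscore = FALSE)
    # identical decisions on the training points and on random probes
    probes <- matrix(rnorm(40), 20, 2) * 2 + 2
    expect_identical(predict(m, x)$class, oracle$classify(x))
    expect_identical(predict(m, probes)$class, oracle$classify(probes))
    # identical geometric margin: 1 / ||w|| for the canonical SVM hyperplane
    hp <- svm_hyperplane(m)
    expect_equal(1 / sqrt(sum(hp$w^2)), oracle$margin, tolerance = 1e-3)
  }
})

test_that("decision-boundary ties go to the first class deterministically", {
  x <- rbind(c(-1, 0), c(1, 0))
  m <- train_linear_svm(x, c("1", "2"), zscore = FALSE)
  p <- predict(m, rbind(c(0, 0)))
  expect_identical(p$class, "1")
  expect_equal(p$decision, 0, tolerance = 1e-10)
})

test_that("z-scoring uses training statistics only (leakage canary)", {
  set.seed(11)
  xtr <- matrix(rnorm(40 * 10), 40, 10)
  ytr <- rep(c(1, 2), 20)
  m <- train_linear_svm(xtr, ytr)
  base <- predict(m, xtr)$class
  # a wild test-only artifact cannot change the trained model or its
  # decisions on the training data
  xte <- matrix(rnorm(10 * 10, mean = 50, sd = 100), 10, 10)
  invisible(predict(m, xte))
  expect_identical(predict(m, xtr)$class, base)
  # and the scaling applied to test data is the training scaling
  expect_equal(m$center, colMeans(xtr))
})

test_that("cross-classification is perfect in the separable limit and chance without tuning", {
  # high snr, no noise: delta 0 decodes perfectly
  s_hi <- small_session(seed = 61, snr = 1,
                        noise = noise_model(0, 0.001, 0, 0))
  tb_hi <- estimate_trial_betas(s_hi)
  r0 <- loro_crossclassify(tb_hi, truth_roi_masks(s_hi)$feedback, 0, 0, "ST")
  expect_equal(mean(r0$folds$accuracy), 1)
  # sigma -> 0: shifted patterns share nothing; cross-decoding is at chance
  accs <- vapply(1:6, function(i) {
    s <- small_session(seed = 200 + i, snr = 1, sigma_deg = 1e-6,
                       noise = noise_model(0, 0.05, 0, 0))
    tb <- estimate_trial_betas(s)
    mean(loro_crossclassify(tb, truth_roi_masks(s)$feedback, 0, 8, "ST")$folds$accuracy)
  }, 1)
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("label shuffling drives accuracy to chance", {
  s <- small_session(seed = 62, snr = 0.05)
  tb <- estimate_trial_betas(s)
  roi <- truth_roi_masks(s)$feedback
  set.seed(3)
  accs <- vapply(1:40, function(i) {
    tb2 <- tb
    img <- tb2$labels$trial_type == "image"
    for (r in unique(tb2$labels$run)) {
      rows <- which(img & tb2$labels$run == r)
      tb2$labels$image[rows] <- sample(tb2$labels$image[rows])
    }
    mean(loro_crossclassify(tb2, roi, 0, 0, "ST")$folds$accuracy)
  }, 1)
  expect_gt(mean(accs), 0.45)
  expect_lt(mean(accs), 0.55)
})

test_that("averaged-block testing is at least as accurate as single-trial on average", {
  diffs <- vapply(1:6, function(i) {
    s <- small_session(seed = 300 + i, snr = 0.012)
    tb <- estimate_trial_betas(s)
    pr <- shift_profile(tb, truth_roi_masks(s)["feedback"], s$design)
    ab <- pr$accuracy[pr$mode == "AB" & pr$kind == "within" & pr$train_shift == 0]
    st <- pr$accuracy[pr$mode == "ST" & pr$kind == "within" & pr$train_shift == 0]
    mean(ab) - mean(st)
  }, 1)
  expect_gte(mean(diffs), 0)
})

test_that("mean accuracy decreases with shift delta under Gaussian tuning", {
  prof <- lapply(1:10, function(i) {
    s <- small_session(seed = 400 + i, snr = 0.03)
    tb <- estimate_trial_betas(s)
    pr <- shift_profile(tb, truth_roi_masks(s)["feedback"], s$design,
                        modes = "ST")
    pr$rep_delta <- reported_delta(pr)
    aggregate(accuracy ~ rep_delta, pr[!is.na(pr$rep_delta), ], mean)
  })
  tab <- do.call(rbind, prof)
  means <- tapply(tab$accuracy, tab$rep_delta, mean)
  # non-increasing up to Monte-Carlo noise at the near-chance tail
  expect_true(all(diff(means[order(as.numeric(names(means)))]) <= 0.03))
  expect_gt(means[["0"]], means[["8"]])
})

test_that("shift profiles cover exactly the deltas implied by the shift set", {
  s <- small_session(seed = 63, shifts = c(0, 3, 7))
  tb <- estimate_trial_betas(s)
  pr <- shift_profile(tb, truth_roi_masks(s), s$design)
  expect_setequal(unique(pr$delta[pr$kind == "cross"]), c(3, 4, 7))
  expect_setequal(na.omit(unique(reported_delta(pr))), c(0, 3, 4, 7))
  expect_setequal(unique(pr$roi), c("feedback", "feedforward"))
  expect_true(all(pr$accuracy >= 0 & pr$accuracy <= 1))
  expect_identical(max(pr$fold), 4L)

  empty <- structure(list(voxels = integer(0), source_contrast = "x",
                          threshold = 3, n_voxels = 0L), class = "roi_mask")
  expect_error(loro_crossclassify(tb, empty, 0, 0, "ST"), "empty ROI")
  expect_error(loro_crossclassify(tb, truth_roi_masks(s)$feedback, 0, 5, "ST"),
               "not present")
})
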