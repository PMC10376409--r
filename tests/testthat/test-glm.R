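test_that("the canonical HRF has the expected shape", {
  h <- canonical_hrf(tr_s = 1)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  expect_true(any(h < 0))                        # undershoot
  # dense-grid oracle for the peak location
  tt <- seq(0, 32, by = 0.01)
  dense <- dgamma(tt, shape = 7, rate = 1) - dgamma(tt, shape = 17, rate = 1) / 6
  expect_equal(tt[which.max(dense)], 6, tolerance = 0.05)
  expect_equal(which.max(h) - 1, 6)
  expect_gte(length(h), 30)
  # convolving a 12 s boxcar yields a response outlasting the boxcar
  box <- c(rep(1, 12), rep(0, 48))
  conv <- stats::convolve(box, rev(h), type = "open")[1:60]
  expect_gt(sum(conv > 0.1 * max(conv)), 12)
  expect_error(canonical_hrf(0), "positive")
})

test_that("high-pass filtering removes trends and keeps passband signal", {
  n <- 768
  ramp <- matrix(seq_len(n), nrow = 1)
  out <- highpass_and_detrend(ramp, 1, 0.006, keep_mean = FALSE)
  expect_lt(max(abs(out)), 1e-8)

  const <- matrix(5, 1, n)
  expect_equal(highpass_and_detrend(const, 1, 0.006, keep_mean = TRUE),
               const)

  # FFT amplitude oracle: 0.05 Hz sinusoid retains > 95% amplitude
  sig <- sin(2 * pi * 0.05 * seq_len(n))
  filt <- drop(highpass_and_detrend(matrix(sig, 1), 1, 0.006))
  amp_in <- max(Mod(fft(sig)[2:(n / 2)]))
  amp_out <- max(Mod(fft(filt - mean(filt))[2:(n / 2)]))
  expect_gt(amp_out / amp_in, 0.95)
  # a very slow sinusoid (below cutoff) is strongly attenuated
  slow <- sin(2 * pi * 0.002 * seq_len(n))
  filt_slow <- drop(highpass_and_detrend(matrix(slow, 1), 1, 0.006,
                                         keep_mean = FALSE))
  expect_lt(sd(filt_slow) / sd(slow), 0.25)

  expect_error(highpass_and_detrend(matrix(sig, 1), 1, cutoff_hz = 0.6),
               "Nyquist")
  expect_error(highpass_and_detrend(matrix(1, 1, 1), 1), ">= 2")
})

test_that("single-trial designs have one task regressor per trial", {
  s <- simulate_session(seed = 21)   # default design: 36 image + 18 mapping
  ev <- s$events[s$events$run == 1, ]
  ev$onset_s <- ev$onset_s - s$design$n_discard_vols * s$design$tr_s
  dm <- build_single_trial_design(ev, s$design$n_vols - 2L, s$design$tr_s)
  expect_length(dm$task_cols, 54L)
  expect_gte(sum(grepl("img", colnames(dm$X))), 36L)
  expect_true(all(c("intercept", "trend") %in% colnames(dm$X)))
  # column peak lags trial onset by at least the HRF peak delay and at most
  # the block duration plus the HRF delay
  k <- 5
  peak_t <- which.max(dm$X[, k]) - 1
  expect_gte(peak_t, ev$onset_s[k] + 6)
  expect_lte(peak_t, ev$onset_s[k] + 12 + 6)

  empty <- build_single_trial_design(ev[0, ], 100, 1)
  expect_length(empty$task_cols, 0L)
  expect_identical(ncol(empty$X), 2L)

  ev2 <- ev[1:2, ]; ev2$onset_s <- c(10, 10)
  expect_error(build_single_trial_design(ev2, 700, 1), "overlap")
  ev3 <- ev[1, ]; ev3$onset_s <- 1e5
  expect_error(build_single_trial_design(ev3, 700, 1), "bounds")
})

test_that("beta estimation recovers noiseless amplitudes and ignores drift", {
  d <- small_design()
  lay <- small_layout(map_amp = 2, surround_mean = 0.5, ff_mean = 1.5)
  s <- simulate_session(design = d, tuning = tuning_model(2.4, 0.3),
                        noise = noise_model(0, 0, 0, 0), seed = 31, layout = lay)
  tb <- estimate_trial_betas(s)
  # feedforward voxel amplitudes: ff_mean + snr * pattern, exactly
  v <- lay$feedforward[3]
  img <- tb$labels$trial_type == "image"
  truth <- vapply(which(img), function(k) {
    i <- tb$labels$image[k]
    sh <- paste0("s", tb$labels$shift_deg[k])
    1.5 + 0.3 * s$truth$patterns$feedforward[i, sh, 3]
  }, 1)
  expect_equal(unname(tb$betas[img, v]), truth, tolerance = 1e-6)

  # pure linear drift is absorbed by the confounds
  s2 <- s
  drift <- outer(rep(1, nrow(s$runs[[1]])), seq_len(ncol(s$runs[[1]]))) * 0.05
  s2$runs <- lapply(s$runs, function(r) r + drift)
  tb2 <- estimate_trial_betas(s2)
  expect_equal(tb$betas, tb2$betas, tolerance = 1e-6)
})

test_that("OLS residuals are orthogonal to the design and rank errors are named", {
  ev <- data.frame(onset_s = c(10, 40), duration_s = 12,
                   condition = c("a", "b"), run = 1)
  dm <- build_single_trial_design(ev, 80, 1)
  set.seed(1)
  ts <- matrix(rnorm(3 * 80), 3, 80)
  tb <- estimate_betas(ts, dm)
  coefs <- qr.coef(qr(dm$X), t(ts))
  resid <- t(ts) - dm$X %*% coefs
  expect_lt(max(abs(crossprod(dm$X, resid))), 1e-8)

  # time series orthogonal to all regressors -> betas ~ 0
  Q <- qr.Q(qr(dm$X))
  orth <- ts - ts %*% Q %*% t(Q)
  expect_lt(max(abs(estimate_betas(orth, dm)$betas)), 1e-8)

  dup <- dm
  dup$X <- cbind(dm$X, dm$X[, 1])
  colnames(dup$X)[ncol(dup$X)] <- "copy_of_trial1"
  expect_error(estimate_betas(ts, dup), "copy_of_trial1")
})

test_that("filter-then-fit equals modelling the filter basis (projection commutation)", {
  s <- small_session(seed = 41)
  d <- s$design
  # route 1: the package path (data and task regressors filtered)
  tb1 <- estimate_trial_betas(s)
  # route 2 (oracle): no filtering; the filter's nuisance space (intercept,
  # trend, cosine basis) enters the GLM as confound regressors
  out <- NULL
  for (r in seq_along(s$runs)) {
    y <- s$runs[[r]][, 3:d$n_vols, drop = FALSE]
    ev <- s$events[s$events$run == r, ]
    ev$onset_s <- ev$onset_s - 2
    n <- ncol(y)
    dm <- build_single_trial_design(ev, n, d$tr_s)
    dct <- shiftdecode:::dct_basis(n, d$tr_s, 0.006)
    X <- cbind(dm$X, dct)
    colnames(X) <- c(colnames(dm$X), paste0("dct", seq_len(ncol(dct))))
    coefs <- qr.coef(qr(X), t(y))
    out <- rbind(out, coefs[dm$task_cols, , drop = FALSE])
  }
  expect_equal(unname(tb1$betas), unname(out), tolerance = 1e-8)
})

test_that("beta recovery error decreases monotonically with snr", {
  maes <- vapply(c(0.005, 0.02, 0.08), function(snr) {
    errs <- vapply(1:2, function(i) {
      s <- small_session(seed = 100 + i, snr = snr)
      tb <- estimate_trial_betas(s)
      img <- tb$labels$trial_type == "image"
      fb <- s$rois$feedback
      truth <- t(vapply(which(img), function(k) {
        i2 <- tb$labels$image[k]
        sh <- paste0("s", tb$labels$shift_deg[k])
        snr * s$truth$patterns$feedback[i2, sh, ]
      }, numeric(length(fb))))
      # relative error of the recovered pattern amplitudes
      mean(abs(tb$betas[img, fb] - truth)) / snr
    }, 1)
    mean(errs)
  }, 1)
  expect_true(all(diff(maes) < 0))
})
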