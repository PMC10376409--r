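#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities with the response peaking at
#' `peak_s` seconds and the undershoot at `undershoot_s` seconds
#' (gamma shape = peak + 1, rate = 1, so the mode sits at the peak),
#' normalised to a maximum of 1.
#'
#' @param tr_s Sampling interval in seconds (> 0).
#' @param duration_s Kernel support in seconds (>= 30 recommended).
#' @param peak_s,undershoot_s,ratio Shape parameters: response peak time,
#'   undershoot peak time, and peak-to-undershoot amplitude ratio.
#' @return Numeric kernel sampled at `0, tr_s, 2 tr_s, ...`; value 0 at t = 0.
#' @export
canonical_hrf <- function(tr_s, duration_s = 32, peak_s = 6,
                          undershoot_s = 16, ratio = 6) {
  if (tr_s <= 0) stop("'tr_s' must be positive", call. = FALSE)
  t <- seq(0, duration_s, by = tr_s)
  h <- stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    stats::dgamma(t, shape = undershoot_s + 1, rate = 1) / ratio
  h / max(h)
}

# Discrete cosine high-pass basis: component k has frequency k / (2 T tr)
# Hz; all components strictly below the cutoff are included.
dct_basis <- function(n, tr_s, cutoff_hz) {
  K <- floor(2 * n * tr_s * cutoff_hz)
  t <- seq_len(n) - 0.5
  if (K < 1) return(matrix(numeric(0), n, 0))
  vapply(seq_len(K), function(k) cos(pi * k * t / n), numeric(n))
}

#' Temporal high-pass filtering and linear-trend removal
#'
#' Projects each voxel time series onto the complement of a nuisance space
#' spanned by an intercept, a linear trend and a discrete-cosine basis of all
#' frequencies below `cutoff_hz`. With `keep_mean = TRUE` the voxel mean is
#' added back after filtering.
#'
#' @param ts Voxel-by-time numeric matrix (a plain vector is treated as one
#'   voxel).
#' @param tr_s Sampling interval (seconds).
#' @param cutoff_hz High-pass cutoff frequency in Hz.
#' @param keep_mean Re-add the voxel mean after projection?
#' @return Filtered matrix of the same shape.
#' @export
highpass_and_detrend <- function(ts, tr_s = 1, cutoff_hz = 0.006,
                                 keep_mean = TRUE) {
  if (is.vector(ts)) ts <- matrix(ts, nrow = 1)
  n <- ncol(ts)
  if (n < 2) stop("time axis must have >= 2 samples", call. = FALSE)
  if (cutoff_hz >= 1 / (2 * tr_s)) {
    stop("'cutoff_hz' must be below the Nyquist frequency", call. = FALSE)
  }
  tt <- seq_len(n)
  nuis <- cbind(1, tt - mean(tt), dct_basis(n, tr_s, cutoff_hz))
  Q <- qr.Q(qr(nuis))
  out <- ts - (ts %*% Q) %*% t(Q)
  if (keep_mean) out <- out + rowMeans(ts)
  out
}

#' Single-trial design matrix
#'
#' One HRF-convolved boxcar regressor per trial (image and mapping trials
#' alike), plus a confound block of an intercept and a linear trend.
#'
#' @param events Event table for one run: columns `onset_s`, `duration_s`,
#'   `condition`, and optionally `trial_type` and `run`.
#' @param n_vols Number of volumes in the run.
#' @param tr_s Repetition time (seconds).
#' @param hrf HRF kernel sampled at `tr_s` (default [canonical_hrf()]).
#' @return Object of class `"design_matrix"`: list with `X` (time x
#'   regressor), `labels` (one row per task regressor), `task_cols`,
#'   `confound_cols`, `tr_s`.
#' @export
build_single_trial_design <- function(events, n_vols, tr_s,
                                      hrf = canonical_hrf(tr_s)) {
  if (nrow(events) > 0) {
    if (any(events$onset_s < 0) ||
        any(events$onset_s + events$duration_s > n_vols * tr_s + 1e-9)) {
      stop("events fall outside the run bounds", call. = FALSE)
    }
    check_no_overlap(cbind(events,
                           run = if (is.null(events$run)) 1L else events$run)[,
                     c("run", "onset_s", "duration_s"), drop = FALSE])
  }
  n_trials <- nrow(events)
  Xtask <- if (n_trials > 0) {
    trial_regressor_matrix(events$onset_s, events$duration_s, n_vols, tr_s, hrf)
  } else {
    matrix(numeric(0), n_vols, 0)
  }
  tt <- seq_len(n_vols)
  Xconf <- cbind(intercept = rep(1, n_vols), trend = tt - mean(tt))
  task_names <- if (n_trials > 0) {
    sprintf("trial%03d_%s", seq_len(n_trials), events$condition)
  } else character(0)
  X <- cbind(Xtask, Xconf)
  colnames(X) <- c(task_names, "intercept", "trend")
  structure(list(
    X = X,
    labels = events,
    task_cols = seq_len(n_trials),
    confound_cols = n_trials + 1:2,
    tr_s = tr_s
  ), class = "design_matrix")
}

#' Ordinary-least-squares single-trial beta estimation
#'
#' Fits the design to every voxel time course at once and returns the task
#' (per-trial) coefficients. Errors on rank-deficient designs, naming the
#' collinear columns.
#'
#' @param ts Voxel-by-time matrix whose column count matches the design rows.
#' @param design A [build_single_trial_design()] object.
#' @return Object of class `"trial_betas"`: list with `betas` (trial x
#'   voxel) and `labels` (one row per trial: run, condition, ...).
#' @export
estimate_betas <- function(ts, design) {
  stopifnot(inherits(design, "design_matrix"))
  if (is.vector(ts)) ts <- matrix(ts, nrow = 1)
  X <- design$X
  if (ncol(ts) != nrow(X)) {
    stop("time axis of 'ts' does not match the design", call. = FALSE)
  }
  dec <- qr(X)
  if (dec$rank < ncol(X)) {
    bad <- colnames(X)[dec$pivot[(dec$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(dec, t(ts))            # regressor x voxel
  betas <- coefs[design$task_cols, , drop = FALSE]
  structure(list(betas = betas, labels = design$labels),
            class = "trial_betas")
}

#' Run the single-trial GLM over a whole simulated session
#'
#' Per run: drops the initial `n_discard_vols` volumes, applies
#' [highpass_and_detrend()] to both the voxel time series and the task
#' regressors (so the filtering cannot bias the trial amplitudes --- this is
#' the projected-out-nuisance form of including the filter basis in the
#' model), and estimates betas; results are stacked across runs.
#'
#' @param session A `"sim_session"` (or compatible list with `runs`,
#'   `events`, `design`).
#' @param cutoff_hz High-pass cutoff (Hz).
#' @return A `"trial_betas"` object covering all runs; `labels` includes
#'   `run`, `condition`, `trial_type`, `image`, `shift_deg`, `sequence`.
#' @export
estimate_trial_betas <- function(session, cutoff_hz = 0.006) {
  design <- session$design
  drop_n <- design$n_discard_vols
  out_b <- NULL
  out_l <- NULL
  for (r in seq_along(session$runs)) {
    y <- session$runs[[r]]
    keep <- (drop_n + 1L):ncol(y)
    y <- y[, keep, drop = FALSE]
    y <- highpass_and_detrend(y, design$tr_s, cutoff_hz, keep_mean = FALSE)
    ev <- session$events[session$events$run == r, , drop = FALSE]
    ev$onset_s <- ev$onset_s - drop_n * design$tr_s
    dm <- build_single_trial_design(ev, ncol(y), design$tr_s)
    dm$X[, dm$task_cols] <- t(highpass_and_detrend(
      t(dm$X[, dm$task_cols, drop = FALSE]), design$tr_s, cutoff_hz,
      keep_mean = FALSE))
    tb <- estimate_betas(y, dm)
    out_b <- rbind(out_b, tb$betas)
    out_l <- rbind(out_l, tb$labels)
  }
  structure(list(betas = out_b, labels = out_l), class = "trial_betas")
}

#' @export
print.trial_betas <- function(x, ...) {
  cat(sprintf("<trial_betas> %d trials x %d voxels (%d runs)\n",
              nrow(x$betas), ncol(x$betas), length(unique(x$labels$run))))
  invisible(x)
}
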