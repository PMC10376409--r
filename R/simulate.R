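#' Ground-truth voxel layout of a simulated session
#'
#' Voxels are laid out in contiguous blocks: a feedback block (responds to the
#' `target` checkerboard and carries the occluded-quadrant scene patterns), a
#' feedforward block (stimulated by all image conditions, carries its own
#' scene patterns, unresponsive to the mapping checkerboards, which fall in
#' the occluded quadrant of the other hemifield), a surround block (split
#' between the two surround checkerboards, stimulated by the images but
#' carrying no scene-specific pattern), and inert voxels.
#'
#' @param n_feedback,n_feedforward,n_surround,n_null Block sizes.
#' @param map_amp Response amplitude of mapping-checkerboard trials in the
#'   voxels they drive (units of noise SD).
#' @param ff_mean Mean image-trial response of feedforward voxels.
#' @param surround_mean Mean image-trial response of surround voxels.
#' @return An object of class `"roi_layout"`.
#' @export
roi_layout <- function(n_feedback = 150L, n_feedforward = 150L,
                       n_surround = 150L, n_null = 150L,
                       map_amp = 3, ff_mean = 2, surround_mean = 2) {
  stopifnot(n_feedback >= 2, n_feedforward >= 2, n_surround >= 2, n_null >= 0)
  n <- c(n_feedback, n_feedforward, n_surround, n_null)
  ends <- cumsum(n)
  starts <- c(1L, head(ends, -1L) + 1L)
  idx <- function(k) if (n[k] > 0) seq.int(starts[k], ends[k]) else integer(0)
  surround <- idx(3L)
  half <- length(surround) %/% 2L
  structure(list(
    n_voxels = sum(n),
    feedback = idx(1L), feedforward = idx(2L), surround = surround,
    surround1 = surround[seq_len(half)],
    surround2 = surround[setdiff(seq_along(surround), seq_len(half))],
    null = idx(4L),
    map_amp = map_amp, ff_mean = ff_mean, surround_mean = surround_mean
  ), class = "roi_layout")
}

# One run's trial schedule: image sequences (6 randomly ordered image
# conditions) interleaved with mapping sequences, each sequence preceded by a
# fixation period, plus a trailing fixation. Onsets are in seconds from the
# start of the *generated* run, i.e. they include the to-be-discarded initial
# volumes.
run_schedule <- function(design, run, seed) {
  set.seed(seed)
  img_conds <- image_conditions(design)
  map_conds <- rep(design$mapping_conditions, design$mapping_reps_per_sequence)
  n_img <- design$sequences_per_run
  n_map <- design$mapping_sequences_per_run
  # spread mapping sequences evenly through the run
  seq_types <- character(0)
  img_left <- n_img; map_left <- n_map
  block <- if (n_map > 0) ceiling(n_img / n_map) else n_img
  while (img_left > 0 || map_left > 0) {
    take <- min(block, img_left)
    seq_types <- c(seq_types, rep("image", take))
    img_left <- img_left - take
    if (map_left > 0) {
      seq_types <- c(seq_types, "mapping")
      map_left <- map_left - 1L
    }
  }
  t <- design$n_discard_vols * design$tr_s
  rows <- vector("list", length(seq_types))
  for (k in seq_along(seq_types)) {
    t <- t + design$fixation_s
    conds <- if (seq_types[k] == "image") sample(img_conds) else sample(map_conds)
    onsets <- t + (seq_along(conds) - 1L) * design$trial_duration_s
    rows[[k]] <- data.frame(
      run = run, onset_s = onsets, duration_s = design$trial_duration_s,
      condition = conds,
      trial_type = seq_types[k],
      sequence = k, stringsAsFactors = FALSE)
    t <- t + length(conds) * design$trial_duration_s
  }
  ev <- do.call(rbind, rows)
  is_img <- ev$trial_type == "image"
  ev$image <- NA_integer_
  ev$image[is_img] <- as.integer(sub("^img(\\d+)_s.*$", "\\1", ev$condition[is_img]))
  ev$shift_deg <- NA_real_
  ev$shift_deg[is_img] <- as.numeric(sub("^img\\d+_s", "", ev$condition[is_img]))
  ev$trial <- seq_len(nrow(ev))
  ev
}

# HRF-convolved regressor for one boxcar trial, sampled at the TR grid.
# The boxcar is the fraction of each volume's acquisition interval covered
# by the trial, so off-grid onsets are handled exactly.
hrf_regressor <- function(onset, duration, n_vols, tr_s, kernel) {
  t0 <- (seq_len(n_vols) - 1) * tr_s
  box <- pmax(0, (pmin(t0 + tr_s, onset + duration) - pmax(t0, onset)) / tr_s)
  stats::convolve(box, rev(kernel), type = "open")[seq_len(n_vols)]
}

# All trial regressors at once (time x trial). Grid-aligned trials of a
# shared duration reuse one precomputed response shape; anything else falls
# back to the generic convolution.
trial_regressor_matrix <- function(onsets, durations, n_vols, tr_s, kernel) {
  n_trials <- length(onsets)
  R <- matrix(0, n_vols, n_trials)
  offs <- onsets / tr_s
  aligned <- abs(offs - round(offs)) < 1e-9
  shapes <- list()
  for (k in seq_len(n_trials)) {
    if (aligned[k]) {
      key <- format(durations[k])
      if (is.null(shapes[[key]])) {
        n_on <- max(1L, round(durations[k] / tr_s))
        shapes[[key]] <- stats::convolve(c(rep(1, n_on), rep(0, length(kernel))),
                                         rev(kernel), type = "open")
      }
      sh <- shapes[[key]]
      i0 <- round(offs[k])
      len <- min(length(sh), n_vols - i0)
      if (len > 0) R[i0 + seq_len(len), k] <- sh[seq_len(len)]
    } else {
      R[, k] <- hrf_regressor(onsets[k], durations[k], n_vols, tr_s, kernel)
    }
  }
  R
}

check_no_overlap <- function(events) {
  for (r in unique(events$run)) {
    ev <- events[events$run == r, ]
    ev <- ev[order(ev$onset_s), ]
    if (any(duplicated(ev$onset_s))) {
      stop("overlapping trials with identical onsets in run ", r, call. = FALSE)
    }
    if (nrow(ev) > 1 &&
        any(ev$onset_s[-1] < (ev$onset_s + ev$duration_s)[-nrow(ev)] - 1e-9)) {
      stop("overlapping trials in run ", r, call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Simulate the BOLD time series of one scanning session
#'
#' Each trial contributes a boxcar of `trial_duration_s` at its onset,
#' convolved with the canonical double-gamma HRF. The per-voxel trial
#' amplitude is determined by the ground-truth layout: feedback voxels
#' respond to image trials with `snr * pattern(image, shift)` (zero-mean
#' across voxels: the occluded quadrant receives no net feedforward drive)
#' and to `target` mapping trials; feedforward voxels respond to every image
#' trial with a common mean plus their own `snr * pattern`; surround voxels
#' respond to their checkerboard and to image trials without scene-specific
#' structure. Signal is scaled by `(1 + jitter)` per trial and summed with
#' stationary AR(1) noise and slow drift.
#'
#' @param design An [experiment_design()].
#' @param patterns A list with elements `feedback` and `feedforward`, each a
#'   [make_patterns()] array sized to the corresponding layout block and to
#'   the design's images and shifts.
#' @param noise A [noise_model()].
#' @param tuning A [tuning_model()]; `snr` scales the scene patterns.
#' @param seed Integer seed (schedules, jitter, noise, drift).
#' @param layout A [roi_layout()].
#' @return An object of class `"sim_session"`: a list with `runs` (one
#'   voxel-by-time matrix per run), `events`, `rois` (ground-truth index
#'   sets), `truth` (patterns and generating models), `design`, and `seed`.
#' @export
simulate_timeseries <- function(design, patterns, noise, tuning, seed,
                                layout = roi_layout()) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(noise, "noise_model"),
            inherits(tuning, "tuning_model"),
            inherits(layout, "roi_layout"))
  img_conds <- image_conditions(design)
  all_conds <- c(img_conds, design$mapping_conditions)
  for (nm in c("feedback", "feedforward")) {
    p <- patterns[[nm]]
    if (is.null(p) || dim(p)[1] < design$n_images ||
        dim(p)[2] < length(design$shift_levels_deg) ||
        dim(p)[3] != length(layout[[nm]])) {
      stop("'patterns$", nm, "' does not cover the design conditions / layout",
           call. = FALSE)
    }
  }
  V <- layout$n_voxels
  n_vols <- design$n_vols
  kernel <- canonical_hrf(design$tr_s)

  # voxel x condition amplitude map (before snr-scaled patterns)
  A <- matrix(0, V, length(all_conds), dimnames = list(NULL, all_conds))
  A[layout$feedback, "target"] <- layout$map_amp
  A[layout$surround1, "surround1"] <- layout$map_amp
  A[layout$surround2, "surround2"] <- layout$map_amp
  A[layout$feedforward, img_conds] <- layout$ff_mean
  A[layout$surround, img_conds] <- layout$surround_mean
  shift_key <- paste0("s", design$shift_levels_deg)
  for (i in seq_len(design$n_images)) {
    for (k in seq_along(shift_key)) {
      cond <- sprintf("img%d_s%g", i, design$shift_levels_deg[k])
      A[layout$feedback, cond] <- A[layout$feedback, cond] +
        tuning$snr * patterns$feedback[i, shift_key[k], ]
      A[layout$feedforward, cond] <- A[layout$feedforward, cond] +
        tuning$snr * patterns$feedforward[i, shift_key[k], ]
    }
  }

  runs <- vector("list", design$n_runs)
  events <- vector("list", design$n_runs)
  for (r in seq_len(design$n_runs)) {
    ev <- run_schedule(design, r, derive_seed(seed, 1L, r))
    events[[r]] <- ev
    set.seed(derive_seed(seed, 2L, r))
    n_trials <- nrow(ev)
    R <- trial_regressor_matrix(ev$onset_s, ev$duration_s, n_vols,
                                design$tr_s, kernel)
    jitter <- 1 + stats::rnorm(n_trials, 0, noise$trial_jitter_sd)
    amp <- A[, ev$condition, drop = FALSE] * rep(jitter, each = V)
    y <- amp %*% t(R)
    if (noise$noise_sd > 0) {
      burn <- 50L
      w <- matrix(stats::rnorm((n_vols + burn) * V,
                               sd = noise$noise_sd * sqrt(1 - noise$ar1_coef^2)),
                  n_vols + burn, V)
      if (noise$ar1_coef > 0) {
        w <- stats::filter(w, noise$ar1_coef, method = "recursive")
      }
      y <- y + t(w[burn + seq_len(n_vols), , drop = FALSE])
    }
    if (noise$drift_amp > 0) {
      tt <- seq_len(n_vols)
      b <- cbind(2 * (tt - 1) / (n_vols - 1) - 1,
                 cos(pi * (tt - 0.5) / n_vols))
      coefs <- matrix(stats::rnorm(2 * V, 0, noise$drift_amp), 2, V)
      y <- y + t(b %*% coefs)
    }
    runs[[r]] <- y
  }
  events <- do.call(rbind, events)
  check_no_overlap(events)
  run_end <- design$n_vols * design$tr_s
  stopifnot(all(events$onset_s + events$duration_s <= run_end + 1e-9))

  structure(list(
    runs = runs, events = events,
    rois = list(feedback = layout$feedback, feedforward = layout$feedforward,
                surround = layout$surround, surround1 = layout$surround1,
                surround2 = layout$surround2, null = layout$null),
    truth = list(patterns = patterns, tuning = tuning, noise = noise,
                 layout = layout),
    design = design, seed = as.integer(seed),
    subject_id = NA_character_, experiment = NA_integer_
  ), class = "sim_session")
}

#' Simulate one subject's session, drawing ground-truth patterns internally
#'
#' Convenience wrapper around [make_patterns()] and [simulate_timeseries()];
#' pattern seeds and the time-series seed are derived deterministically from
#' `seed`, so the session is reproducible bit-for-bit.
#'
#' @inheritParams simulate_timeseries
#' @return A `"sim_session"`; see [simulate_timeseries()].
#' @export
simulate_session <- function(design = experiment_design(),
                             tuning = tuning_model(),
                             noise = noise_model(),
                             seed = 1L,
                             layout = roi_layout()) {
  patterns <- list(
    feedback = make_patterns(length(layout$feedback), design$n_images,
                             design$shift_levels_deg, tuning,
                             derive_seed(seed, .SEED_STAGE[["patterns"]], 1L)),
    feedforward = make_patterns(length(layout$feedforward), design$n_images,
                                design$shift_levels_deg, tuning,
                                derive_seed(seed, .SEED_STAGE[["patterns"]], 2L)))
  simulate_timeseries(design, patterns, noise, tuning,
                      derive_seed(seed, .SEED_STAGE[["timeseries"]]), layout)
}

#' The four reference experiment designs
#'
#' Experiments one and two use spatial shifts `{0, 2, 8}` degrees; experiments
#' three and four use `{0, 3, 7}`. Cross-classification across these shift
#' sets probes deltas of 2, 3, 4, 6, 7 and 8 degrees.
#'
#' @return List of four [experiment_design()] objects.
#' @export
reference_experiments <- function() {
  list(experiment_design(shift_levels_deg = c(0, 2, 8)),
       experiment_design(shift_levels_deg = c(0, 2, 8)),
       experiment_design(shift_levels_deg = c(0, 3, 7)),
       experiment_design(shift_levels_deg = c(0, 3, 7)))
}

#' Simulate a multi-subject cohort
#'
#' Subjects are assigned to experiments in order; subject-level seeds are
#' derived deterministically from the master seed so any subject can be
#' regenerated in isolation.
#'
#' @param n_subjects Total number of subjects (>= 1).
#' @param experiments List of [experiment_design()] objects.
#' @param tuning,noise,layout Shared generative models.
#' @param seed Master seed.
#' @param cohort_sizes Optional integer vector (one entry per experiment,
#'   summing to `n_subjects`); defaults to an even split with earlier
#'   experiments taking the remainder. The reference cohort is 26 subjects
#'   split 8/7/6/5.
#' @return List of `"sim_session"` objects with `subject_id` and `experiment`
#'   fields populated.
#' @export
simulate_cohort <- function(n_subjects = 26L,
                            experiments = reference_experiments(),
                            tuning = tuning_model(),
                            noise = noise_model(),
                            seed = 1L,
                            cohort_sizes = NULL,
                            layout = roi_layout()) {
  if (n_subjects < 1) stop("'n_subjects' must be >= 1", call. = FALSE)
  n_exp <- length(experiments)
  if (is.null(cohort_sizes)) {
    if (n_exp == 4L && n_subjects == 26L) {
      cohort_sizes <- c(8L, 7L, 6L, 5L)
    } else {
      base <- n_subjects %/% n_exp
      cohort_sizes <- rep(base, n_exp)
      extra <- n_subjects - base * n_exp
      if (extra > 0) cohort_sizes[seq_len(extra)] <- cohort_sizes[seq_len(extra)] + 1L
    }
  }
  if (length(cohort_sizes) != n_exp || sum(cohort_sizes) != n_subjects) {
    stop("'cohort_sizes' must have one entry per experiment and sum to 'n_subjects'",
         call. = FALSE)
  }
  assignment <- rep(seq_len(n_exp), cohort_sizes)
  sessions <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    s <- simulate_session(design = experiments[[assignment[i]]],
                          tuning = tuning, noise = noise,
                          seed = derive_seed(seed, .SEED_STAGE[["cohort"]], i),
                          layout = layout)
    s$subject_id <- sprintf("sub-%02d", i)
    s$experiment <- assignment[i]
    sessions[[i]] <- s
  }
  sessions
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("<sim_session> %s  experiment %s\n",
              ifelse(is.na(x$subject_id), "(unassigned)", x$subject_id),
              ifelse(is.na(x$experiment), "-", x$experiment)))
  cat(sprintf("  %d runs of %d volumes x %d voxels (TR %g s)\n",
              length(x$runs), ncol(x$runs[[1]]), nrow(x$runs[[1]]),
              x$design$tr_s))
  cat(sprintf("  shifts {%s} deg; %d image + %d mapping trials per run\n",
              paste(x$design$shift_levels_deg, collapse = ", "),
              sum(x$events$trial_type == "image" & x$events$run == 1),
              sum(x$events$trial_type == "mapping" & x$events$run == 1)))
  invisible(x)
}
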