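#' Spatial tuning model for cross-shift pattern similarity
#'
#' The generator's operationalisation of feedback spatial precision: the
#' expected correlation between the multivoxel patterns evoked by the same
#' scene at two spatial shifts `s1`, `s2` (degrees of visual angle) follows a
#' Gaussian similarity kernel of the shift difference,
#' `rho(delta) = exp(-delta^2 / (2 * sigma_deg^2))`.
#'
#' @param sigma_deg Spatial tuning width in degrees of visual angle
#'   (strictly positive; `Inf` is allowed and makes all shifts identical).
#' @param snr Scene-pattern amplitude expressed in units of the noise
#'   standard deviation (dimensionless, `>= 0`). `snr = 0` means voxel
#'   patterns carry no scene information.
#' @return An object of class `"tuning_model"`.
#' @seealso [shift_similarity()], [make_patterns()]
#' @export
tuning_model <- function(sigma_deg = 2.4, snr = snr_reference()) {
  if (!is.numeric(sigma_deg) || length(sigma_deg) != 1L || is.na(sigma_deg) ||
      sigma_deg <= 0) {
    stop("'sigma_deg' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr < 0) {
    stop("'snr' must be a single non-negative number", call. = FALSE)
  }
  structure(list(sigma_deg = sigma_deg, snr = snr), class = "tuning_model")
}

#' Gaussian similarity kernel over spatial shift
#'
#' @param delta_deg Non-negative shift difference(s) in degrees.
#' @param tuning A [tuning_model()].
#' @return Correlations in `[0, 1]`; `1` at `delta_deg = 0`.
#' @export
shift_similarity <- function(delta_deg, tuning) {
  stopifnot(inherits(tuning, "tuning_model"))
  if (any(delta_deg < 0)) stop("'delta_deg' must be non-negative", call. = FALSE)
  if (is.infinite(tuning$sigma_deg)) return(rep(1, length(delta_deg)))
  exp(-delta_deg^2 / (2 * tuning$sigma_deg^2))
}

#' Additive noise model for simulated BOLD time series
#'
#' Voxel time series receive stationary AR(1) noise, slow per-voxel drift
#' (a random mixture of a linear ramp and a very low frequency cosine), and
#' multiplicative per-trial amplitude jitter shared across voxels.
#'
#' @param ar1_coef Lag-1 autocorrelation of the noise process, in `[0, 1)`.
#' @param noise_sd Stationary noise standard deviation (BOLD units, > 0).
#' @param drift_amp Standard deviation of the drift-component coefficients
#'   (BOLD units, >= 0).
#' @param trial_jitter_sd Standard deviation of the per-trial multiplicative
#'   amplitude jitter (dimensionless, >= 0).
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(ar1_coef = 0.3, noise_sd = 1, drift_amp = 1.5,
                        trial_jitter_sd = 0.1) {
  if (ar1_coef < 0 || ar1_coef >= 1) {
    stop("'ar1_coef' must lie in [0, 1)", call. = FALSE)
  }
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (drift_amp < 0) stop("'drift_amp' must be >= 0", call. = FALSE)
  if (trial_jitter_sd < 0) stop("'trial_jitter_sd' must be >= 0", call. = FALSE)
  structure(list(ar1_coef = ar1_coef, noise_sd = noise_sd,
                 drift_amp = drift_amp, trial_jitter_sd = trial_jitter_sd),
            class = "noise_model")
}

#' Block-design experiment layout
#'
#' Describes one experiment: two natural scenes, each presented at three
#' spatial shifts (6 image conditions), plus three contrast-reversing
#' checkerboard mapping conditions (`target`, `surround1`, `surround2`)
#' that localise the occluded image quadrant. A trial is a 12 s block
#' (30 on/off flashes of 200 ms each -- the flicker exists only in the
#' duration arithmetic, not in the simulated signal). A sequence is the six
#' image conditions in random order (72 s), preceded by a 12 s fixation
#' period; mapping sequences interleave with image sequences so that with the
#' defaults one run lasts 768 s (12 min 48 s).
#'
#' @param shift_levels_deg Three spatial shifts in degrees, e.g. `c(0, 2, 8)`.
#' @param n_runs Number of runs per subject.
#' @param sequences_per_run Image sequences per run (each contains every
#'   image condition exactly once).
#' @param trial_duration_s Trial (block) duration in seconds; must equal
#'   `n_flashes * (flash_on_ms + flash_off_ms) / 1000`.
#' @param n_flashes,flash_on_ms,flash_off_ms Flicker parameters.
#' @param fixation_s Fixation period before each sequence and after the last.
#' @param tr_s Repetition time in seconds.
#' @param n_images Number of scene images (two-class decoding requires 2).
#' @param mapping_conditions Labels of the three checkerboard conditions.
#' @param mapping_sequences_per_run Mapping sequences per run; each presents
#'   every mapping condition `mapping_reps_per_sequence` times.
#' @param mapping_reps_per_sequence Repeats of each mapping condition within
#'   one mapping sequence.
#' @param n_discard_vols Initial volumes simulated but dropped before the GLM
#'   (T1 saturation convention).
#' @return An object of class `"experiment_design"` with derived fields
#'   `sequence_duration_s`, `run_duration_s` and `n_vols` (volumes generated
#'   per run, including the discarded ones).
#' @export
experiment_design <- function(shift_levels_deg = c(0, 2, 8),
                              n_runs = 4L,
                              sequences_per_run = 6L,
                              trial_duration_s = 12,
                              n_flashes = 30L,
                              flash_on_ms = 200,
                              flash_off_ms = 200,
                              fixation_s = 12,
                              tr_s = 1,
                              n_images = 2L,
                              mapping_conditions = c("target", "surround1", "surround2"),
                              mapping_sequences_per_run = 3L,
                              mapping_reps_per_sequence = 2L,
                              n_discard_vols = 2L) {
  shift_levels_deg <- sort(unique(as.numeric(shift_levels_deg)))
  if (any(shift_levels_deg < 0)) stop("shifts must be non-negative", call. = FALSE)
  if (tr_s <= 0) stop("'tr_s' must be positive", call. = FALSE)
  flick <- n_flashes * (flash_on_ms + flash_off_ms) / 1000
  if (abs(flick - trial_duration_s) > 1e-9) {
    stop(sprintf(
      "trial_duration_s (%g s) must equal n_flashes * (on + off) ms = %g s",
      trial_duration_s, flick), call. = FALSE)
  }
  n_shifts <- length(shift_levels_deg)
  sequence_duration_s <- n_images * n_shifts * trial_duration_s
  map_seq_duration_s <- length(mapping_conditions) * mapping_reps_per_sequence *
    trial_duration_s
  run_duration_s <- sequences_per_run * (fixation_s + sequence_duration_s) +
    mapping_sequences_per_run * (fixation_s + map_seq_duration_s) + fixation_s
  des <- structure(list(
    shift_levels_deg = shift_levels_deg,
    n_runs = as.integer(n_runs),
    sequences_per_run = as.integer(sequences_per_run),
    trial_duration_s = trial_duration_s,
    n_flashes = as.integer(n_flashes),
    flash_on_ms = flash_on_ms,
    flash_off_ms = flash_off_ms,
    fixation_s = fixation_s,
    tr_s = tr_s,
    n_images = as.integer(n_images),
    mapping_conditions = mapping_conditions,
    mapping_sequences_per_run = as.integer(mapping_sequences_per_run),
    mapping_reps_per_sequence = as.integer(mapping_reps_per_sequence),
    n_discard_vols = as.integer(n_discard_vols),
    sequence_duration_s = sequence_duration_s,
    run_duration_s = run_duration_s,
    n_vols = as.integer(round(run_duration_s / tr_s)) + as.integer(n_discard_vols)
  ), class = "experiment_design")
  des
}

#' Image condition labels of a design
#'
#' @param design An [experiment_design()].
#' @return Character vector `img<i>_s<shift>` over images and shifts.
#' @export
image_conditions <- function(design) {
  as.vector(t(outer(seq_len(design$n_images), design$shift_levels_deg,
                    function(i, s) sprintf("img%d_s%g", i, s))))
}

#' Shift deltas testable by cross-classification under a design
#'
#' For a shift set `{0, a, b}` the within-condition delta 0 plus the absolute
#' pairwise differences `a`, `b - a`, and `b`.
#'
#' @param design An [experiment_design()].
#' @return Sorted numeric vector of deltas, starting at 0.
#' @export
design_deltas <- function(design) {
  s <- design$shift_levels_deg
  sort(unique(c(0, abs(as.vector(outer(s, s, "-"))))))
}

#' Deterministic seed chain
#'
#' Folds successive indices into a 31-bit state so that any stage of the
#' pipeline can reproduce its sub-seed from the master seed and its
#' coordinates (stage id, subject, run, ...). Used for every internal source
#' of randomness; two different coordinate paths practically never collide.
#'
#' @param master Master seed (integer).
#' @param ... Integer coordinates identifying the consumer.
#' @return An integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  m <- 2147483647            # 2^31 - 1, keeps set.seed() input in range
  s <- as.numeric(master) %% m
  for (k in idx) {
    s <- (s * 69069 + as.numeric(k) + 1) %% m
  }
  as.integer(s)
}

# stage ids for derive_seed(); fixed so sub-streams never collide
.SEED_STAGE <- c(patterns = 11L, timeseries = 23L, cohort = 37L,
                 bootstrap = 53L, permutation = 71L, qc = 89L)
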