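#' First-level bootstrap estimate of a subject's mean accuracy
#'
#' Resamples the subject's fold accuracies with replacement `B` times and
#' returns the mean of the resampled means (which converges to the sample
#' mean as `B` grows).
#'
#' @param fold_accuracies Numeric vector of per-fold accuracies (>= 1).
#' @param B Number of bootstrap samples.
#' @param seed Integer seed.
#' @return Single numeric estimate of the subject mean.
#' @export
bootstrap_subject_mean <- function(fold_accuracies, B = 1000L, seed = 1L) {
  n <- length(fold_accuracies)
  if (n == 0) stop("no fold accuracies supplied", call. = FALSE)
  if (n == 1 || stats::var(fold_accuracies) == 0) return(mean(fold_accuracies))
  fold_accuracies <- sort(fold_accuracies)   # order-invariant resampling
  set.seed(seed)
  draws <- matrix(sample(fold_accuracies, n * B, replace = TRUE), nrow = n)
  mean(colMeans(draws))
}

#' Second-level bootstrap: group mean and middle-95% confidence interval
#'
#' Resamples subjects with replacement `B` times; the group mean is the mean
#' of the bootstrap means, and the confidence interval spans the middle
#' `coverage` fraction of the bootstrap distribution (2.5th to 97.5th
#' percentile by default), reported as non-negative offsets below and above
#' the group mean. Decoding against chance is significant iff 0.5 lies
#' outside `[mean - lower_offset, mean + upper_offset]`.
#'
#' @param subject_means Numeric vector of per-subject mean accuracies (>= 2).
#' @param B Number of bootstrap samples.
#' @param coverage Central coverage of the interval.
#' @param seed Integer seed.
#' @param chance Chance level used for the significance flag.
#' Two flags are recorded: `ci_excludes_chance` (the two-sided statement
#' that 0.5 lies outside the interval) and `significant_vs_chance` (the
#' reported one-sided statement: the interval excludes 0.5 *and* the group
#' mean is above it, since decoding below chance is not evidence of carried
#' information).
#'
#' @return Object of class `"group_inference"`: list with `group_mean`,
#'   `ci_lower_offset`, `ci_upper_offset`, `ci_excludes_chance`,
#'   `significant_vs_chance`, `n_subjects`, and the raw `boot_means`.
#' @export
bootstrap_group <- function(subject_means, B = 1000L, coverage = 0.95,
                            seed = 1L, chance = 0.5) {
  n <- length(subject_means)
  if (n < 2) stop("group bootstrap needs at least 2 subjects", call. = FALSE)
  subject_means <- sort(subject_means)       # order-invariant resampling
  set.seed(seed)
  draws <- matrix(sample(subject_means, n * B, replace = TRUE), nrow = n)
  boot_means <- colMeans(draws)
  gm <- mean(boot_means)
  alpha <- (1 - coverage) / 2
  ci <- unname(stats::quantile(boot_means, c(alpha, 1 - alpha)))
  lower_off <- max(0, gm - ci[1])
  upper_off <- max(0, ci[2] - gm)
  excludes <- chance < gm - lower_off || chance > gm + upper_off
  structure(list(
    group_mean = gm,
    ci_lower_offset = lower_off,
    ci_upper_offset = upper_off,
    ci_excludes_chance = excludes,
    significant_vs_chance = excludes && gm > chance,
    n_subjects = n,
    coverage = coverage,
    boot_means = boot_means
  ), class = "group_inference")
}

#' @export
print.group_inference <- function(x, ...) {
  cat(sprintf("<group_inference> mean %.2f%%  CI [-%.4f, +%.4f]  n = %d%s\n",
              100 * x$group_mean, x$ci_lower_offset, x$ci_upper_offset,
              x$n_subjects,
              if (x$significant_vs_chance) "  * vs chance" else ""))
  invisible(x)
}

#' Permutation test of the difference between two condition means
#'
#' Pools the two samples, reshuffles condition labels `n_perm` times, and
#' compares the observed absolute difference of means with the null
#' distribution of absolute differences. The p-value uses the add-one
#' convention (the observed statistic counts as one null sample), so it is
#' never exactly zero; the difference is declared significant when the
#' observed value falls in the top 5% of the null distribution
#' (`p <= 0.05`).
#'
#' @param valsA,valsB Numeric vectors of subject means per condition.
#' @param n_perm Number of permutations (warns below 100).
#' @param seed Integer seed.
#' @param alpha Significance criterion on the permutation p-value.
#' @return Object of class `"permutation_test"`: list with `observed_diff`,
#'   `null_diffs`, `p_value`, `significant`.
#' @export
permutation_diff_test <- function(valsA, valsB, n_perm = 1000L, seed = 1L,
                                  alpha = 0.05) {
  if (length(valsA) == 0 || length(valsB) == 0) {
    stop("both conditions must be non-empty", call. = FALSE)
  }
  if (n_perm < 100) warning("fewer than 100 permutations", call. = FALSE)
  observed <- abs(mean(valsA) - mean(valsB))
  pooled <- sort(c(valsA, valsB))            # order-invariant null
  nA <- length(valsA)
  set.seed(seed)
  null_diffs <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pooled), nA)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  }, numeric(1))
  p <- (1 + sum(null_diffs >= observed - 1e-12)) / (n_perm + 1)
  structure(list(observed_diff = observed, null_diffs = null_diffs,
                 p_value = p, significant = p <= alpha),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<permutation_test> |diff| = %.4f  p = %.4g%s\n",
              x$observed_diff, x$p_value,
              if (x$significant) "  *" else ""))
  invisible(x)
}

#' Exclude subjects with chance-level feedforward classification
#'
#' Mirrors the cohort quality-control rule: a subject is excluded when their
#' within-shift single-trial decoding in the stimulated (feedforward) ROI --
#' pooled over all shift levels and folds -- is not above chance by a
#' one-sided binomial test at level `alpha`.
#'
#' @param profiles Named list of per-subject [shift_profile()] data.frames.
#' @param alpha Binomial test level.
#' @param roi,mode Profile rows used for the criterion.
#' @return List with `kept`, `excluded` (subject names) and a per-subject
#'   summary data.frame (`accuracy`, `n_trials`, `p_value`).
#' @export
qc_exclude_subjects <- function(profiles, alpha = 0.05,
                                roi = "feedforward", mode = "ST") {
  stopifnot(!is.null(names(profiles)))
  summary <- do.call(rbind, lapply(names(profiles), function(id) {
    pr <- profiles[[id]]
    rows <- pr$roi == roi & pr$mode == mode & pr$kind == "within"
    if (!any(rows)) {
      stop("no within-shift ", roi, " ", mode, " results for subject ", id,
           call. = FALSE)
    }
    correct <- sum(round(pr$accuracy[rows] * pr$n_test[rows]))
    n <- sum(pr$n_test[rows])
    p <- stats::binom.test(correct, n, p = 0.5,
                           alternative = "greater")$p.value
    data.frame(subject = id, accuracy = correct / n, n_trials = n,
               p_value = p, excluded = p > alpha)
  }))
  list(kept = summary$subject[!summary$excluded],
       excluded = summary$subject[summary$excluded],
       summary = summary)
}

#' Pool per-subject condition means across experiments
#'
#' Experiments listed together in a pooling group must test identical shift
#' deltas (they differ only in stimuli and subjects); their subjects'
#' condition means are concatenated. Subjects from experiments lacking a
#' given delta simply do not contribute to that delta.
#'
#' @param subject_table Data.frame with columns `subject`, `experiment`,
#'   `roi`, `mode`, `delta`, `subj_mean`.
#' @param pooling List of integer vectors grouping experiment indices, e.g.
#'   `list(c(1, 2), c(3, 4))`.
#' @return The validated table with a `pool` column attached; errors if a
#'   pooling group mixes different delta sets.
#' @export
pool_experiments <- function(subject_table,
                             pooling = list(c(1L, 2L), c(3L, 4L))) {
  needed <- c("subject", "experiment", "roi", "mode", "delta", "subj_mean")
  stopifnot(all(needed %in% names(subject_table)))
  deltas_of <- function(e) {
    sort(unique(subject_table$delta[subject_table$experiment == e]))
  }
  for (grp in pooling) {
    grp <- grp[grp %in% subject_table$experiment]
    if (length(grp) < 2) next
    sets <- lapply(grp, deltas_of)
    if (!all(vapply(sets[-1], identical, logical(1), sets[[1]]))) {
      stop("cannot pool experiments {", paste(grp, collapse = ", "),
           "}: their tested deltas differ", call. = FALSE)
    }
  }
  pool_id <- rep(NA_integer_, nrow(subject_table))
  for (k in seq_along(pooling)) {
    pool_id[subject_table$experiment %in% pooling[[k]]] <- k
  }
  subject_table$pool <- pool_id
  subject_table
}
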