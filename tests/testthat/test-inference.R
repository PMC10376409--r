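test_that("first-level bootstrap reduces to the mean in degenerate cases", {
  expect_identical(bootstrap_subject_mean(rep(0.75, 4)), 0.75)
  expect_identical(bootstrap_subject_mean(0.6), 0.6)
  expect_error(bootstrap_subject_mean(numeric(0)), "no fold accuracies")
  # law of large numbers: close to the sample mean at B = 1000
  v <- c(0.58, 0.67, 0.75, 0.83)
  expect_lt(abs(bootstrap_subject_mean(v, B = 1000, seed = 1) - mean(v)), 0.005)
  expect_lt(abs(bootstrap_subject_mean(v, B = 20000, seed = 1) - mean(v)),
            abs(bootstrap_subject_mean(v, B = 50, seed = 1) - mean(v)) + 0.005)
})

test_that("group bootstrap reports offsets that bracket the middle 95%", {
  expect_error(bootstrap_group(0.7), "at least 2")
  gi0 <- bootstrap_group(rep(0.8, 10), seed = 1)
  expect_equal(gi0$group_mean, 0.8)
  expect_equal(gi0$ci_lower_offset, 0)
  expect_equal(gi0$ci_upper_offset, 0)
  expect_true(gi0$significant_vs_chance)

  set.seed(42)
  vals <- rbeta(12, 20, 12)
  gi <- bootstrap_group(vals, B = 2000, seed = 2)
  expect_gte(gi$ci_lower_offset, 0)
  expect_gte(gi$ci_upper_offset, 0)
  inside <- mean(gi$boot_means >= gi$group_mean - gi$ci_lower_offset &
                 gi$boot_means <= gi$group_mean + gi$ci_upper_offset)
  expect_equal(inside, 0.95, tolerance = 0.01)
  # significance flag follows the interval, and the reporting format
  # round-trips: mean% plus two offsets reconstruct the interval bounds
  lo <- gi$group_mean - gi$ci_lower_offset
  hi <- gi$group_mean + gi$ci_upper_offset
  expect_identical(gi$significant_vs_chance, !(lo <= 0.5 && 0.5 <= hi))
  expect_equal(unname(quantile(gi$boot_means, c(0.025, 0.975))), c(lo, hi))
})

test_that("inference is invariant to subject ordering", {
  vals <- c(0.61, 0.55, 0.72, 0.64, 0.58, 0.69)
  a <- bootstrap_group(vals, seed = 5)
  b <- bootstrap_group(rev(vals), seed = 5)
  expect_identical(a[c("group_mean", "ci_lower_offset", "ci_upper_offset")],
                   b[c("group_mean", "ci_lower_offset", "ci_upper_offset")])
  pa <- permutation_diff_test(vals, rev(vals) + 0.1, seed = 5)
  pb <- permutation_diff_test(sample(vals), sample(vals + 0.1), seed = 5)
  expect_identical(pa$p_value, pb$p_value)
})

test_that("permutation test handles degenerate and well-separated inputs", {
  v <- c(0.5, 0.6, 0.7)
  same <- permutation_diff_test(v, v, seed = 1)
  expect_equal(same$observed_diff, 0)
  expect_false(same$significant)

  apart <- permutation_diff_test(rep(0.9, 10), rep(0.5, 10),
                                 n_perm = 1000, seed = 2)
  # only 2 of choose(20,10) assignments reach the observed |difference|
  expect_lte(apart$p_value, 0.001)
  expect_true(apart$significant)
  expect_length(apart$null_diffs, 1000)
  expect_error(permutation_diff_test(numeric(0), v), "non-empty")
  expect_warning(permutation_diff_test(v, v, n_perm = 50), "100")
})

test_that("permutation p-values are approximately uniform under exchangeability", {
  set.seed(9)
  ps <- vapply(1:200, function(i) {
    a <- rnorm(10, 0.6, 0.05)
    b <- rnorm(10, 0.6, 0.05)
    permutation_diff_test(a, b, n_perm = 199, seed = 1000 + i)$p_value
  }, 1)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("subjects with chance-level feedforward decoding are excluded", {
  profiles <- list(
    good = fake_profile(acc_ff = 0.97),
    chance = fake_profile(acc_ff = 0.5),
    cohortlike = fake_profile(acc_ff = 0.75))
  qc <- qc_exclude_subjects(profiles)
  expect_setequal(as.character(qc$excluded), "chance")
  expect_setequal(as.character(qc$kept), c("good", "cohortlike"))
  # 144 trials at exactly 50% -> binomial p far above alpha
  expect_gt(qc$summary$p_value[qc$summary$subject == "chance"], 0.4)
  expect_identical(qc$summary$n_trials[1], 144)
})

test_that("null-signal subjects injected into a cohort are caught by QC", {
  profiles <- list()
  set.seed(13)
  for (i in 1:8) {
    acc <- if (i <= 2) 0.5 + rnorm(1, 0, 0.01) else 0.9
    profiles[[sprintf("s%02d", i)]] <- fake_profile(acc_ff = min(1, acc))
  }
  qc <- qc_exclude_subjects(profiles)
  expect_setequal(as.character(qc$excluded), c("s01", "s02"))
})

test_that("experiment pooling validates shared deltas", {
  tab <- expand.grid(subject = sprintf("s%d", 1:4), roi = "feedback",
                     mode = "ST", delta = c(0, 2, 6, 8),
                     stringsAsFactors = FALSE)
  tab$experiment <- ifelse(tab$subject %in% c("s1", "s2"), 1L, 2L)
  tab$subj_mean <- 0.6
  pooled <- pool_experiments(tab, pooling = list(c(1L, 2L)))
  expect_identical(nrow(pooled), nrow(tab))
  expect_true(all(pooled$pool == 1L))
  # identity pooling of a single experiment
  one <- pool_experiments(tab[tab$experiment == 1L, ], pooling = list(1L))
  expect_identical(one$subj_mean, tab$subj_mean[tab$experiment == 1L])
  # mismatched delta sets cannot be pooled
  bad <- tab
  bad$delta[bad$experiment == 2L & bad$delta == 2] <- 3
  expect_error(pool_experiments(bad, pooling = list(c(1L, 2L))), "differ")
})
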