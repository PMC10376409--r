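# Small, fast fixtures shared across the suite. All data are generated in
# code; sizes are deliberately far below the reference study so individual
# tests run in well under a second.

small_design <- function(shifts = c(0, 2, 8)) {
  experiment_design(shift_levels_deg = shifts,
                    sequences_per_run = 2L,
                    mapping_sequences_per_run = 1L,
                    mapping_reps_per_sequence = 2L)
}

small_layout <- function(...) {
  roi_layout(n_feedback = 30L, n_feedforward = 30L, n_surround = 30L,
             n_null = 10L, ...)
}

small_session <- function(seed = 1L, snr = 0.03, sigma_deg = 2.4,
                          shifts = c(0, 2, 8), noise = noise_model(), ...) {
  simulate_session(design = small_design(shifts),
                   tuning = tuning_model(sigma_deg, snr),
                   noise = noise, seed = seed,
                   layout = small_layout(...))
}

# Brute-force maximum-margin separator for 2-D two-class points: the optimal
# hyperplane bisects the shortest segment between the convex hulls of the
# two classes (closest distance found by exhaustive vertex/edge enumeration).
# Independent of the SVM implementation under test.
brute_force_margin <- function(x, y) {
  stopifnot(ncol(x) == 2, length(unique(y)) == 2)
  lv <- sort(unique(y))
  A <- x[y == lv[1], , drop = FALSE]
  B <- x[y == lv[2], , drop = FALSE]
  seg_point <- function(p, a, b) {
    # closest point to p on segment ab
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), 1e-300)
    a + min(1, max(0, t)) * ab
  }
  segments_of <- function(M) {
    if (nrow(M) == 1) return(list(list(M[1, ], M[1, ])))
    h <- grDevices::chull(M)
    idx <- cbind(h, c(h[-1], h[1]))
    lapply(seq_len(nrow(idx)), function(k) list(M[idx[k, 1], ], M[idx[k, 2], ]))
  }
  best <- list(d = Inf)
  for (sa in segments_of(A)) for (sb in segments_of(B)) {
    cand <- list()
    for (p in list(sa[[1]], sa[[2]])) {
      q <- seg_point(p, sb[[1]], sb[[2]]); cand <- c(cand, list(list(p, q)))
    }
    for (p in list(sb[[1]], sb[[2]])) {
      q <- seg_point(p, sa[[1]], sa[[2]]); cand <- c(cand, list(list(q, p)))
    }
    for (cd in cand) {
      d <- sqrt(sum((cd[[1]] - cd[[2]])^2))
      if (d < best$d) best <- list(d = d, u = cd[[1]], v = cd[[2]])
    }
  }
  w <- best$u - best$v                 # points towards class lv[1]
  mid <- (best$u + best$v) / 2
  list(w = w, b = -sum(w * mid), margin = best$d / 2,
       classify = function(newx) {
         s <- drop(newx %*% w) - sum(w * mid)
         ifelse(s >= 0, lv[1], lv[2])
       })
}

# synthetic per-subject profile table for QC tests
fake_profile <- function(acc_ff, n_test = 12, shifts = c(0, 2, 8),
                         acc_fb = 0.5) {
  rows <- expand.grid(fold = 1:4, train_shift = shifts,
                      roi = c("feedback", "feedforward"), mode = c("ST", "AB"),
                      stringsAsFactors = FALSE)
  rows$kind <- "within"
  rows$test_shift <- rows$train_shift
  rows$delta <- 0
  rows$accuracy <- ifelse(rows$roi == "feedforward", acc_ff, acc_fb)
  rows$n_test <- n_test
  rows
}
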