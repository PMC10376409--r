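#' Generate ground-truth voxel patterns with controlled cross-shift similarity
#'
#' For each scene image, the set of multivoxel patterns across spatial shifts
#' is drawn jointly from a zero-mean, unit-variance Gaussian process over
#' shift with covariance `K[j, k] = rho(|s_j - s_k|)`, where `rho` is the
#' Gaussian similarity kernel of `tuning`. The expected correlation between
#' the patterns of the same image at shifts `s1` and `s2` therefore equals
#' `rho(|s1 - s2|)` for every pair of shifts, matching the convention that
#' the tested quantity is the absolute train--test shift difference.
#' Patterns of different images are independent.
#'
#' @param n_voxels Number of voxels (>= 2).
#' @param n_images Number of scene images.
#' @param shifts Numeric vector of non-negative shifts (degrees).
#' @param tuning A [tuning_model()]; only `sigma_deg` is used here.
#' @param seed Integer seed; the draw is reproducible.
#' @return A 3-d array `[image, shift, voxel]` with `dimnames` on the first
#'   two margins, of class `"pattern_set"`. Attribute `"shifts"` stores the
#'   shift grid.
#' @examples
#' p <- make_patterns(200, 2, c(0, 2, 8), tuning_model(sigma_deg = 2.4), seed = 1)
#' cor(p[1, "s0", ], p[1, "s2", ])   # approx exp(-4 / (2 * 2.4^2))
#' @export
make_patterns <- function(n_voxels, n_images, shifts, tuning, seed) {
  stopifnot(inherits(tuning, "tuning_model"))
  if (n_voxels < 2) stop("'n_voxels' must be >= 2", call. = FALSE)
  if (any(shifts < 0)) stop("'shifts' must be non-negative", call. = FALSE)
  shifts <- as.numeric(shifts)
  n_shifts <- length(shifts)
  K <- shift_similarity(abs(outer(shifts, shifts, "-")), tuning)
  K <- matrix(K, n_shifts, n_shifts)
  # matrix square root by eigendecomposition; tolerant of the rank-deficient
  # limit sigma -> Inf where K is all ones
  eig <- eigen(K, symmetric = TRUE)
  L <- eig$vectors %*% (sqrt(pmax(eig$values, 0)) * t(eig$vectors))
  set.seed(seed)
  out <- array(NA_real_, dim = c(n_images, n_shifts, n_voxels),
               dimnames = list(image = paste0("img", seq_len(n_images)),
                               shift = paste0("s", shifts), NULL))
  for (i in seq_len(n_images)) {
    z <- matrix(stats::rnorm(n_shifts * n_voxels), n_shifts, n_voxels)
    out[i, , ] <- L %*% z
  }
  attr(out, "shifts") <- shifts
  class(out) <- c("pattern_set", class(out))
  out
}
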