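#' Pairwise streamline distances
#'
#' Two fiber-space metrics over resampled streamlines with k samples each:
#'
#' * `mean_closest_distance(f1, f2)` — directed mean closest-point distance:
#'   the average over points of `f1` of the distance to the nearest point of
#'   `f2`. Not symmetric.
#' * `fiber_distance(f1, f2, metric = "smp")` — symmetrized mean closest-point
#'   distance, the average of the two directed values.
#' * `point_distance(f1, f2)` — directed mean of index-corresponding point
#'   distances (requires equal k).
#' * `fiber_distance(f1, f2, metric = "pp")` — symmetrized point-to-point
#'   distance: the smaller of `point_distance(f1, f2)` and
#'   `point_distance(f1, flip(f2))`, making the metric orientation-invariant.
#'
#' @param f1,f2 k x 3 coordinate matrices with the same k.
#' @param metric `"pp"` (symmetrized point-to-point, the stage-1 default) or
#'   `"smp"` (symmetrized mean closest point).
#' @return Distance in mm.
#' @export
fiber_distance <- function(f1, f2, metric = c("pp", "smp")) {
  metric <- match.arg(metric)
  f1 <- as_streamline_matrix(f1); f2 <- as_streamline_matrix(f2)
  check_same_k(f1, f2)
  if (metric == "smp") {
    0.5 * (mean_closest_distance(f1, f2) + mean_closest_distance(f2, f1))
  } else {
    min(point_distance(f1, f2), point_distance(f1, flip_streamline(f2)))
  }
}

check_same_k <- function(f1, f2) {
  if (nrow(f1) != nrow(f2)) {
    abort("Fibers must be resampled to the same number of points.")
  }
}

#' @rdname fiber_distance
#' @export
mean_closest_distance <- function(f1, f2) {
  f1 <- as_streamline_matrix(f1); f2 <- as_streamline_matrix(f2)
  cd <- cross_dist(f1, f2)
  mean(apply(cd, 1L, min))
}

#' @rdname fiber_distance
#' @export
point_distance <- function(f1, f2) {
  f1 <- as_streamline_matrix(f1); f2 <- as_streamline_matrix(f2)
  check_same_k(f1, f2)
  mean(sqrt(rowSums((f1 - f2)^2)))
}

# Euclidean cross-distance matrix between two point sets (rows).
# Accumulates squared coordinate differences directly: the crossprod
# expansion cancels catastrophically for near-identical rows (errors at the
# sqrt(machine eps) scale), which matters for rigid-invariance guarantees.
cross_dist <- function(a, b) {
  d2 <- 0
  for (j in seq_len(ncol(a))) d2 <- d2 + outer(a[, j], b[, j], "-")^2
  sqrt(d2)
}

#' Pairwise fiber distance matrix for a tractogram
#'
#' Computes the full N x N matrix of pairwise distances between all resampled
#' fibers under the chosen metric. Both metrics are symmetric with a zero
#' diagonal. The computation is vectorized over sample positions (`"pp"`) or
#' over fiber point blocks (`"smp"`); complexity is O(N^2) by construction.
#'
#' @param tract A tractogram tibble whose fibers share a common k (see
#'   [resample_fibers()]).
#' @param metric `"pp"` or `"smp"`.
#' @return An N x N numeric matrix with attribute `metric`.
#' @export
fiber_distance_matrix <- function(tract, metric = c("pp", "smp")) {
  metric <- match.arg(metric)
  check_tractogram(tract)
  k <- fiber_k(tract)
  n <- nrow(tract)
  fibers <- tract$points
  if (metric == "pp") {
    fwd <- matrix(0, n, n)
    rev_ <- matrix(0, n, n)
    for (j in seq_len(k)) {
      pj <- t(vapply(fibers, function(f) f[j, ], numeric(3)))
      qj <- t(vapply(fibers, function(f) f[k + 1L - j, ], numeric(3)))
      fwd <- fwd + as.matrix(dist(pj))
      rev_ <- rev_ + cross_dist(pj, qj)
    }
    D <- pmin(fwd, rev_) / k
  } else {
    pts <- do.call(rbind, fibers)             # (N k) x 3, fiber-major
    cd <- cross_dist(pts, pts)
    # min over the target fiber's k columns, then mean over source points
    D <- matrix(0, n, n)
    for (j in seq_len(n)) {
      cols <- ((j - 1L) * k + 1L):(j * k)
      mins <- matrixStats_rowMins(cd[, cols, drop = FALSE])
      directed_ij <- colMeans(matrix(mins, nrow = k))  # d_m(F_i, F_j) for all i
      D[, j] <- D[, j] + directed_ij / 2
      D[j, ] <- D[j, ] + directed_ij / 2
    }
  }
  D <- (D + t(D)) / 2
  diag(D) <- 0
  attr(D, "metric") <- metric
  D
}

matrixStats_rowMins <- function(m) do.call(pmin, as.data.frame(m))

#' Exponential affinity matrix from a distance matrix
#'
#' Converts distances to similarities as `a_ij = exp(-d_ij / sigma)` for
#' `i != j`, with a zero diagonal (no self-loops). With `sigma = "max"` the
#' normalization is the largest pairwise distance, which bounds off-diagonal
#' affinities to `[exp(-1), 1]` regardless of the dataset scale. If every
#' distance is zero the normalization degenerates and sigma falls back to 1
#' (all off-diagonal affinities become 1).
#'
#' @param D Symmetric non-negative distance matrix with zero diagonal.
#' @param sigma Positive normalization scalar in mm, or `"max"` (default).
#' @return Affinity matrix with attribute `sigma` (the resolved value).
#' @export
build_affinity <- function(D, sigma = "max") {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) abort("`D` must be square.")
  if (any(!is.finite(D)) || any(D < 0)) abort("`D` must be finite and non-negative.")
  if (identical(sigma, "max")) {
    sigma <- max(D)
    if (sigma == 0) sigma <- 1
  } else if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    abort("`sigma` must be a positive number or \"max\".")
  }
  A <- exp(-D / sigma)
  diag(A) <- 0
  attr(A, "sigma") <- sigma
  A
}
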