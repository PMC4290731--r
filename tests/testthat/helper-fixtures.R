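# Shared in-code fixtures: simple geometric fibers, random resampled fibers,
# rigid transforms, and small affinity matrices. Everything is generated at
# test time under explicit seeds.

straight_fiber <- function(from = c(0, 0, 0), to = c(11, 0, 0), m = 2) {
  t(vapply(seq(0, 1, length.out = m),
           function(a) from + a * (to - from), numeric(3)))
}

quarter_circle <- function(radius = 10, m = 100) {
  th <- seq(0, pi / 2, length.out = m)
  cbind(radius * cos(th), radius * sin(th), 0)
}

# A random smooth-ish fiber already resampled to k points.
random_fiber <- function(k = 12, scale = 10) {
  base <- apply(matrix(rnorm(3 * k, sd = scale / k), ncol = 3), 2, cumsum)
  resample_streamline(base, k)
}

random_walk_fiber <- function(m = 10, sd = 1) {
  apply(matrix(rnorm(3 * m, sd = sd), ncol = 3), 2, cumsum)
}

random_rotation <- function() {
  rotation_matrix(rnorm(3), runif(1, 0, 360))
}

# Brute-force directed mean closest-point distance (independent oracle).
brute_mean_closest <- function(f1, f2) {
  tot <- 0
  for (i in seq_len(nrow(f1))) {
    best <- Inf
    for (j in seq_len(nrow(f2))) {
      best <- min(best, sqrt(sum((f1[i, ] - f2[j, ])^2)))
    }
    tot <- tot + best
  }
  tot / nrow(f1)
}

# Brute-force symmetrized point-to-point distance (independent oracle).
brute_pp <- function(f1, f2) {
  k <- nrow(f1)
  d_fwd <- mean(sqrt(rowSums((f1 - f2)^2)))
  d_rev <- mean(sqrt(rowSums((f1 - f2[k:1, , drop = FALSE])^2)))
  min(d_fwd, d_rev)
}

# Uniform clique affinity: n nodes, off-diagonal weight w.
clique_affinity <- function(n, w = 1) {
  A <- matrix(w, n, n)
  diag(A) <- 0
  A
}

block_affinity_matrix <- function(sizes, w = 1) {
  n <- sum(sizes)
  A <- matrix(0, n, n)
  at <- 0L
  for (s in sizes) {
    idx <- (at + 1L):(at + s)
    A[idx, idx] <- w
    at <- at + s
  }
  diag(A) <- 0
  A
}

# Minimal subject_clustering with a prescribed cohesiveness curve, for
# exercising the selection arithmetic in isolation.
fake_clustering <- function(coh, residual = rep(FALSE, length(coh))) {
  structure(list(
    clusters = tibble::tibble(
      cluster = seq_along(coh),
      members = as.list(seq_along(coh)),
      x = as.list(rep(1, length(coh))),
      cohesiveness = coh, residual = residual,
      size = rep(1L, length(coh)),
      medoid = seq_along(coh), kept = !residual),
    assignment = seq_along(coh), distance = NULL, sigma = 1,
    subject_id = "s", fiber_id = seq_along(coh), metric = "pp", k = 12,
    config = ds_config(), selection = NULL), class = "subject_clustering")
}

# Small well-separated multi-bundle subject (parallel straight bundles).
parallel_bundles <- function(n_bundles = 3, m = 20, k = 12, sep = 20,
                             spread = 0.3, seed = 42) {
  withr::with_seed(seed, {
    fibers <- list(); labels <- integer(0)
    for (b in seq_len(n_bundles)) {
      ctr <- straight_fiber(c(0, (b - 1) * sep, 0), c(30, (b - 1) * sep, 0), m = k)
      fb <- generate_bundle(ctr, m, spread = spread, jitter = 0.05)
      fibers <- c(fibers, fb)
      labels <- c(labels, rep(b, m))
    }
    tractogram(fibers, bundle = labels)
  })
}
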