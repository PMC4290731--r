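#' Configuration for dominant-set extraction
#'
#' @param theta Support threshold in `[0, 1)`: after convergence, indices with
#'   `x_i > theta * max(x)` form the cluster. Very small values keep the model
#'   stable; the default 1e-5 acts as a noise reducer. `theta = 1` would empty
#'   the support under the strict inequality and is rejected.
#' @param epsilon Convergence tolerance on the Euclidean distance between
#'   consecutive iterates (default 1e-7).
#' @param max_iterations Iteration cap with a warning on non-convergence
#'   (default 10000).
#' @param regularization Diagonal shift alpha: the dynamics iterate on
#'   `A + alpha * I`. The default 0 is the clustering formulation (zero
#'   diagonal, no self-loops). For unweighted 0/1 adjacency matrices,
#'   `alpha = 1/2` makes strict local maximizers correspond exactly to
#'   maximal cliques and removes spurious mixed solutions; see the methods
#'   vignette.
#' @param perturbation Relative magnitude of the deterministic tie-breaking
#'   offset added to the barycenter start (default 1e-4). Exactly symmetric
#'   affinity patterns (duplicate rows, twin vertices) otherwise trap the
#'   dynamics on saddle points. Set to 0 for the exact barycenter.
#' @return A list of class `ds_config`.
#' @export
ds_config <- function(theta = 1e-5, epsilon = 1e-7, max_iterations = 10000,
                      regularization = 0, perturbation = 1e-4) {
  if (!is.numeric(theta) || theta < 0 || theta >= 1) {
    abort("`theta` must lie in [0, 1).")
  }
  if (!is.numeric(epsilon) || epsilon <= 0) abort("`epsilon` must be > 0.")
  if (!is.numeric(max_iterations) || max_iterations < 1) {
    abort("`max_iterations` must be >= 1.")
  }
  if (!is.numeric(regularization) || regularization < 0) {
    abort("`regularization` must be >= 0.")
  }
  if (!is.numeric(perturbation) || perturbation < 0) {
    abort("`perturbation` must be >= 0.")
  }
  structure(list(theta = theta, epsilon = epsilon,
                 max_iterations = as.integer(max_iterations),
                 regularization = regularization, perturbation = perturbation),
            class = "ds_config")
}

check_affinity <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) abort("`A` must be square.")
  if (any(!is.finite(A)) || any(A < 0)) abort("`A` must be finite and non-negative.")
  if (max(abs(A - t(A))) > 1e-12 * max(1, max(A))) abort("`A` must be symmetric.")
  A
}

ds_start <- function(n, perturbation) {
  x <- rep(1, n)
  if (perturbation > 0 && n > 1L) {
    x <- x + perturbation * seq(0, 1, length.out = n)
  }
  x / sum(x)
}

#' Replicator dynamics on the simplex
#'
#' Finds a local maximizer of the quadratic form `x' A x` over the standard
#' simplex by iterating `x_i <- x_i (A x)_i / (x' A x)`. For symmetric
#' non-negative `A` the objective is non-decreasing and every iterate stays on
#' the simplex (the iterate is renormalized each step to absorb floating-point
#' drift). Iteration stops when the Euclidean distance between consecutive
#' iterates falls below `epsilon` or after `max_iterations` (with a warning).
#'
#' The default start is the barycenter of the simplex with a tiny
#' deterministic tie-breaking offset (see [ds_config()]).
#'
#' If the objective is zero at some iterate (isolated node set, no cohesive
#' structure) a classed error `fibersets_no_cohesion` is signalled; callers
#' such as [ds_peel()] catch it.
#'
#' @param A Symmetric non-negative affinity matrix with zero diagonal.
#' @param x0 Optional start vector on the simplex; used exactly as given.
#' @param config A [ds_config()].
#' @param trace Keep the per-iteration objective sequence (default `FALSE`).
#' @return A list with elements `x` (converged characteristic vector),
#'   `objective` (`x' A x` on the unregularized matrix), `iterations`,
#'   `converged`, `max_sum_deviation` and `min_entry` (worst simplex
#'   violations seen across all iterates, before/after the renormalization
#'   guard), and `objective_trace` when `trace = TRUE`.
#' @export
replicator_dynamics <- function(A, x0 = NULL, config = ds_config(),
                                trace = FALSE) {
  A <- check_affinity(A)
  n <- nrow(A)
  if (is.null(x0)) {
    x <- ds_start(n, config$perturbation)
  } else {
    x <- as.numeric(x0)
    if (length(x) != n) abort("`x0` must have length nrow(A).")
    if (any(x < 0) || abs(sum(x) - 1) > 1e-8) abort("`x0` must lie on the simplex.")
  }
  M <- if (config$regularization > 0) A + diag(config$regularization, n) else A
  objs <- if (trace) numeric(0) else NULL
  max_sum_dev <- 0
  min_entry <- min(x)
  converged <- FALSE
  it <- 0L
  while (it < config$max_iterations) {
    it <- it + 1L
    Mx <- as.vector(M %*% x)
    q <- sum(x * Mx)
    if (trace) objs <- c(objs, q)
    if (q <= 0) {
      abort("No cohesive structure: x' A x is zero at the current iterate.",
            class = "fibersets_no_cohesion")
    }
    xn <- x * Mx / q
    max_sum_dev <- max(max_sum_dev, abs(sum(xn) - 1))
    xn <- xn / sum(xn)
    min_entry <- min(min_entry, min(xn))
    delta <- sqrt(sum((xn - x)^2))
    x <- xn
    if (delta < config$epsilon) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(paste0("Replicator dynamics did not converge within ",
                config$max_iterations, " iterations."))
  }
  out <- list(x = x, objective = as.numeric(crossprod(x, A %*% x)),
              iterations = it, converged = converged,
              max_sum_deviation = max_sum_dev, min_entry = min_entry)
  if (trace) out$objective_trace <- objs
  out
}

#' Support of a characteristic vector
#'
#' Indices participating in the dominant set: `{i : x_i > theta * max(x)}`.
#' With `theta = 0` this is the strict-positivity support.
#'
#' @param x Non-negative characteristic vector.
#' @param theta Threshold in `[0, 1]`; note `theta = 1` yields an empty set
#'   under the strict inequality.
#' @return Integer vector of indices.
#' @export
ds_support <- function(x, theta = 1e-5) {
  if (!is.numeric(theta) || theta < 0 || theta > 1) abort("`theta` must lie in [0, 1].")
  which(x > theta * max(x))
}

#' Cohesiveness of a cluster
#'
#' The objective value `x' A x`: internal coherence of the cluster described
#' by characteristic vector `x` over affinity matrix `A`. Non-negative, and
#' bounded above by the largest off-diagonal affinity.
#'
#' @param x Characteristic vector.
#' @param A Affinity matrix of matching dimension.
#' @return Scalar `x' A x`.
#' @export
cohesiveness <- function(x, A) {
  A <- as.matrix(A)
  if (length(x) != nrow(A)) abort("Dimensions of `x` and `A` disagree.")
  as.numeric(crossprod(x, A %*% x))
}

#' Extract all dominant sets by peeling
#'
#' Repeatedly runs replicator dynamics from the (tie-broken) barycenter on
#' the affinity submatrix of the not-yet-clustered nodes, extracts the
#' support as a cluster, removes its members, and continues until fewer than
#' two nodes remain or no cohesive structure is left. The affinity matrix is
#' computed once; peeling deletes rows/columns without re-normalizing.
#' Leftover nodes are emitted as residual singleton clusters so every input
#' index appears in exactly one cluster.
#'
#' @param A Symmetric non-negative affinity matrix with zero diagonal.
#' @param config A [ds_config()].
#' @param groups Optional group label per node (e.g. the subject of each
#'   bundle in cross-subject clustering). Nodes of one group are expected to
#'   have zero mutual affinity, which provably excludes them from sharing a
#'   dominant set; if the thresholded support still contains several rows of
#'   one group (slowly decaying transients can sit above `theta * max(x)`
#'   when the epsilon stop fires first), only the row with the largest
#'   characteristic weight per group is extracted and the others stay in the
#'   pool for later peels.
#' @return A tibble of class `ds_partition` with one row per cluster:
#'   `cluster` (extraction rank), `members` (list of index vectors), `x`
#'   (list of characteristic vectors over the members), `cohesiveness`,
#'   `size`, and `residual` (singletons emitted after peeling stopped).
#' @export
ds_peel <- function(A, config = ds_config(), groups = NULL) {
  A <- check_affinity(A)
  if (!is.null(groups) && length(groups) != nrow(A)) {
    abort("`groups` must have one label per node.")
  }
  remaining <- seq_len(nrow(A))
  rows <- list()
  while (length(remaining) >= 2L) {
    sub <- A[remaining, remaining, drop = FALSE]
    rd <- tryCatch(replicator_dynamics(sub, config = config),
                   fibersets_no_cohesion = function(e) NULL)
    if (is.null(rd)) break
    s <- ds_support(rd$x, config$theta)
    if (!is.null(groups)) {
      g <- groups[remaining[s]]
      if (anyDuplicated(g)) {
        keep <- unlist(lapply(split(seq_along(s), g), function(idx) {
          idx[which.max(rd$x[s][idx])]
        }), use.names = FALSE)
        s <- s[sort(keep)]
      }
    }
    rows[[length(rows) + 1L]] <- tibble(
      members = list(remaining[s]),
      x = list(rd$x[s] / sum(rd$x[s])),
      cohesiveness = rd$objective,
      residual = FALSE)
    remaining <- remaining[-s]
  }
  for (i in remaining) {
    rows[[length(rows) + 1L]] <- tibble(
      members = list(i), x = list(1), cohesiveness = 0, residual = TRUE)
  }
  out <- bind_rows(rows)
  out <- tibble::add_column(out, cluster = seq_len(nrow(out)), .before = 1L)
  out$size <- lengths(out$members)
  attr(out, "n") <- nrow(A)
  class(out) <- c("ds_partition", class(out))
  out
}

#' Per-item cluster labels from a dominant-set partition
#'
#' @param partition A `ds_partition` tibble from [ds_peel()].
#' @param n Number of items (defaults to the partition's `n` attribute).
#' @return Integer vector of cluster labels (extraction ranks).
#' @export
partition_labels <- function(partition, n = attr(partition, "n")) {
  labels <- integer(n)
  for (i in seq_len(nrow(partition))) labels[partition$members[[i]]] <- partition$cluster[i]
  labels
}
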