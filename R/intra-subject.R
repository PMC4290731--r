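#' Stage 1: cluster one subject's fibers into bundles
#'
#' Resamples fibers to a common k if needed, builds the pairwise distance
#' matrix (symmetrized point-to-point by default — the fiber-space metric
#' most correlated with the landmark distance used at stage 2), converts it
#' to an exponential affinity with `sigma = max`, and extracts all dominant
#' sets by peeling. Cohesiveness is recorded per cluster in extraction order;
#' a medoid fiber is computed for every non-residual cluster.
#'
#' @param tract A tractogram tibble with at least 2 fibers (one subject).
#' @param k Samples per fiber (default 12).
#' @param metric Stage-1 fiber metric, `"pp"` (default) or `"smp"`.
#' @param config A [ds_config()].
#' @return An object of class `subject_clustering`: a list with `clusters`
#'   (tibble: `cluster`, `members`, `size`, `cohesiveness`, `residual`,
#'   `medoid`, `kept`), `assignment` (per-fiber cluster label), `distance`
#'   (the N x N metric matrix), `sigma`, `subject_id`, `fiber_id`, `metric`,
#'   `k` and `config`. Selection (`kept`) starts all-kept for non-residual
#'   clusters; apply [select_clusters()] to prune.
#' @export
cluster_fibers <- function(tract, k = 12, metric = c("pp", "smp"),
                           config = ds_config()) {
  metric <- match.arg(metric)
  check_tractogram(tract)
  if (nrow(tract) < 2L) abort("Need at least 2 fibers to cluster.")
  if ("subject_id" %in% names(tract) && length(unique(tract$subject_id)) > 1L) {
    abort("`cluster_fibers()` works on a single subject; split the cohort first.")
  }
  ks <- unique(map_int(tract$points, nrow))
  if (length(ks) != 1L || ks[1] != k) tract <- resample_fibers(tract, k)
  D <- fiber_distance_matrix(tract, metric = metric)
  A <- build_affinity(D, sigma = "max")
  part <- ds_peel(A, config = config)
  clusters <- mutate(
    part,
    medoid = map_int(.data$members, medoid_index, D = D),
    kept = !.data$residual)
  out <- list(
    clusters = as_tibble(clusters),
    assignment = partition_labels(part),
    distance = D,
    sigma = attr(A, "sigma"),
    subject_id = if ("subject_id" %in% names(tract)) tract$subject_id[1] else NA_character_,
    fiber_id = tract$fiber_id,
    metric = metric,
    k = k,
    config = config,
    selection = NULL)
  class(out) <- "subject_clustering"
  out
}

#' @export
print.subject_clustering <- function(x, ...) {
  cl <- x$clusters
  cat("<subject_clustering> subject:", x$subject_id,
      "| fibers:", length(x$assignment),
      "| clusters:", sum(!cl$residual),
      "(+", sum(cl$residual), "residual ) | kept:", sum(cl$kept), "\n")
  invisible(x)
}

#' Detrend a cohesiveness curve
#'
#' Cohesiveness declines with extraction rank roughly following a smooth
#' trend; a least-squares second-order polynomial in rank is subtracted so
#' that outlying clusters stand out as residuals around zero. With fewer
#' than 3 values a quadratic cannot be fitted and centered values are
#' returned instead.
#'
#' @param values Cohesiveness values in extraction order.
#' @return Residuals after removing the fitted quadratic trend.
#' @export
normalize_cohesiveness <- function(values) {
  values <- as.numeric(values)
  m <- length(values)
  if (m < 3L) return(values - mean(values))
  rank <- seq_len(m)
  fit <- lm(values ~ rank + I(rank^2))
  as.numeric(stats::residuals(fit))
}

#' Prune weak clusters by cohesiveness statistics
#'
#' Two-step selection mirroring how late, incoherent dominant sets are
#' discarded: (1) drop residual singletons and the last
#' `ceiling(tail_fraction * M)` non-residual clusters by extraction rank
#' (the tail of the cohesiveness curve); (2) detrend the survivors'
#' cohesiveness with [normalize_cohesiveness()], model the residuals as
#' centered Gaussian noise with sigma estimated from the data (mean pinned
#' at 0), and reject clusters in the negative tail at one-sided confidence
#' `alpha` (residual < -z_(1-alpha) * sigma-hat).
#'
#' @param clustering A `subject_clustering` from [cluster_fibers()].
#' @param tail_fraction Fraction of late clusters to drop (default 0.05).
#' @param alpha One-sided rejection level for the negative residual tail
#'   (default 0.05; `alpha -> 0` disables step 2).
#' @return The clustering with its `kept` column updated and a `selection`
#'   record (`residuals`, `sigma_hat`, `threshold`).
#' @export
select_clusters <- function(clustering, tail_fraction = 0.05, alpha = 0.05) {
  if (!inherits(clustering, "subject_clustering")) {
    abort("`clustering` must come from cluster_fibers().")
  }
  if (tail_fraction < 0 || tail_fraction >= 1) abort("`tail_fraction` must be in [0, 1).")
  if (alpha < 0 || alpha >= 0.5) abort("`alpha` must be in [0, 0.5).")
  cl <- clustering$clusters
  core <- which(!cl$residual)
  m <- length(core)
  kept <- rep(FALSE, nrow(cl))
  n_tail <- if (tail_fraction > 0) ceiling(tail_fraction * m) else 0L
  survivors <- if (n_tail > 0) head(core, m - n_tail) else core
  kept[survivors] <- TRUE
  res <- sigma_hat <- threshold <- NULL
  if (length(survivors) > 0L && alpha > 0) {
    res <- normalize_cohesiveness(cl$cohesiveness[survivors])
    sigma_hat <- sqrt(mean(res^2))          # mean pinned at 0
    # below machine-precision scale the residuals are fit round-off, not noise
    floor_ <- 1e-10 * max(abs(cl$cohesiveness[survivors]), 1e-300)
    if (sigma_hat > floor_) {
      threshold <- -qnorm(1 - alpha) * sigma_hat
      kept[survivors[res < threshold]] <- FALSE
    }
  }
  clustering$clusters$kept <- kept
  clustering$selection <- list(
    tail_fraction = tail_fraction, alpha = alpha, n_tail_dropped = n_tail,
    residuals = res, sigma_hat = sigma_hat, threshold = threshold,
    survivors = survivors)
  clustering
}

#' Medoid of a cluster
#'
#' The member minimizing the sum of distances to all other members; ties are
#' broken by the lowest index. Invariant to member ordering.
#'
#' @param members Integer vector of member indices (non-empty).
#' @param D Full pairwise distance matrix.
#' @return The medoid index (an element of `members`).
#' @export
medoid_index <- function(members, D) {
  members <- sort(as.integer(members))
  if (length(members) == 0L) abort("Empty member set.")
  if (length(members) == 1L) return(members)
  rowsum_ <- rowSums(D[members, members, drop = FALSE])
  members[which.min(rowsum_)]
}

#' Medoid streamlines of kept bundles
#'
#' @param clustering A (selected) `subject_clustering`.
#' @param tract The tractogram it was fitted on (used for the fiber
#'   geometry; fibers are resampled to the clustering's k if needed).
#' @return A tibble with one row per kept bundle: `subject_id`, `bundle_id`
#'   (extraction rank), `cohesiveness`, `medoid_fiber` (row index in
#'   `tract`), `points`.
#' @export
bundle_medoids <- function(clustering, tract) {
  if (!inherits(clustering, "subject_clustering")) {
    abort("`clustering` must come from cluster_fibers().")
  }
  check_tractogram(tract)
  ks <- unique(map_int(tract$points, nrow))
  if (length(ks) != 1L || ks[1] != clustering$k) {
    tract <- resample_fibers(tract, clustering$k)
  }
  cl <- filter(clustering$clusters, .data$kept)
  tibble(
    subject_id = clustering$subject_id,
    bundle_id = cl$cluster,
    cohesiveness = cl$cohesiveness,
    medoid_fiber = cl$medoid,
    points = tract$points[cl$medoid])
}

#' @export
tidy.subject_clustering <- function(x, ...) {
  tibble(
    subject_id = x$subject_id,
    fiber_id = x$fiber_id,
    cluster = x$assignment,
    kept = x$clusters$kept[x$assignment],
    cohesiveness = x$clusters$cohesiveness[x$assignment])
}

#' @export
glance.subject_clustering <- function(x, ...) {
  cl <- x$clusters
  tibble(
    subject_id = x$subject_id,
    n_fibers = length(x$assignment),
    n_clusters = sum(!cl$residual),
    n_residual = sum(cl$residual),
    n_kept = sum(cl$kept),
    mean_cohesiveness = mean(cl$cohesiveness[!cl$residual]),
    sigma = x$sigma,
    metric = x$metric,
    k = x$k)
}

#' Cohesiveness-curve plot for a subject clustering
#'
#' Cohesiveness by extraction rank with the fitted quadratic trend and, when
#' [select_clusters()] has been applied, the one-sided rejection band;
#' dropped clusters are marked.
#'
#' @param object A `subject_clustering`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subject_clustering <- function(object, ...) {
  cl <- filter(object$clusters, !.data$residual)
  df <- tibble(rank = cl$cluster, cohesiveness = cl$cohesiveness, kept = cl$kept)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$cohesiveness)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(color = .data$kept)) +
    ggplot2::labs(x = "extraction rank", y = "cohesiveness  x'Ax",
                  color = "kept") +
    ggplot2::theme_minimal()
  if (nrow(df) >= 3L) {
    fit <- lm(cohesiveness ~ rank + I(rank^2), data = df)
    df$trend <- predict(fit)
    p <- p + ggplot2::geom_line(data = df, ggplot2::aes(y = .data$trend),
                                linetype = "dashed", color = "steelblue")
    if (!is.null(object$selection$threshold)) {
      p <- p + ggplot2::geom_line(
        data = mutate(df, band = .data$trend + object$selection$threshold),
        ggplot2::aes(y = .data$band), linetype = "dotted", color = "darkred")
    }
  }
  p
}
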