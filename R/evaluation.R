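#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions
#' (Hubert-Arabie form, computed from the contingency table). Equals 1 iff
#' the partitions are identical up to relabeling; the expected value under
#' random labellings is 0.
#'
#' @param truth,pred Label vectors of equal length (>= 2).
#' @return A scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(truth, pred) {
  if (length(truth) != length(pred)) abort("Label vectors must have equal length.")
  if (length(truth) < 2L) abort("Need at least 2 items.")
  ct <- table(truth, pred)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(ct))
  sum_a <- sum(comb2(rowSums(ct)))
  sum_b <- sum(comb2(colSums(ct)))
  total <- comb2(length(truth))
  expected <- sum_a * sum_b / total
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maxidx - expected)
}

#' Completeness of a clustering
#'
#' Conditional-entropy completeness: `1 - H(pred | truth) / H(pred)`,
#' defined as 1 when `H(pred) = 0`. It reaches 1 exactly when every
#' ground-truth class is fully contained in a single predicted cluster
#' (members of one bundle are never split), and 0 when knowing the class
#' carries no information about the cluster. The entropy base cancels in the
#' ratio.
#'
#' @param truth,pred Label vectors of equal length.
#' @return A scalar in `[0, 1]`.
#' @export
completeness_score <- function(truth, pred) {
  if (length(truth) != length(pred)) abort("Label vectors must have equal length.")
  n <- length(truth)
  ct <- table(truth, pred)
  pk <- colSums(ct) / n
  hk <- -sum(ifelse(pk > 0, pk * log(pk), 0))
  if (hk == 0) return(1)
  joint <- ct / n
  pc <- rowSums(ct) / n
  hkc <- -sum(ifelse(joint > 0, joint * log(sweep(joint, 1L, pc, "/")), 0))
  1 - hkc / hk
}

#' Pair-counting completeness
#'
#' A pair-counting variant of completeness for cross-checking: among all
#' item pairs sharing a ground-truth class, the fraction also sharing a
#' predicted cluster. 1 when no true class is ever split; returns `NA` when
#' the truth has no co-classified pair.
#'
#' @inheritParams completeness_score
#' @return A scalar in `[0, 1]`, or `NA`.
#' @export
pair_completeness <- function(truth, pred) {
  if (length(truth) != length(pred)) abort("Label vectors must have equal length.")
  ct <- table(truth, pred)
  comb2 <- function(x) x * (x - 1) / 2
  same_truth <- sum(comb2(rowSums(ct)))
  if (same_truth == 0) return(NA_real_)
  sum(comb2(ct)) / same_truth
}

#' Clustering evaluation report
#'
#' @param truth,pred Label vectors of equal length.
#' @return One-row tibble with `ari`, `completeness`, `pair_completeness`,
#'   `n_items`, `n_true_clusters`, `n_pred_clusters`.
#' @export
evaluation_report <- function(truth, pred) {
  tibble(
    ari = adjusted_rand_index(truth, pred),
    completeness = completeness_score(truth, pred),
    pair_completeness = pair_completeness(truth, pred),
    n_items = length(truth),
    n_true_clusters = length(unique(truth)),
    n_pred_clusters = length(unique(pred)))
}

#' Correlation between fiber-space and landmark-space metrics
#'
#' Computes all pairwise fiber distances under the two streamline metrics
#' (symmetrized mean closest point, symmetrized point-to-point) and the two
#' landmark metrics (min-landmark, full landmark) and reports the Pearson
#' correlation of each streamline/landmark pairing over the fiber pairs,
#' plus binned 2-D histograms. The landmark encoding that best preserves
#' streamline-space similarity is the one to use for cross-subject
#' matching; the full landmark distance paired with the point-to-point
#' distance is expected to correlate most.
#'
#' @param tract A tractogram tibble (>= 10 fibers) resampled to a common k
#'   (resampled internally to `k` if not).
#' @param landmarks A landmark tibble for the same subject.
#' @param k Samples per fiber (default 12).
#' @param bins Bins per axis of the 2-D histograms (default 40).
#' @return An object of class `metric_correlation`: tibble with columns
#'   `stream_metric`, `landmark_metric`, `pearson` (NA with a `degenerate`
#'   flag when a distance set has zero variance), with the histogram list in
#'   attribute `histograms`.
#' @export
metric_correlation <- function(tract, landmarks, k = 12, bins = 40) {
  check_tractogram(tract)
  if (nrow(tract) < 10L) abort("Need at least 10 fibers.")
  ks <- unique(map_int(tract$points, nrow))
  if (length(ks) != 1L || ks[1] != k) tract <- resample_fibers(tract, k)
  up <- upper.tri(matrix(0, nrow(tract), nrow(tract)))
  stream <- list(
    smp = fiber_distance_matrix(tract, "smp")[up],
    pp = fiber_distance_matrix(tract, "pp")[up])
  Emin <- encode_fibers(tract, landmarks, "min")
  Efull <- encode_fibers(tract, landmarks, "full")
  land <- list(
    min_landmark = landmark_distance_matrix(Emin)[up],
    full_landmark = landmark_distance_matrix(Efull)[up])
  rows <- list(); hists <- list()
  for (sm in names(stream)) for (lm_ in names(land)) {
    a <- stream[[sm]]; b <- land[[lm_]]
    degenerate <- sd(a) == 0 || sd(b) == 0
    rows[[paste(sm, lm_)]] <- tibble(
      stream_metric = sm, landmark_metric = lm_,
      pearson = if (degenerate) NA_real_ else cor(a, b),
      degenerate = degenerate)
    hists[[paste(sm, lm_, sep = "_vs_")]] <- bin2d(a, b, bins)
  }
  out <- bind_rows(rows)
  attr(out, "histograms") <- hists
  class(out) <- c("metric_correlation", class(out))
  out
}

bin2d <- function(a, b, bins) {
  brk <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = bins + 1L)
  }
  ia <- cut(a, brk(a), include.lowest = TRUE, labels = FALSE)
  ib <- cut(b, brk(b), include.lowest = TRUE, labels = FALSE)
  counts <- matrix(0L, bins, bins)
  for (i in seq_along(ia)) counts[ia[i], ib[i]] <- counts[ia[i], ib[i]] + 1L
  list(counts = counts, breaks_stream = brk(a), breaks_landmark = brk(b))
}

#' Paired 2-D histograms of streamline vs landmark distances
#'
#' @param object A `metric_correlation`.
#' @param ... Unused.
#' @return A faceted ggplot of the four metric pairings.
#' @export
autoplot.metric_correlation <- function(object, ...) {
  hists <- attr(object, "histograms")
  dfs <- purrr::imap(hists, function(h, nm) {
    mids <- function(b) (b[-1] + b[-length(b)]) / 2
    g <- tidyr::expand_grid(i = seq_len(nrow(h$counts)),
                            j = seq_len(ncol(h$counts)))
    tibble(pairing = nm,
           stream = mids(h$breaks_stream)[g$i],
           landmark = mids(h$breaks_landmark)[g$j],
           count = as.integer(h$counts[cbind(g$i, g$j)]))
  })
  df <- filter(bind_rows(dfs), .data$count > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stream, y = .data$landmark,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~pairing, scales = "free") +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = "streamline-space distance (mm)",
                  y = "landmark-space distance (mm)") +
    ggplot2::theme_minimal()
}
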