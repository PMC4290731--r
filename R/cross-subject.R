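#' Encode per-subject bundle medoids in landmark space
#'
#' Each medoid streamline is mapped to its full landmark encoding using the
#' landmarks of its own subject. Because the encoding stores only
#' point-to-landmark distances, subjects never need to share a coordinate
#' frame.
#'
#' @param medoids A tibble of medoid fibers (`subject_id`, `bundle_id`,
#'   `points`), e.g. row-bound outputs of [bundle_medoids()].
#' @param landmarks A multi-subject landmark tibble (`subject_id`, `label`,
#'   `x`, `y`, `z`); each subject must carry the same labels in the same
#'   order.
#' @param encoding `"full"` (default) or `"min"`.
#' @return The `medoids` tibble with an `encoding` list-column added;
#'   attributes `k` and `n_landmarks` record the encoding geometry.
#' @export
encode_medoids <- function(medoids, landmarks, encoding = c("full", "min")) {
  encoding <- match.arg(encoding)
  check_tractogram(medoids)
  if (!"subject_id" %in% names(medoids)) abort("`medoids` needs a `subject_id` column.")
  if (!"subject_id" %in% names(landmarks)) abort("`landmarks` needs a `subject_id` column.")
  subjects <- unique(medoids$subject_id)
  label_order <- NULL
  enc_rows <- vector("list", nrow(medoids))
  k <- n <- NULL
  for (s in subjects) {
    L <- filter(as_tibble(landmarks), .data$subject_id == s)
    if (nrow(L) == 0L) abort(paste0("No landmarks for subject ", s, "."))
    if (is.null(label_order)) {
      label_order <- L$label
    } else if (!identical(L$label, label_order)) {
      abort(paste0("Landmark label order for subject ", s,
                   " differs from the cohort order."))
    }
    idx <- which(medoids$subject_id == s)
    E <- encode_fibers(medoids[idx, ], landmark_set(L), encoding = encoding)
    k <- attr(E, "k"); n <- attr(E, "n")
    for (j in seq_along(idx)) enc_rows[[idx[j]]] <- E[j, ]
  }
  out <- mutate(as_tibble(medoids), encoding = enc_rows)
  attr(out, "k") <- k
  attr(out, "n_landmarks") <- n
  attr(out, "encoding_type") <- encoding
  out
}

#' Block affinity matrix across subjects
#'
#' Builds the affinity over the union of all subjects' bundles. For bundles
#' of different subjects the affinity is `exp(-d_l / sigma_kh)` with `d_l`
#' the (flip-minimized) landmark distance and `sigma_kh` a per-subject-pair
#' normalization (default: the maximum landmark distance within that block;
#' `sigma_scope = "global"` uses one maximum over all cross-subject pairs).
#' Same-subject entries and the diagonal are forced to zero, which provably
#' prevents two bundles of one subject from sharing a dominant set — the
#' resulting matrix has the characteristic block shape with zero diagonal
#' blocks. Degenerate all-zero blocks fall back to `sigma = 1`.
#'
#' @param encoded Output of [encode_medoids()] (>= 2 subjects, each >= 1
#'   bundle; all encodings the same length).
#' @param sigma_scope `"per_block"` (default) or `"global"`.
#' @return An object of class `cross_affinity`: list with `values` (M x M
#'   matrix), `subject_of`, `bundle_of`, `block_sigmas` (tibble), and
#'   `distance` (the landmark distance matrix).
#' @export
build_block_affinity <- function(encoded, sigma_scope = c("per_block", "global")) {
  sigma_scope <- match.arg(sigma_scope)
  if (!"encoding" %in% names(encoded)) abort("Run encode_medoids() first.")
  subjects <- unique(encoded$subject_id)
  if (length(subjects) < 2L) abort("Cross-subject matching needs at least 2 subjects.")
  lens <- lengths(encoded$encoding)
  if (length(unique(lens)) != 1L) {
    bad <- unique(encoded$subject_id[lens != lens[1]])
    abort(paste0("Encoding length mismatch between subjects: ",
                 paste(unique(c(encoded$subject_id[1], bad)), collapse = ", "),
                 ". All subjects must share k and the landmark set size."))
  }
  E <- do.call(rbind, encoded$encoding)
  attr(E, "encoding") <- attr(encoded, "encoding_type") %||% "full"
  k <- attr(encoded, "k")
  Dl <- landmark_distance_matrix(E, k = k)
  M <- nrow(E)
  subject_of <- encoded$subject_id
  A <- matrix(0, M, M)
  sig_rows <- list()
  cross_mask <- outer(subject_of, subject_of, "!=")
  # distances at round-off scale are "identical encodings": normalizing by
  # them would amplify float noise into e^-1 contrast, so fall back to 1
  degenerate_tol <- 1e-9 * max(abs(E), 1)
  global_sigma <- if (any(cross_mask)) max(Dl[cross_mask]) else 0
  if (global_sigma <= degenerate_tol) global_sigma <- 1
  for (a in seq_along(subjects)) {
    for (b in seq_along(subjects)) {
      if (a >= b) next
      ia <- which(subject_of == subjects[a])
      ib <- which(subject_of == subjects[b])
      blk <- Dl[ia, ib, drop = FALSE]
      sigma <- if (sigma_scope == "global") global_sigma else max(blk)
      if (sigma <= degenerate_tol) sigma <- 1
      A[ia, ib] <- exp(-blk / sigma)
      A[ib, ia] <- t(exp(-blk / sigma))
      sig_rows[[length(sig_rows) + 1L]] <- tibble(
        subject_a = subjects[a], subject_b = subjects[b], sigma = sigma)
    }
  }
  diag(A) <- 0
  out <- list(values = A, subject_of = subject_of,
              bundle_of = encoded$bundle_id,
              block_sigmas = bind_rows(sig_rows),
              sigma_scope = sigma_scope,
              distance = Dl)
  class(out) <- "cross_affinity"
  out
}

#' @export
print.cross_affinity <- function(x, ...) {
  cat("<cross_affinity>", length(x$subject_of), "bundles,",
      length(unique(x$subject_of)), "subjects, sigma scope:", x$sigma_scope, "\n")
  invisible(x)
}

#' Heatmap of the cross-subject block affinity
#'
#' @param object A `cross_affinity`.
#' @param ... Unused.
#' @return A ggplot object showing the block structure (zero diagonal
#'   blocks, cross-subject similarities off-diagonal).
#' @export
autoplot.cross_affinity <- function(object, ...) {
  M <- nrow(object$values)
  df <- tidyr::expand_grid(row = seq_len(M), col = seq_len(M))
  df$affinity <- as.vector(object$values[cbind(df$row, df$col)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$affinity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "affinity") +
    ggplot2::theme_minimal()
}

#' Stage 2: cluster bundles across subjects
#'
#' Runs dominant-set peeling on the block affinity. Because same-subject
#' affinities are zero, no extracted cluster can contain two bundles of the
#' same subject (asserted anyway). Clusters are flagged `complete` when they
#' span every subject.
#'
#' @param affinity A `cross_affinity` from [build_block_affinity()].
#' @param config A [ds_config()].
#' @return An object of class `cross_clustering`: tibble with one row per
#'   cluster — `cluster`, `members` (list-tibble of `subject_id`,
#'   `bundle_id`), `n_members`, `complete`, `cohesiveness`, `residual` —
#'   with attributes `n_subjects` and `subjects`.
#' @export
cluster_bundles <- function(affinity, config = ds_config()) {
  if (!inherits(affinity, "cross_affinity")) {
    abort("`affinity` must come from build_block_affinity().")
  }
  part <- ds_peel(affinity$values, config = config,
                  groups = affinity$subject_of)
  subjects <- unique(affinity$subject_of)
  members <- map(part$members, function(idx) {
    sub <- affinity$subject_of[idx]
    if (anyDuplicated(sub)) {
      abort("Internal error: a cross cluster contains two bundles of one subject.")
    }
    tibble(subject_id = sub, bundle_id = affinity$bundle_of[idx], index = idx)
  })
  out <- tibble(
    cluster = part$cluster,
    members = members,
    n_members = lengths(part$members),
    complete = lengths(part$members) == length(subjects),
    cohesiveness = part$cohesiveness,
    residual = part$residual)
  attr(out, "n_subjects") <- length(subjects)
  attr(out, "subjects") <- subjects
  class(out) <- c("cross_clustering", class(out))
  out
}

#' Keep only clusters spanning (at least) a given number of subjects
#'
#' The default keeps clusters containing exactly one bundle from every
#' subject; `min_subjects` relaxes the requirement to "at least q subjects".
#' Extraction order is preserved.
#'
#' @param clusters A `cross_clustering` from [cluster_bundles()].
#' @param n_subjects Number of subjects in the cohort (defaults to the
#'   attribute recorded at clustering time).
#' @param min_subjects Minimum member count to keep (default `n_subjects`,
#'   i.e. complete clusters only).
#' @return The filtered `cross_clustering`.
#' @export
select_complete <- function(clusters, n_subjects = attr(clusters, "n_subjects"),
                            min_subjects = n_subjects) {
  if (is.null(n_subjects)) abort("Provide `n_subjects`.")
  keep <- clusters$n_members >= min_subjects
  out <- clusters[keep, , drop = FALSE]
  attr(out, "n_subjects") <- n_subjects
  attr(out, "subjects") <- attr(clusters, "subjects")
  class(out) <- unique(c("cross_clustering", class(out)))
  out
}

#' @export
tidy.cross_clustering <- function(x, ...) {
  out <- tidyr::unnest(tibble(cluster = x$cluster,
                              complete = x$complete,
                              cohesiveness = x$cohesiveness,
                              members = x$members), "members")
  select(out, "cluster", "subject_id", "bundle_id", "complete", "cohesiveness")
}

#' @export
glance.cross_clustering <- function(x, ...) {
  tibble(
    n_clusters = nrow(x),
    n_complete = sum(x$complete),
    n_subjects = attr(x, "n_subjects") %||% NA_integer_,
    mean_cohesiveness = mean(x$cohesiveness[!x$residual]))
}
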