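#' Landmark sets
#'
#' A landmark set is a tibble with columns `label` (ROI identifier), `x`,
#' `y`, `z` (world mm). The label order defines the encoding order and must
#' be identical across all subjects of a cohort; [encode_fibers()] relies on
#' it. A `subject_id` column may be present in multi-subject tables.
#'
#' @param df Data frame with columns `label`, `x`, `y`, `z` (optionally
#'   `subject_id`).
#' @return A validated landmark tibble.
#' @export
landmark_set <- function(df) {
  df <- as_tibble(df)
  need <- c("label", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("Missing landmark column(s): ", paste(miss, collapse = ", ")))
  if (nrow(df) < 1L) abort("A landmark set needs at least one landmark.")
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    abort("Landmark coordinates must be finite.")
  }
  df
}

landmark_coords <- function(landmarks) {
  landmarks <- landmark_set(landmarks)
  cbind(x = landmarks$x, y = landmarks$y, z = landmarks$z)
}

#' Landmarks from a labeled volume
#'
#' For each requested label, the landmark is the unweighted center of gravity
#' of all voxels carrying that label, mapped to world mm through the affine.
#' Voxel indices are treated as 0-based grid coordinates, the NIfTI
#' convention for voxel-to-world affines.
#'
#' @param label_volume 3D integer array of ROI labels.
#' @param affine 4 x 4 voxel-to-world matrix (default identity).
#' @param label_ids Ordered vector of label values to extract; the output
#'   preserves this order. Every id must occur in the volume.
#' @return A landmark tibble (`label`, `x`, `y`, `z`).
#' @export
landmarks_from_labels <- function(label_volume, affine = diag(4), label_ids) {
  if (length(dim(label_volume)) != 3L) abort("`label_volume` must be a 3D array.")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) abort("`affine` must be a 4 x 4 matrix.")
  rows <- lapply(label_ids, function(id) {
    idx <- which(label_volume == id, arr.ind = TRUE)
    if (nrow(idx) == 0L) {
      abort(paste0("Label ", id, " does not occur in the volume."))
    }
    vox <- colMeans(idx) - 1  # 0-based voxel center of gravity
    world <- as.vector(affine %*% c(vox, 1))[1:3]
    tibble(label = id, x = world[1], y = world[2], z = world[3])
  })
  landmark_set(bind_rows(rows))
}

#' Encode fibers by their distances to landmarks
#'
#' Two space-invariant fiber descriptors built from point-to-landmark
#' Euclidean distances. Because every entry is a distance between two points,
#' both encodings are unchanged when fiber and landmarks are moved by the
#' same rigid transform — the property that makes cross-subject matching
#' registration-free.
#'
#' * `"full"` — every sample point is mapped against every landmark: a
#'   `k * n` vector in point-major order (all n landmark distances for point
#'   1, then point 2, ...).
#' * `"min"` — one value per landmark: the minimum distance from the landmark
#'   to any point of the fiber (an `n` vector, orientation-invariant by
#'   construction).
#'
#' @param tract A tractogram tibble with fibers resampled to a common k.
#' @param landmarks A landmark tibble for the same subject (see
#'   [landmark_set()]).
#' @param encoding `"full"` (default) or `"min"`.
#' @return An N x (k*n) or N x n numeric matrix with attributes `k`, `n` and
#'   `encoding`.
#' @export
encode_fibers <- function(tract, landmarks, encoding = c("full", "min")) {
  encoding <- match.arg(encoding)
  check_tractogram(tract)
  L <- landmark_coords(landmarks)
  k <- fiber_k(tract)
  E <- t(vapply(tract$points, function(p) {
    cd <- cross_dist(p, L)                    # k x n
    if (encoding == "full") as.vector(t(cd)) else apply(cd, 2L, min)
  }, numeric(if (encoding == "full") k * nrow(L) else nrow(L))))
  attr(E, "k") <- k
  attr(E, "n") <- nrow(L)
  attr(E, "encoding") <- encoding
  E
}

#' Reverse the point blocks of a full landmark encoding
#'
#' The encoding of a flipped fiber equals the original encoding with its k
#' point-blocks in reverse order; no distances need recomputing.
#'
#' @param E Encoding matrix (or single row vector) from
#'   [encode_fibers()] with `encoding = "full"`.
#' @param k Number of sample points per fiber.
#' @return The block-reversed encoding, same shape as the input.
#' @export
flip_encoding <- function(E, k = attr(E, "k")) {
  if (is.null(k)) abort("Provide `k` (sample points per fiber).")
  vec <- is.null(dim(E))
  if (vec) E <- matrix(E, nrow = 1L)
  n <- ncol(E) / k
  if (n != round(n)) abort("Encoding length is not a multiple of `k`.")
  idx <- as.vector(vapply(rev(seq_len(k)), function(b) ((b - 1L) * n + 1L):(b * n),
                          numeric(n)))
  out <- E[, idx, drop = FALSE]
  if (vec) out <- as.vector(out)
  out
}

#' Landmark distance between two encoded fibers
#'
#' Euclidean distance between landmark encodings, minimized over the flipped
#' orientation of the second fiber (streamlines carry no preferred
#' direction). For min-encodings the descriptor is already
#' orientation-invariant and the flip argument is unnecessary.
#'
#' @param e1,e2 Encoding vectors of equal length.
#' @param e2_flipped Encoding of the flipped second fiber; computed via
#'   [flip_encoding()] when `k` is given and omitted otherwise.
#' @param k Sample points per fiber (needed to derive `e2_flipped` for full
#'   encodings when it is not supplied).
#' @return Distance in mm.
#' @export
landmark_distance <- function(e1, e2, e2_flipped = NULL, k = NULL) {
  e1 <- as.numeric(e1); e2 <- as.numeric(e2)
  if (length(e1) != length(e2)) abort("Encodings must have equal length.")
  d <- sqrt(sum((e1 - e2)^2))
  if (is.null(e2_flipped) && !is.null(k)) e2_flipped <- flip_encoding(e2, k)
  if (!is.null(e2_flipped)) {
    e2_flipped <- as.numeric(e2_flipped)
    if (length(e2_flipped) != length(e1)) abort("Encodings must have equal length.")
    d <- min(d, sqrt(sum((e1 - e2_flipped)^2)))
  }
  d
}

#' Pairwise landmark distance matrix between encoded fibers
#'
#' @param E Encoding matrix (rows = fibers) from [encode_fibers()].
#' @param E2 Optional second encoding matrix for rectangular (cross-set)
#'   distances; defaults to `E`.
#' @param k Sample points per fiber; taken from the `encoding` attributes
#'   when present. Full encodings are compared under the flip-minimum.
#' @return Distance matrix `nrow(E)` x `nrow(E2)`.
#' @export
landmark_distance_matrix <- function(E, E2 = NULL, k = attr(E, "k")) {
  symmetric <- is.null(E2)
  if (symmetric) E2 <- E
  if (ncol(E) != ncol(E2)) abort("Encodings must have equal length.")
  D <- cross_dist(E, E2)
  full <- identical(attr(E, "encoding") %||% "full", "full")
  if (full) {
    if (is.null(k)) abort("Provide `k` for full encodings.")
    D <- pmin(D, cross_dist(E, flip_encoding(E2, k)))
  }
  if (symmetric) {
    D <- pmin(D, t(D))
    diag(D) <- 0
  }
  D
}
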