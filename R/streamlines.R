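#' Build a tractogram tibble from a list of streamlines
#'
#' A tractogram is an ordinary tibble with one row per streamline and a
#' `points` list-column holding an m x 3 numeric matrix of world-space
#' coordinates (mm) per fiber. All pipeline functions take and return this
#' shape, so calls chain with the pipe.
#'
#' @param points List of numeric matrices, each with 3 columns (x, y, z in mm)
#'   and at least 2 rows.
#' @param subject_id Optional subject identifier (recycled).
#' @param bundle Optional integer ground-truth / cluster label per fiber.
#' @param validate Check streamline invariants (finite coordinates, no
#'   zero-length segments). Default `TRUE`.
#'
#' @return A tibble with columns `subject_id` (if given), `fiber_id`,
#'   `bundle` (if given) and `points`.
#' @export
#' @examples
#' tractogram(list(cbind(0:2, 0, 0), cbind(0:3, 1, 0)))
tractogram <- function(points, subject_id = NULL, bundle = NULL,
                       validate = TRUE) {
  if (!is.list(points)) points <- list(points)
  points <- lapply(points, as_streamline_matrix)
  if (validate) {
    for (i in seq_along(points)) validate_streamline(points[[i]], i)
  }
  out <- tibble(fiber_id = seq_along(points), points = points)
  if (!is.null(bundle)) {
    out <- tibble::add_column(out, bundle = rep_len(bundle, nrow(out)),
                              .before = "points")
  }
  if (!is.null(subject_id)) {
    if (!is.character(subject_id) || any(!nzchar(subject_id))) {
      abort("`subject_id` must be a non-empty character value.")
    }
    out <- tibble::add_column(out, subject_id = rep_len(subject_id, nrow(out)),
                              .before = "fiber_id")
  }
  out
}

as_streamline_matrix <- function(p) {
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (ncol(p) != 3L) abort("Each streamline must be an m x 3 matrix.")
  colnames(p) <- c("x", "y", "z")
  p
}

validate_streamline <- function(p, i = NULL) {
  where <- if (is.null(i)) "" else paste0(" (fiber ", i, ")")
  if (nrow(p) < 2L) abort(paste0("A streamline needs at least 2 points", where, "."))
  if (!all(is.finite(p))) abort(paste0("Streamline coordinates must be finite", where, "."))
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (any(seg == 0)) {
    abort(paste0("Zero-length segment (repeated consecutive point)", where, "."))
  }
  invisible(p)
}

#' Convert a long point table to a tractogram
#'
#' @param df Data frame with columns `fiber_id`, `x`, `y`, `z` (optionally
#'   `subject_id` and `bundle`), points ordered within fiber.
#' @inheritParams tractogram
#' @return A tractogram tibble (see [tractogram()]).
#' @export
as_tractogram <- function(df, validate = TRUE) {
  df <- as_tibble(df)
  need <- c("fiber_id", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  keys <- intersect(c("subject_id", "fiber_id", "bundle"), names(df))
  nested <- df |>
    group_by(dplyr::across(dplyr::all_of(keys))) |>
    summarise(points = list(cbind(x = .data$x, y = .data$y, z = .data$z)),
              .groups = "drop")
  if (validate) purrr::walk(nested$points, validate_streamline)
  nested
}

#' Unnest a tractogram into one row per point
#'
#' @param tract A tractogram tibble.
#' @return Long tibble with `fiber_id`, `point_id`, `x`, `y`, `z` plus any
#'   identifier columns present in the input.
#' @export
streamline_points <- function(tract) {
  check_tractogram(tract)
  keys <- setdiff(names(tract), "points")
  rows <- purrr::map2(seq_len(nrow(tract)), tract$points, function(i, p) {
    out <- as_tibble(as.data.frame(p))
    out$point_id <- seq_len(nrow(p))
    out
  })
  tidyr::unnest(mutate(tract[keys], .pts = rows), ".pts") |>
    select(dplyr::all_of(keys), "point_id", "x", "y", "z")
}

check_tractogram <- function(tract, arg = "tract") {
  if (!is.data.frame(tract) || !"points" %in% names(tract)) {
    abort(paste0("`", arg, "` must be a tractogram tibble with a `points` column."))
  }
  invisible(tract)
}

#' Arc length of a streamline
#'
#' Sum of Euclidean segment lengths of the polyline, in mm.
#'
#' @param points An m x 3 coordinate matrix.
#' @return Length in mm (non-negative scalar).
#' @export
#' @examples
#' arc_length(cbind(c(0, 3), c(0, 4), c(0, 0))) # 5
arc_length <- function(points) {
  p <- as_streamline_matrix(points)
  if (nrow(p) < 2L) abort("arc_length() needs at least 2 points.")
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Annotate fibers with their arc length
#'
#' @param tract A tractogram tibble.
#' @return The input with a `length_mm` column added.
#' @export
fiber_lengths <- function(tract) {
  check_tractogram(tract)
  mutate(tract, length_mm = map_dbl(.data$points, arc_length))
}

#' Drop fibers shorter than a minimum arc length
#'
#' Short spurious streamlines (tracking noise near cortex) are removed before
#' clustering; 3 mm is the conventional cutoff. The boundary is inclusive:
#' a fiber exactly at `min_length_mm` is kept.
#'
#' @param tract A tractogram tibble.
#' @param min_length_mm Minimum arc length in mm (default 3).
#' @return The tractogram restricted to fibers with arc length >=
#'   `min_length_mm`, order preserved.
#' @export
filter_short_fibers <- function(tract, min_length_mm = 3) {
  check_tractogram(tract)
  if (!is.numeric(min_length_mm) || min_length_mm < 0) {
    abort("`min_length_mm` must be a non-negative number.")
  }
  keep <- map_dbl(tract$points, arc_length) >= min_length_mm
  tract[keep, , drop = FALSE]
}

#' Reverse the point order of a streamline
#'
#' Streamlines carry no preferred orientation, so every metric also considers
#' the flipped version of a fiber. `flip_streamline()` is an involution.
#'
#' @param points An m x 3 coordinate matrix.
#' @return The matrix with rows in reverse order.
#' @export
flip_streamline <- function(points) {
  p <- as_streamline_matrix(points)
  p[rev(seq_len(nrow(p))), , drop = FALSE]
}

#' Resample a streamline to k points equally spaced in arc length
#'
#' Each coordinate is interpolated with a cubic spline against the cumulative
#' chord-length parameter (linear interpolation for fibers with fewer than 4
#' points), the interpolant is densely evaluated to measure its arc length,
#' and k points are read off at equal arc-length spacing. First and last
#' output points coincide with the input endpoints.
#'
#' @param points An m x 3 coordinate matrix with at least 2 distinct points.
#' @param k Number of output samples (default 12, >= 2).
#' @param dense Number of dense evaluations used for the arc-length
#'   parameterization (default `max(20 * m, 200)`).
#' @return A k x 3 matrix.
#' @export
resample_streamline <- function(points, k = 12, dense = NULL) {
  p <- as_streamline_matrix(points)
  if (nrow(p) > 1L) {
    dup <- c(FALSE, rowSums(abs(p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])) == 0)
    p <- p[!dup, , drop = FALSE]
  }
  if (nrow(p) < 2L) abort("Cannot resample a fiber with fewer than 2 distinct points.")
  if (!is.numeric(k) || k < 2L) abort("`k` must be an integer >= 2.")
  k <- as.integer(k)
  s <- c(0, cumsum(sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))))
  if (s[length(s)] == 0) abort("Cannot resample a fiber with fewer than 2 distinct points.")
  dense <- dense %||% max(20L * nrow(p), 200L)
  method <- if (nrow(p) >= 4L) "spline" else "linear"
  tgrid <- seq(0, s[length(s)], length.out = dense)
  curve <- vapply(1:3, function(j) {
    if (method == "spline") {
      stats::spline(s, p[, j], xout = tgrid, method = "natural")$y
    } else {
      stats::approx(s, p[, j], xout = tgrid)$y
    }
  }, numeric(dense))
  arc <- c(0, cumsum(sqrt(rowSums((curve[-1L, , drop = FALSE] - curve[-dense, , drop = FALSE])^2))))
  target <- seq(0, arc[dense], length.out = k)
  tk <- stats::approx(arc, tgrid, xout = target, ties = "ordered")$y
  out <- vapply(1:3, function(j) {
    if (method == "spline") {
      stats::spline(s, p[, j], xout = tk, method = "natural")$y
    } else {
      stats::approx(s, p[, j], xout = tk)$y
    }
  }, numeric(k))
  out[1L, ] <- p[1L, ]
  out[k, ] <- p[nrow(p), ]
  colnames(out) <- c("x", "y", "z")
  out
}

#' Resample every fiber of a tractogram
#'
#' @param tract A tractogram tibble.
#' @param k Samples per fiber (default 12).
#' @return The tractogram with each `points` matrix replaced by its k-point
#'   resampling; the sample count is recorded in the `k` attribute.
#' @export
resample_fibers <- function(tract, k = 12) {
  check_tractogram(tract)
  out <- mutate(tract, points = map(.data$points, resample_streamline, k = k))
  attr(out, "k") <- as.integer(k)
  out
}

fiber_k <- function(tract) {
  ks <- unique(map_int(tract$points, nrow))
  if (length(ks) != 1L) {
    abort("Fibers have differing point counts; resample first with resample_fibers().")
  }
  ks
}

#' Partition fibers into left, right and inter-hemispheric sets
#'
#' A fiber with every point strictly on one side of the sagittal plane
#' `x = midplane_x` is assigned to that hemisphere; fibers crossing or
#' touching the plane are inter-hemispheric. The three groups partition the
#' input.
#'
#' @param tract A tractogram tibble.
#' @param midplane_x Sagittal midplane position in mm (default 0).
#' @return The tractogram with a `hemisphere` factor column
#'   (`left` / `right` / `inter`).
#' @export
split_hemispheres <- function(tract, midplane_x = 0) {
  check_tractogram(tract)
  if (!is.numeric(midplane_x) || !is.finite(midplane_x)) {
    abort("`midplane_x` must be a finite number.")
  }
  side <- map_chr(tract$points, function(p) {
    if (all(p[, 1] < midplane_x)) "left"
    else if (all(p[, 1] > midplane_x)) "right"
    else "inter"
  })
  mutate(tract, hemisphere = factor(side, levels = c("left", "right", "inter")))
}

#' @importFrom purrr map_chr walk
NULL
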