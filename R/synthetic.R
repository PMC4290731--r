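#' Configuration of the synthetic tractography cohort generator
#'
#' The generator emulates the study conditions of a multi-subject
#' tractography experiment inside a spherical volume: each subject carries
#' the same set of bundles (smooth centerlines with Gaussian cross-sectional
#' spread and per-point jitter), deformed by a per-subject rigid transform,
#' with landmarks co-transformed exactly, random point-order flips, and
#' ground-truth bundle labels.
#'
#' @param n_subjects Number of subjects (default 4).
#' @param n_bundles Bundles per subject (default 10).
#' @param fibers_per_bundle Streamlines per bundle (default 30).
#' @param sphere_radius Radius of the containing sphere in mm (default 50).
#' @param cross_section_sd Per-fiber perpendicular offset: a signed
#'   `N(0, sd)` magnitude along a uniformly random perpendicular direction
#'   (default 0.5 mm), so the offset norm is half-normal.
#' @param point_jitter_sd Per-point isotropic Gaussian jitter of the
#'   canonical fibers (default 0.1 mm).
#' @param flip_probability Probability that a fiber's point order is
#'   reversed (default 0.5).
#' @param rotation_deg,translation_mm Magnitude of the per-subject rigid
#'   transform: rotation angle drawn uniformly in `[0, rotation_deg]` about a
#'   random axis, translation components uniform in
#'   `[-translation_mm, translation_mm]` (defaults 10 deg, 5 mm).
#' @param subject_jitter_sd Per-point Gaussian noise added independently per
#'   subject after the rigid transform (default 0: subjects are exact rigid
#'   copies of the canonical fibers).
#' @param n_landmarks Landmarks per subject (default 50), laid out on a
#'   spherical shell at 0.9 radius and co-transformed with each subject.
#' @param centerline_points Samples per bundle centerline (default 30).
#' @param separation_factor Required minimum centerline separation in units
#'   of `cross_section_sd` (default 6); violating it raises an infeasible
#'   packing error.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 4, n_bundles = 10,
                             fibers_per_bundle = 30, sphere_radius = 50,
                             cross_section_sd = 0.5, point_jitter_sd = 0.1,
                             flip_probability = 0.5, rotation_deg = 10,
                             translation_mm = 5, subject_jitter_sd = 0,
                             n_landmarks = 50, centerline_points = 30,
                             separation_factor = 6, seed = 1) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_bundles = as.integer(n_bundles),
              fibers_per_bundle = as.integer(fibers_per_bundle),
              sphere_radius = sphere_radius,
              cross_section_sd = cross_section_sd,
              point_jitter_sd = point_jitter_sd,
              flip_probability = flip_probability,
              rotation_deg = rotation_deg, translation_mm = translation_mm,
              subject_jitter_sd = subject_jitter_sd,
              n_landmarks = as.integer(n_landmarks),
              centerline_points = as.integer(centerline_points),
              separation_factor = separation_factor,
              seed = as.integer(seed))
  with(cfg, {
    if (n_subjects < 1 || n_bundles < 1 || fibers_per_bundle < 1 || n_landmarks < 1) {
      abort("Counts must be >= 1.")
    }
    if (cross_section_sd < 0 || point_jitter_sd < 0 || subject_jitter_sd < 0) {
      abort("Standard deviations must be >= 0.")
    }
    if (flip_probability < 0 || flip_probability > 1) {
      abort("`flip_probability` must lie in [0, 1].")
    }
  })
  structure(cfg, class = "synthetic_config")
}

# Evaluate code under a fixed seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic near-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(m) {
  i <- seq_len(m)
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * (i - 0.5) / m
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(golden * i), y = r * sin(golden * i), z = z)
}

#' Rotation matrix about an axis
#'
#' @param axis 3-vector (normalized internally).
#' @param angle_deg Rotation angle in degrees.
#' @return 3 x 3 rotation matrix (Rodrigues formula).
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to a point matrix
#'
#' @param points m x 3 matrix.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation 3-vector in mm.
#' @return Transformed m x 3 matrix.
#' @export
apply_rigid <- function(points, rotation, translation = c(0, 0, 0)) {
  out <- as_streamline_matrix(points) %*% t(rotation)
  out <- sweep(out, 2L, -as.numeric(translation))
  colnames(out) <- c("x", "y", "z")
  out
}

# Draw a rigid transform of the configured magnitude from the current RNG.
draw_rigid <- function(rotation_deg, translation_mm) {
  axis <- rnorm(3)
  angle <- if (rotation_deg > 0) runif(1, 0, rotation_deg) else 0
  tr <- if (translation_mm > 0) runif(3, -translation_mm, translation_mm) else c(0, 0, 0)
  list(rotation = rotation_matrix(axis, angle), translation = tr,
       angle_deg = angle)
}

# Smooth bundle centerlines: tangential chords near Fibonacci anchors on an
# inner shell, with a mild quadratic bend. Draws directions from the RNG.
bundle_centerlines <- function(cfg) {
  R <- cfg$sphere_radius
  anchors <- 0.55 * R * fibonacci_sphere(cfg$n_bundles)
  lapply(seq_len(cfg$n_bundles), function(b) {
    a <- anchors[b, ]
    radial <- a / sqrt(sum(a^2))
    v <- rnorm(3); v <- v - sum(v * radial) * radial; v <- v / sqrt(sum(v^2))
    w <- c(radial[2] * v[3] - radial[3] * v[2],
           radial[3] * v[1] - radial[1] * v[3],
           radial[1] * v[2] - radial[2] * v[1])
    tt <- seq(-0.25 * R, 0.25 * R, length.out = cfg$centerline_points)
    curv <- runif(1, -0.012, 0.012)
    ctr <- outer(tt, v) + outer(curv * tt^2, w) +
      matrix(a, cfg$centerline_points, 3, byrow = TRUE)
    colnames(ctr) <- c("x", "y", "z")
    ctr
  })
}

min_centerline_separation <- function(centerlines) {
  B <- length(centerlines)
  if (B < 2L) return(Inf)
  m <- Inf
  for (a in seq_len(B - 1L)) for (b in (a + 1L):B) {
    m <- min(m, min(cross_dist(centerlines[[a]], centerlines[[b]])))
  }
  m
}

#' Generate one synthetic fiber bundle
#'
#' Streamlines are the centerline plus a per-fiber constant perpendicular
#' offset (signed Gaussian magnitude along a random perpendicular direction)
#' plus per-point isotropic jitter; each fiber's point order is flipped with
#' `flip_probability`. Draws from the current RNG state; seed the stream via
#' `seed` for stand-alone use.
#'
#' @param centerline m x 3 matrix of centerline samples.
#' @param n_fibers Number of streamlines.
#' @param spread Cross-section standard deviation in mm.
#' @param jitter Per-point jitter standard deviation in mm.
#' @param flip_probability Point-order flip probability.
#' @param seed Optional seed (RNG state restored afterwards).
#' @return List of point matrices.
#' @export
generate_bundle <- function(centerline, n_fibers, spread = 0.5, jitter = 0.1,
                            flip_probability = 0.5, seed = NULL) {
  gen <- function() {
    m <- nrow(centerline)
    dir <- centerline[m, ] - centerline[1, ]
    dir <- dir / sqrt(sum(dir^2))
    ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n1 <- ref - sum(ref * dir) * dir; n1 <- n1 / sqrt(sum(n1^2))
    n2 <- c(dir[2] * n1[3] - dir[3] * n1[2],
            dir[3] * n1[1] - dir[1] * n1[3],
            dir[1] * n1[2] - dir[2] * n1[1])
    lapply(seq_len(n_fibers), function(f) {
      phi <- runif(1, 0, 2 * pi)
      g <- rnorm(1, 0, spread)
      off <- g * (cos(phi) * n1 + sin(phi) * n2)
      pts <- centerline + matrix(off, m, 3, byrow = TRUE)
      if (jitter > 0) pts <- pts + matrix(rnorm(m * 3, 0, jitter), m, 3)
      if (runif(1) < flip_probability) pts <- pts[m:1, , drop = FALSE]
      colnames(pts) <- c("x", "y", "z")
      pts
    })
  }
  if (is.null(seed)) gen() else with_seed_(seed, gen())
}

#' Generate one synthetic subject
#'
#' Lays out `n_bundles` centerlines inside the sphere, verifies the
#' separation constraint (raising an infeasible-packing error otherwise),
#' and grows each bundle with [generate_bundle()]. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Seed override (defaults to `cfg$seed`).
#' @return A tractogram tibble with a `bundle` ground-truth column, plus a
#'   `centerlines` attribute.
#' @export
generate_subject <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed_(seed, {
    ctr <- bundle_centerlines(cfg)
    sep <- min_centerline_separation(ctr)
    need <- cfg$separation_factor * cfg$cross_section_sd
    if (sep < need) {
      abort(paste0("Infeasible packing: minimum centerline separation ",
                   signif(sep, 4), " mm < required ", signif(need, 4),
                   " mm. Reduce n_bundles or cross_section_sd, or increase ",
                   "sphere_radius."))
    }
    fibers <- list(); labels <- integer(0)
    for (b in seq_len(cfg$n_bundles)) {
      fb <- generate_bundle(ctr[[b]], cfg$fibers_per_bundle,
                            spread = cfg$cross_section_sd,
                            jitter = cfg$point_jitter_sd,
                            flip_probability = cfg$flip_probability)
      fibers <- c(fibers, fb)
      labels <- c(labels, rep(b, cfg$fibers_per_bundle))
    }
    out_of_sphere <- any(vapply(fibers, function(p) max(rowSums(p^2)), 1) >
                           cfg$sphere_radius^2)
    if (out_of_sphere) {
      abort("Infeasible packing: fibers exceed the sphere radius.")
    }
    tract <- tractogram(fibers, bundle = labels)
    attr(tract, "centerlines") <- ctr
    tract
  })
}

#' Generate a multi-subject synthetic cohort
#'
#' One canonical subject is generated from `cfg$seed`, canonical landmarks
#' are laid out on a shell at 0.9 sphere radius (with a small seeded jitter),
#' and every subject is a rigid copy: fibers AND landmarks transformed
#' together by a per-subject rigid transform, optionally followed by
#' per-subject point noise (`subject_jitter_sd`). Cross-subject ground truth
#' is the bundle id, exact by construction. RNG layout: the canonical
#' subject uses `seed`, the landmarks `seed + 777`, and subject `s` draws
#' its transform and noise from `seed + s * 10007`, so adding subjects never
#' perturbs earlier subjects' draws.
#'
#' @param cfg A [synthetic_config()].
#' @return A list of class `synthetic_cohort`: `tract` (tractogram tibble
#'   with `subject_id`, `fiber_id`, `bundle`, `points`), `landmarks`
#'   (tibble `subject_id`, `label`, `x`, `y`, `z`), `transforms` (per
#'   subject), `canonical` (the untransformed subject), and `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$n_subjects < 2L) abort("A cohort needs at least 2 subjects.")
  canonical <- generate_subject(cfg)
  lm0 <- with_seed_(cfg$seed + 777L, {
    pts <- 0.9 * cfg$sphere_radius * fibonacci_sphere(cfg$n_landmarks)
    pts + matrix(rnorm(cfg$n_landmarks * 3, 0, 0.02 * cfg$sphere_radius),
                 ncol = 3)
  })
  tracts <- list(); lms <- list(); transforms <- list()
  for (s in seq_len(cfg$n_subjects)) {
    sid <- sprintf("sub-%02d", s)
    res <- with_seed_(cfg$seed + s * 10007L, {
      tr <- draw_rigid(cfg$rotation_deg, cfg$translation_mm)
      pts <- lapply(canonical$points, apply_rigid,
                    rotation = tr$rotation, translation = tr$translation)
      if (cfg$subject_jitter_sd > 0) {
        pts <- lapply(pts, function(p) {
          p + matrix(rnorm(length(p), 0, cfg$subject_jitter_sd), ncol = 3)
        })
      }
      list(tr = tr, pts = pts)
    })
    transforms[[sid]] <- res$tr
    tracts[[s]] <- tractogram(res$pts, subject_id = sid,
                              bundle = canonical$bundle)
    lmk <- apply_rigid(lm0, res$tr$rotation, res$tr$translation)
    lms[[s]] <- tibble(subject_id = sid, label = seq_len(cfg$n_landmarks),
                       x = lmk[, 1], y = lmk[, 2], z = lmk[, 3])
  }
  out <- list(tract = bind_rows(tracts), landmarks = bind_rows(lms),
              transforms = transforms, canonical = canonical, config = cfg)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat("<synthetic_cohort>", cfg$n_subjects, "subjects x", cfg$n_bundles,
      "bundles x", cfg$fibers_per_bundle, "fibers; radius",
      cfg$sphere_radius, "mm; seed", cfg$seed, "\n")
  invisible(x)
}
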