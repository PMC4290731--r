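test_that("ROI centers of gravity map through the affine", {
  vol <- array(0L, dim = c(6, 6, 6))
  vol[1, 1, 1] <- 1L   # voxel (0,0,0)
  vol[3, 1, 1] <- 1L   # voxel (2,0,0)
  vol[4, 5, 6] <- 2L   # voxel (3,4,5)
  lm <- landmarks_from_labels(vol, diag(4), label_ids = c(1L, 2L))
  expect_equal(unlist(lm[1, c("x", "y", "z")]), c(x = 1, y = 0, z = 0))
  expect_equal(unlist(lm[2, c("x", "y", "z")]), c(x = 3, y = 4, z = 5))

  # 0.13 mm in-plane scaling: voxel-space centroid (10,10,0) -> (1.3,1.3,0)
  vol2 <- array(0L, dim = c(22, 22, 3))
  vol2[10:12, 11, 1] <- 3L  # voxels (9..11, 10, 0), centroid (10,10,0)
  aff <- diag(c(0.13, 0.13, 1, 1))
  lm2 <- landmarks_from_labels(vol2, aff, label_ids = 3L)
  expect_equal(unlist(lm2[1, c("x", "y", "z")]), c(x = 1.3, y = 1.3, z = 0),
               tolerance = 1e-12)
  expect_error(landmarks_from_labels(vol, diag(4), label_ids = 9L),
               "Label 9")
})

test_that("min encoding takes the minimum over fiber samples", {
  fiber <- resample_streamline(straight_fiber(c(0, 0, 0), c(11, 0, 0)), 12)
  lms <- landmark_set(tibble::tibble(
    label = 1:3,
    x = c(5, 0, 100), y = c(0, 3, 0), z = c(0, 4, 0)))
  tract <- tractogram(list(fiber))
  E <- encode_fibers(tract, lms, "min")
  expect_identical(dim(E), c(1L, 3L))
  expect_equal(E[1, 1], 0)      # landmark on the fiber
  expect_equal(E[1, 2], 5)      # 3-4-5 from the origin sample
  expect_equal(E[1, 3], 89)     # beyond the far endpoint
  # exhaustive oracle over the 12 samples
  for (s in 1:3) {
    L <- unlist(lms[s, c("x", "y", "z")])
    expect_equal(E[1, s], min(sqrt(rowSums(sweep(fiber, 2, L)^2))))
  }
})

test_that("full encoding is point-major with length k * n", {
  f <- rbind(c(0, 0, 0), c(1, 0, 0))
  tract <- tractogram(list(f))
  one <- landmark_set(tibble::tibble(label = 1, x = 0, y = 0, z = 0))
  E <- encode_fibers(tract, one, "full")
  expect_equal(as.vector(E), c(0, 1))
  withr::with_seed(2, {
    lms <- landmark_set(tibble::tibble(label = 1:50, x = rnorm(50, sd = 20),
                                       y = rnorm(50, sd = 20), z = rnorm(50, sd = 20)))
    tract12 <- tractogram(list(random_fiber(12)))
    E12 <- encode_fibers(tract12, lms, "full")
    expect_identical(ncol(E12), 600L)  # 12 x 50
    # entry (point j, landmark s) is the point-landmark distance
    p <- tract12$points[[1]]
    expect_equal(E12[1, (3 - 1) * 50 + 7],
                 sqrt(sum((p[3, ] - unlist(lms[7, c("x", "y", "z")]))^2)))
  })
})

test_that("flipped-fiber encoding equals the block-reversed encoding", {
  withr::with_seed(4, {
    lms <- landmark_set(tibble::tibble(label = 1:5, x = rnorm(5, sd = 10),
                                       y = rnorm(5, sd = 10), z = rnorm(5, sd = 10)))
    f <- random_fiber(12)
    Ef <- encode_fibers(tractogram(list(f)), lms, "full")
    Eflip <- encode_fibers(tractogram(list(flip_streamline(f))), lms, "full")
    expect_equal(as.vector(Eflip), as.vector(flip_encoding(Ef)), tolerance = 1e-12)
  })
})

test_that("landmark distance is zero for identical or flipped fibers", {
  withr::with_seed(5, {
    lms <- landmark_set(tibble::tibble(label = 1:8, x = rnorm(8, sd = 15),
                                       y = rnorm(8, sd = 15), z = rnorm(8, sd = 15)))
    f <- random_fiber(12)
    E <- encode_fibers(tractogram(list(f, flip_streamline(f))), lms, "full")
    expect_equal(landmark_distance(E[1, ], E[1, ], k = 12), 0)
    expect_equal(landmark_distance(E[1, ], E[2, ], k = 12), 0, tolerance = 1e-9)
    expect_error(landmark_distance(E[1, ], E[1, 1:10]), "equal length")
  })
})

test_that("joint rigid transforms leave encodings and distances unchanged", {
  withr::with_seed(6, {
    for (i in 1:10) {
      lms_xyz <- matrix(rnorm(30, sd = 20), ncol = 3)
      lms <- landmark_set(tibble::tibble(label = 1:10, x = lms_xyz[, 1],
                                         y = lms_xyz[, 2], z = lms_xyz[, 3]))
      f1 <- random_fiber(12); f2 <- random_fiber(12)
      E <- encode_fibers(tractogram(list(f1, f2)), lms, "full")
      d0 <- landmark_distance(E[1, ], E[2, ], k = 12)
      R <- random_rotation(); tr <- rnorm(3, sd = 30)
      lmt <- apply_rigid(lms_xyz, R, tr)
      lms_t <- landmark_set(tibble::tibble(label = 1:10, x = lmt[, 1],
                                           y = lmt[, 2], z = lmt[, 3]))
      Et <- encode_fibers(tractogram(list(apply_rigid(f1, R, tr),
                                          apply_rigid(f2, R, tr))), lms_t, "full")
      expect_lt(max(abs(Et - E)), 1e-9)
      expect_lt(abs(landmark_distance(Et[1, ], Et[2, ], k = 12) - d0), 1e-9)
    }
  })
})

test_that("landmark distance matrix matches the pairwise scalar", {
  withr::with_seed(8, {
    lms <- landmark_set(tibble::tibble(label = 1:6, x = rnorm(6, sd = 10),
                                       y = rnorm(6, sd = 10), z = rnorm(6, sd = 10)))
    tract <- tractogram(lapply(1:7, function(i) random_fiber(12)))
    E <- encode_fibers(tract, lms, "full")
    D <- landmark_distance_matrix(E)
    expect_true(isSymmetric(unclass(D), check.attributes = FALSE))
    for (i in 1:7) for (j in 1:7) {
      if (i == j) next
      expect_equal(D[i, j], landmark_distance(E[i, ], E[j, ], k = 12),
                   tolerance = 1e-10)
    }
    Emin <- encode_fibers(tract, lms, "min")
    Dmin <- landmark_distance_matrix(Emin)
    expect_equal(Dmin[2, 5], sqrt(sum((Emin[2, ] - Emin[5, ])^2)))
  })
})
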