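# Small cohort of medoid-level bundles: each subject holds rigid copies of
# the same canonical fibers, with co-transformed landmarks.
medoid_cohort <- function(n_subjects = 3, n_bundles = 2, seed = 41,
                          rotation = 25, translation = 15, jitter = 0) {
  withr::with_seed(seed, {
    canonical <- lapply(seq_len(n_bundles), function(b) {
      resample_streamline(random_walk_fiber(12, sd = 4) +
                            matrix(c(0, 18 * b, 0), 12, 3, byrow = TRUE), 12)
    })
    lm0 <- matrix(rnorm(45, sd = 25), ncol = 3)
    meds <- list(); lms <- list()
    for (s in seq_len(n_subjects)) {
      sid <- sprintf("s%02d", s)
      tr <- list(rotation = rotation_matrix(rnorm(3), runif(1, 0, rotation)),
                 translation = runif(3, -translation, translation))
      pts <- lapply(canonical, function(p) {
        q <- apply_rigid(p, tr$rotation, tr$translation)
        if (jitter > 0) q <- q + matrix(rnorm(length(q), 0, jitter), ncol = 3)
        q
      })
      meds[[s]] <- tibble::tibble(subject_id = sid,
                                  bundle_id = seq_len(n_bundles), points = pts)
      lmt <- apply_rigid(lm0, tr$rotation, tr$translation)
      lms[[s]] <- tibble::tibble(subject_id = sid, label = seq_len(nrow(lm0)),
                                 x = lmt[, 1], y = lmt[, 2], z = lmt[, 3])
    }
    list(medoids = dplyr::bind_rows(meds), landmarks = dplyr::bind_rows(lms))
  })
}

test_that("block affinity zeroes same-subject blocks and normalizes per block", {
  co <- medoid_cohort(n_subjects = 2, n_bundles = 2)
  enc <- encode_medoids(co$medoids, co$landmarks)
  aff <- build_block_affinity(enc)
  A <- aff$values
  expect_identical(dim(A), c(4L, 4L))
  expect_true(all(A[1:2, 1:2] == 0))
  expect_true(all(A[3:4, 3:4] == 0))
  expect_true(isSymmetric(A))
  blk <- A[1:2, 3:4]
  expect_equal(min(blk[blk > 0]), exp(-1))  # block max distance -> e^-1
  expect_identical(nrow(aff$block_sigmas), 1L)
})

test_that("identical encodings give unit cross-subject affinity", {
  # one bundle per subject, rigid copies: every encoding is identical, all
  # block distances are zero, and the degenerate sigma falls back to 1
  co <- medoid_cohort(n_subjects = 3, n_bundles = 1)
  aff <- build_block_affinity(encode_medoids(co$medoids, co$landmarks))
  cross <- outer(aff$subject_of, aff$subject_of, "!=")
  expect_equal(unname(aff$values[cross]), rep(1, 6))
  expect_equal(aff$block_sigmas$sigma, rep(1, 3))
  # with several bundles, corresponding rigid copies still reach affinity 1
  co2 <- medoid_cohort(n_subjects = 2, n_bundles = 2, rotation = 0,
                       translation = 0)
  aff2 <- build_block_affinity(encode_medoids(co2$medoids, co2$landmarks))
  expect_equal(aff2$values[1, 3], 1)
  expect_equal(aff2$values[2, 4], 1)
})

test_that("encoding mismatches and single subjects are rejected", {
  co <- medoid_cohort(n_subjects = 2, n_bundles = 2)
  enc <- encode_medoids(co$medoids, co$landmarks)
  bad <- enc
  bad$encoding[[3]] <- bad$encoding[[3]][1:10]
  expect_error(build_block_affinity(bad), "mismatch")
  one <- dplyr::filter(enc, subject_id == "s01")
  expect_error(build_block_affinity(one), "at least 2 subjects")
  lm_bad <- co$landmarks
  lm_bad$label[lm_bad$subject_id == "s02"] <- rev(lm_bad$label[lm_bad$subject_id == "s02"])
  expect_error(encode_medoids(co$medoids, lm_bad), "order")
})

test_that("rigidly copied bundles match across subjects exactly", {
  co <- medoid_cohort(n_subjects = 3, n_bundles = 2)
  enc <- encode_medoids(co$medoids, co$landmarks)
  aff <- build_block_affinity(enc)
  # registration-free: corresponding bundles have zero landmark distance
  expect_lt(aff$distance[1, 3], 1e-9)
  clusters <- cluster_bundles(aff)
  complete <- select_complete(clusters)
  expect_identical(nrow(complete), 2L)
  td <- tidy(complete)
  # ground-truth correspondence is the canonical bundle id
  expect_equal(adjusted_rand_index(td$bundle_id, td$cluster), 1)
})

test_that("per-subject rigid transforms leave the block affinity unchanged", {
  co <- medoid_cohort(n_subjects = 3, n_bundles = 2, seed = 43)
  A0 <- build_block_affinity(encode_medoids(co$medoids, co$landmarks))$values
  withr::with_seed(44, {
    med2 <- co$medoids; lm2 <- co$landmarks
    for (s in unique(med2$subject_id)) {
      R <- random_rotation(); tr <- rnorm(3, sd = 40)
      i <- med2$subject_id == s
      med2$points[i] <- lapply(med2$points[i], apply_rigid, rotation = R,
                               translation = tr)
      j <- lm2$subject_id == s
      xyz <- apply_rigid(cbind(lm2$x[j], lm2$y[j], lm2$z[j]), R, tr)
      lm2$x[j] <- xyz[, 1]; lm2$y[j] <- xyz[, 2]; lm2$z[j] <- xyz[, 3]
    }
    A1 <- build_block_affinity(encode_medoids(med2, lm2))$values
    expect_lt(max(abs(A1 - A0)), 1e-9)
  })
})

test_that("no cross cluster ever contains two bundles of one subject", {
  withr::with_seed(45, {
    for (i in 1:10) {
      n_sub <- sample(2:5, 1)
      sizes <- sample(1:6, n_sub, replace = TRUE)
      if (sum(sizes) < 3) sizes <- sizes + 1
      enc <- tibble::tibble(
        subject_id = rep(sprintf("s%d", seq_len(n_sub)), sizes),
        bundle_id = unlist(lapply(sizes, seq_len)),
        points = replicate(sum(sizes), random_fiber(6), simplify = FALSE),
        encoding = replicate(sum(sizes), abs(rnorm(18, sd = 5)), simplify = FALSE))
      attr(enc, "k") <- 6L
      attr(enc, "encoding_type") <- "full"
      clusters <- cluster_bundles(build_block_affinity(enc))
      for (m in clusters$members) {
        expect_identical(anyDuplicated(m$subject_id), 0L)
      }
      expect_identical(sum(clusters$n_members), sum(sizes))
    }
  })
})

test_that("unequal per-subject bundle counts are handled", {
  co <- medoid_cohort(n_subjects = 3, n_bundles = 3, seed = 46)
  med <- co$medoids[-2, ]  # subject 1 loses one bundle
  clusters <- cluster_bundles(build_block_affinity(encode_medoids(med, co$landmarks)))
  complete <- select_complete(clusters)
  expect_gte(nrow(complete), 2L)
  expect_true(all(complete$n_members == 3L))
})

test_that("completeness selection filters by member count", {
  mk <- function(sizes) {
    structure(tibble::tibble(
      cluster = seq_along(sizes),
      members = lapply(sizes, function(s) {
        tibble::tibble(subject_id = sprintf("s%d", seq_len(s)),
                       bundle_id = seq_len(s), index = seq_len(s))
      }),
      n_members = sizes, complete = sizes == 4,
      cohesiveness = rev(seq_along(sizes)) / 10,
      residual = FALSE), n_subjects = 4L,
      subjects = sprintf("s%d", 1:4),
      class = c("cross_clustering", "tbl_df", "tbl", "data.frame"))
  }
  expect_identical(nrow(select_complete(mk(c(4, 4, 3, 2)))), 2L)
  expect_identical(nrow(select_complete(mk(c(2, 3)))), 0L)
  expect_identical(nrow(select_complete(mk(c(4, 4)))), 2L)
  expect_identical(nrow(select_complete(mk(c(4, 3, 2)), min_subjects = 3)), 2L)
})
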