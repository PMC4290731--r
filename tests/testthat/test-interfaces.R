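test_that("TCK round trip preserves coordinates to float32 precision", {
  tract <- parallel_bundles(n_bundles = 2, m = 4)
  path <- withr::local_tempfile(fileext = ".tck")
  write_tck(tract, path)
  back <- read_tck(path, subject_id = "s1")
  expect_identical(nrow(back), nrow(tract))
  for (i in seq_len(nrow(tract))) {
    expect_lt(max(abs(back$points[[i]] - tract$points[[i]])), 1e-4)
  }
  expect_identical(back$subject_id[1], "s1")
})

test_that("empty and malformed TCK files are handled explicitly", {
  path <- withr::local_tempfile(fileext = ".tck")
  write_tck(tibble::tibble(fiber_id = integer(0), points = list()), path)
  empty <- read_tck(path)
  expect_identical(nrow(empty), 0L)
  expect_error(cluster_fibers(empty), "at least 2 fibers")
  bad <- withr::local_tempfile(fileext = ".tck")
  writeLines("not a tractogram", bad)
  expect_error(read_tck(bad), "magic")
  expect_error(read_tck("/nonexistent/x.tck"), "not found")
})

test_that("TCK and CSV encodings load to equal coordinates", {
  tract <- parallel_bundles(n_bundles = 2, m = 3)
  tck <- withr::local_tempfile(fileext = ".tck")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_tck(tract, tck)
  write_streamline_csv(tract, csv)
  a <- read_tck(tck)
  b <- read_streamline_csv(csv)
  for (i in seq_len(nrow(tract))) {
    expect_lt(max(abs(a$points[[i]] - b$points[[i]])), 1e-4)
  }
})

test_that("landmark files load into the canonical order", {
  lm <- tibble::tibble(label = c(3L, 1L, 2L), x = c(1, 2, 3), y = 0, z = c(9, 8, 7))
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(lm, js, digits = NA)
  got <- read_landmarks(js, label_ids = c(1L, 2L, 3L))
  expect_identical(got$label, c(1L, 2L, 3L))
  expect_equal(got$x, c(2, 3, 1))

  cs <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(label_id = c(2L, 1L), label_name = c("b", "a"),
                                  x_mm = c(5, 6), y_mm = 0, z_mm = 1), cs)
  got2 <- read_landmarks(cs, label_ids = c(1L, 2L))
  expect_equal(got2$x, c(6, 5))
  expect_error(read_landmarks(cs, label_ids = c(1L, 9L)), "9")

  # two subjects with different on-disk orders load identically
  lm_b <- lm[c(2, 3, 1), ]
  js_b <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(lm_b, js_b, digits = NA)
  got_b <- read_landmarks(js_b, label_ids = c(1L, 2L, 3L))
  expect_equal(got_b, got)
})

test_that("NIfTI label volumes delegate to the centroid extractor", {
  skip_if_not_installed("RNifti")
  vol <- array(0L, dim = c(8, 8, 8))
  vol[2, 2, 2] <- 1L
  vol[5:7, 5, 5] <- 2L
  path <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  got <- read_landmarks(path, label_ids = c(1L, 2L))
  ref <- landmarks_from_labels(vol, RNifti::xform(RNifti::readNifti(path)),
                               c(1L, 2L))
  expect_equal(got, ref)
  expect_error(read_landmarks(path), "label_ids")
})

test_that("strict config schema rejects unknown keys", {
  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(k_samples = 10, thetaa = 1e-4), js, auto_unbox = TRUE)
  expect_error(read_pipeline_config(js), "thetaa")
  jsonlite::write_json(list(k_samples = 10, theta = 1e-4), js, auto_unbox = TRUE)
  cfg <- read_pipeline_config(js)
  expect_identical(cfg$k_samples, 10L)
  expect_identical(cfg$theta, 1e-4)
  expect_error(pipeline_config(k_samples = 1), ">= 2")
})

test_that("the full pipeline writes provenance-stamped, reproducible outputs", {
  co <- generate_cohort(synthetic_config(n_subjects = 3, n_bundles = 4,
                                         fibers_per_bundle = 8,
                                         n_landmarks = 12, seed = 71))
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  res <- run_pipeline(co$tract, co$landmarks, pipeline_config(), output_dir = out1)
  run_pipeline(co$tract, co$landmarks, pipeline_config(), output_dir = out2)
  expect_true(file.exists(file.path(out1, "cross_manifest.json")))
  man <- jsonlite::fromJSON(file.path(out1, "cross_manifest.json"),
                            simplifyVector = FALSE)
  expect_gte(length(man$clusters), 1L)
  expect_true(all(vapply(man$clusters, function(cl) isTRUE(cl$complete), logical(1))))
  expect_identical(man$config_hash, res$config_hash)
  # determinism: byte-identical manifests across runs
  expect_identical(readLines(file.path(out1, "cross_manifest.json")),
                   readLines(file.path(out2, "cross_manifest.json")))
  tsv <- file.path(out1, "sub-01_clusters.tsv")
  expect_true(file.exists(tsv))
  expect_match(readLines(tsv, n = 1), res$config_hash)
  asg <- read_assignments_tsv(tsv)
  expect_identical(nrow(asg), sum(co$tract$subject_id == "sub-01"))
  expect_true(file.exists(file.path(out1, "run_log.txt")))
})

test_that("a single subject skips the cross stage with a notice", {
  co <- generate_cohort(synthetic_config(n_subjects = 2, n_bundles = 3,
                                         fibers_per_bundle = 8,
                                         n_landmarks = 8, seed = 72))
  one <- dplyr::filter(co$tract, subject_id == "sub-01")
  out <- withr::local_tempdir()
  expect_message(res <- run_pipeline(one, co$landmarks, pipeline_config(),
                                     output_dir = out), "skipped")
  expect_null(res$cross)
  expect_true(file.exists(file.path(out, "sub-01_clusters.tsv")))
  expect_false(file.exists(file.path(out, "cross_manifest.json")))
})

test_that("the CLI simulates, runs and evaluates end to end", {
  skip_if_not_installed("optparse")
  dir <- withr::local_tempdir()
  sim <- file.path(dir, "sim"); out <- file.path(dir, "out")
  suppressMessages(fibersets_cli(c("simulate", "--out", sim, "--seed", "73",
                                   "--subjects", "2", "--bundles", "3",
                                   "--fibers", "8")))
  expect_true(file.exists(file.path(sim, "sub-01.tck")))
  expect_true(file.exists(file.path(sim, "landmarks.json")))
  suppressMessages(fibersets_cli(c("run", "--input", sim, "--out", out)))
  expect_true(file.exists(file.path(out, "cross_manifest.json")))
  # evaluate stage-1 assignments against the simulated ground truth
  truth_all <- readr::read_tsv(file.path(sim, "labels.tsv"), show_col_types = FALSE)
  truth1 <- dplyr::filter(truth_all, subject_id == "sub-01")
  tr_path <- file.path(dir, "truth1.tsv")
  readr::write_tsv(truth1, tr_path)
  rep_path <- file.path(dir, "report.json")
  suppressMessages(fibersets_cli(c("evaluate", "--truth", tr_path, "--pred",
                                   file.path(out, "sub-01_clusters.tsv"),
                                   "--out", rep_path)))
  rep_ <- jsonlite::fromJSON(rep_path)
  expect_gte(rep_$ari, 0.8)
  expect_error(fibersets_cli("frobnicate"), "Unknown subcommand")
  expect_error(fibersets_cli(c("run", "--input", dir, "--out", out)), "No .tck")
})
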