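#' Pipeline configuration
#'
#' All tunable parameters of the two-stage pipeline with their conventional
#' defaults: 12 samples per fiber, support threshold 1e-5, convergence
#' tolerance 1e-7, 5% cohesiveness-tail pruning, one-sided Gaussian outlier
#' rejection at 0.05, and a 3 mm short-fiber filter.
#'
#' @param k_samples Samples per resampled fiber (default 12).
#' @param theta Dominant-set support threshold (default 1e-5).
#' @param epsilon Replicator-dynamics convergence tolerance (default 1e-7).
#' @param max_iterations Replicator iteration cap (default 10000).
#' @param tail_fraction Late-cluster fraction dropped at stage 1 (default 0.05).
#' @param alpha One-sided rejection level for cohesiveness outliers (default 0.05).
#' @param min_fiber_length_mm Short-fiber filter in mm (default 3).
#' @param metric Stage-1 fiber metric, `"pp"` or `"smp"` (default `"pp"`).
#' @param sigma_scope Stage-2 normalization scope, `"per_block"` or
#'   `"global"` (default `"per_block"`).
#' @param split_hemispheres Split each subject at a sagittal midplane and
#'   cluster the three groups separately (default `FALSE`).
#' @param midplane_x Midplane position in mm when splitting (default 0).
#' @param min_subjects Completeness requirement for stage-2 clusters;
#'   `NULL` (default) means all subjects.
#' @param label_ids Optional canonical landmark label order.
#' @param seed Seed recorded for provenance (default 1).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(k_samples = 12, theta = 1e-5, epsilon = 1e-7,
                            max_iterations = 10000, tail_fraction = 0.05,
                            alpha = 0.05, min_fiber_length_mm = 3,
                            metric = c("pp", "smp"),
                            sigma_scope = c("per_block", "global"),
                            split_hemispheres = FALSE, midplane_x = 0,
                            min_subjects = NULL, label_ids = NULL, seed = 1) {
  metric <- match.arg(metric)
  sigma_scope <- match.arg(sigma_scope)
  if (k_samples < 2) abort("`k_samples` must be >= 2.")
  if (min_fiber_length_mm < 0) abort("`min_fiber_length_mm` must be >= 0.")
  ds <- ds_config(theta = theta, epsilon = epsilon,
                  max_iterations = max_iterations)
  structure(list(k_samples = as.integer(k_samples), theta = theta,
                 epsilon = epsilon, max_iterations = as.integer(max_iterations),
                 tail_fraction = tail_fraction, alpha = alpha,
                 min_fiber_length_mm = min_fiber_length_mm, metric = metric,
                 sigma_scope = sigma_scope,
                 split_hemispheres = isTRUE(split_hemispheres),
                 midplane_x = midplane_x, min_subjects = min_subjects,
                 label_ids = label_ids, seed = as.integer(seed), ds = ds),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Strict schema: any key not matching a [pipeline_config()] argument is an
#' error, so a misspelled key can never silently fall back to a default.
#'
#' @param path Config file (`.yaml`/`.yml` needs the yaml package, `.json`
#'   uses jsonlite).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("YAML configs require the yaml package; use JSON instead.")
    }
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path)
  } else {
    abort(paste0("Unknown config format: .", ext))
  }
  allowed <- setdiff(names(formals(pipeline_config)), "...")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", "),
                 ". Allowed: ", paste(allowed, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

pipeline_log <- function(log, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", paste0(...))
  c(log, line)
}

cluster_one_subject <- function(tract, config) {
  clustering <- cluster_fibers(tract, k = config$k_samples,
                               metric = config$metric, config = config$ds)
  select_clusters(clustering, tail_fraction = config$tail_fraction,
                  alpha = config$alpha)
}

#' Run the full two-stage pipeline
#'
#' Per subject: short-fiber filtering, resampling, optional hemisphere
#' split, dominant-set clustering, cohesiveness-based cluster selection and
#' medoid extraction. Across subjects (when there are at least two):
#' landmark encoding of the medoids, block affinity with zeroed
#' intra-subject blocks, dominant-set clustering, and selection of clusters
#' spanning the cohort. With a single subject the cross stage is skipped
#' with an explicit notice.
#'
#' @param tract A multi-subject tractogram tibble (`subject_id` column
#'   required).
#' @param landmarks Multi-subject landmark tibble (`subject_id`, `label`,
#'   `x`, `y`, `z`); may be `NULL` when only stage 1 is wanted.
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, per-subject assignment
#'   TSVs, medoid CSVs, the cross-cluster manifest JSON and a run log are
#'   written there, every file carrying the config hash.
#' @return A list of class `fiber_pipeline`: `subjects` (named list of
#'   `subject_clustering`), `medoids`, `cross` (a `cross_clustering` or
#'   `NULL`), `log` (character), `config`, `config_hash`.
#' @export
run_pipeline <- function(tract, landmarks = NULL, config = pipeline_config(),
                         output_dir = NULL) {
  check_tractogram(tract)
  if (!"subject_id" %in% names(tract)) {
    abort("`tract` needs a `subject_id` column (one tractogram per subject).")
  }
  if (!inherits(config, "pipeline_config")) abort("`config` must be a pipeline_config().")
  hash <- rlang::hash(unclass(config))
  log <- pipeline_log(character(0), "pipeline start, config_hash=", hash)
  for (key in c("k_samples", "theta", "epsilon", "tail_fraction", "alpha",
                "min_fiber_length_mm", "metric", "sigma_scope", "seed")) {
    log <- pipeline_log(log, "param ", key, "=", format(config[[key]]))
  }
  subjects <- unique(tract$subject_id)
  clusterings <- list()
  medoid_rows <- list()
  for (s in subjects) {
    sub <- filter(tract, .data$subject_id == s)
    n0 <- nrow(sub)
    sub <- filter_short_fibers(sub, config$min_fiber_length_mm)
    log <- pipeline_log(log, s, ": ", n0, " fibers, ", nrow(sub),
                        " after length filter")
    if (nrow(sub) < 2L) {
      abort(paste0("Stage intra-subject, subject ", s,
                   ": fewer than 2 fibers after filtering."))
    }
    sub <- resample_fibers(sub, config$k_samples)
    groups <- if (config$split_hemispheres) {
      sp <- split_hemispheres(sub, config$midplane_x)
      split(sp, sp$hemisphere, drop = FALSE)
    } else list(all = sub)
    offset <- 0L
    for (gname in names(groups)) {
      g <- groups[[gname]]
      if (nrow(g) < 2L) {
        if (nrow(g) > 0L) log <- pipeline_log(log, s, "/", gname,
                                              ": <2 fibers, skipped")
        next
      }
      cl <- tryCatch(cluster_one_subject(g, config), error = function(e) {
        abort(paste0("Stage intra-subject, subject ", s, " (", gname, "): ",
                     conditionMessage(e)))
      })
      log <- pipeline_log(log, s, "/", gname, ": ",
                          sum(!cl$clusters$residual), " clusters, ",
                          sum(cl$clusters$kept), " kept")
      med <- bundle_medoids(cl, g)
      med$bundle_id <- med$bundle_id + offset
      med$group <- gname
      offset <- offset + nrow(cl$clusters)
      key <- if (config$split_hemispheres) paste0(s, "/", gname) else s
      clusterings[[key]] <- cl
      medoid_rows[[key]] <- med
    }
  }
  medoids <- bind_rows(medoid_rows)
  cross <- NULL
  if (length(subjects) >= 2L && !is.null(landmarks)) {
    encoded <- encode_medoids(medoids, landmarks)
    aff <- build_block_affinity(encoded, sigma_scope = config$sigma_scope)
    all_clusters <- cluster_bundles(aff, config = config$ds)
    min_subj <- config$min_subjects %||% length(subjects)
    cross <- select_complete(all_clusters, n_subjects = length(subjects),
                             min_subjects = min_subj)
    log <- pipeline_log(log, "cross: ", nrow(all_clusters), " clusters, ",
                        nrow(cross), " spanning >= ", min_subj, " subjects")
  } else if (length(subjects) < 2L) {
    log <- pipeline_log(log, "cross stage skipped: only ", length(subjects),
                        " subject")
    inform("Cross-subject stage skipped: a single subject was provided.")
  } else {
    log <- pipeline_log(log, "cross stage skipped: no landmarks provided")
  }
  out <- list(subjects = clusterings, medoids = medoids, cross = cross,
              log = log, config = config, config_hash = hash)
  class(out) <- "fiber_pipeline"
  if (!is.null(output_dir)) write_pipeline_outputs(out, output_dir)
  out
}

write_pipeline_outputs <- function(result, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(result$subjects)) {
    safe <- gsub("/", "_", key)
    write_assignments_tsv(result$subjects[[key]],
                          file.path(output_dir, paste0(safe, "_clusters.tsv")),
                          config_hash = result$config_hash)
  }
  if (nrow(result$medoids) > 0L) {
    med <- select(result$medoids, "subject_id", "bundle_id", "points")
    med$fiber_id <- result$medoids$medoid_fiber
    write_streamline_csv(med, file.path(output_dir, "medoids.csv"))
  }
  if (!is.null(result$cross)) {
    write_manifest_json(result$cross, file.path(output_dir, "cross_manifest.json"),
                        config_hash = result$config_hash)
  }
  writeLines(c(paste0("# config_hash=", result$config_hash), result$log),
             file.path(output_dir, "run_log.txt"))
  invisible(output_dir)
}

#' @export
print.fiber_pipeline <- function(x, ...) {
  cat("<fiber_pipeline>", length(x$subjects), "subject clustering(s)")
  if (!is.null(x$cross)) cat(";", nrow(x$cross), "cross-subject cluster(s)")
  cat("; config_hash", substr(x$config_hash, 1, 8), "\n")
  invisible(x)
}
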