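#' Read and write MRtrix TCK streamline files
#'
#' Minimal reader/writer for the MRtrix `.tck` format: a text header
#' (`mrtrix tracks`, `key: value` lines, `file: . <offset>`, `END`) followed
#' by little-endian float32 point triplets in world mm, with `(NaN,NaN,NaN)`
#' separating streamlines and `(Inf,Inf,Inf)` terminating the stream.
#'
#' @param path File path.
#' @param subject_id Optional subject id attached to the loaded tractogram.
#' @return `read_tck()` returns a tractogram tibble; `write_tck()` returns
#'   `path` invisibly.
#' @export
read_tck <- function(path, subject_id = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readBin(path, "raw", file.size(path))
  magic_len <- length(charToRaw("mrtrix tracks"))
  if (length(raw) < magic_len ||
      !identical(rawToChar(raw[seq_len(magic_len)]), "mrtrix tracks")) {
    abort(paste0("Not a TCK file (missing 'mrtrix tracks' magic): ", path))
  }
  # header is ASCII up to the END line; locate it before the binary payload
  end_pos <- grepRaw("\nEND\n", raw, fixed = TRUE)
  if (length(end_pos) == 0L) abort(paste0("Malformed TCK header (no END line): ", path))
  lines <- strsplit(rawToChar(raw[seq_len(end_pos[1] - 1L)]), "\n", fixed = TRUE)[[1]]
  header <- lines[-1L]
  kv <- strsplit(header, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ": "), "")
  datatype <- vals[match("datatype", keys)]
  if (!is.na(datatype) && !datatype %in% c("Float32LE", "Float32")) {
    abort(paste0("Unsupported TCK datatype: ", datatype))
  }
  file_field <- vals[match("file", keys)]
  if (is.na(file_field)) abort(paste0("Malformed TCK header (no file field): ", path))
  offset <- as.integer(sub("^\\.\\s+", "", file_field))
  n_float <- (length(raw) - offset) %/% 4L
  vals_f <- readBin(raw[(offset + 1L):length(raw)], "numeric", n = n_float,
                    size = 4L, endian = "little")
  triplets <- matrix(vals_f[seq_len(3L * (length(vals_f) %/% 3L))],
                     ncol = 3L, byrow = TRUE)
  fibers <- list()
  current <- NULL
  for (i in seq_len(nrow(triplets))) {
    v <- triplets[i, ]
    if (all(is.infinite(v))) break
    if (all(is.nan(v))) {
      if (!is.null(current)) fibers[[length(fibers) + 1L]] <- do.call(rbind, current)
      current <- NULL
    } else {
      current <- c(current, list(v))
    }
  }
  if (!is.null(current)) fibers[[length(fibers) + 1L]] <- do.call(rbind, current)
  if (length(fibers) == 0L) {
    out <- tibble(fiber_id = integer(0), points = list())
    if (!is.null(subject_id)) out <- tibble::add_column(
      out, subject_id = character(0), .before = 1L)
    return(out)
  }
  tractogram(fibers, subject_id = subject_id)
}

#' @param tract A tractogram tibble.
#' @rdname read_tck
#' @export
write_tck <- function(tract, path) {
  check_tractogram(tract)
  lines <- c("mrtrix tracks", "datatype: Float32LE",
             paste0("count: ", nrow(tract)))
  make_header <- function(off) {
    paste0(paste(lines, collapse = "\n"), "\nfile: . ", off, "\nEND\n")
  }
  off <- nchar(make_header(0L))
  while (nchar(make_header(off)) != off) off <- nchar(make_header(off))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(make_header(off), con, eos = NULL)
  for (p in tract$points) {
    writeBin(as.numeric(t(p)), con, size = 4L, endian = "little")
    writeBin(as.numeric(c(NaN, NaN, NaN)), con, size = 4L, endian = "little")
  }
  writeBin(as.numeric(c(Inf, Inf, Inf)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read and write streamlines as plain CSV
#'
#' Human-diffable long format with columns `fiber_id`, `point_id`, `x`,
#' `y`, `z` and optionally `subject_id` and `bundle`.
#'
#' @param path File path.
#' @return `read_streamline_csv()` returns a tractogram tibble.
#' @export
read_streamline_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  as_tractogram(df[setdiff(names(df), "point_id")])
}

#' @param tract A tractogram tibble.
#' @rdname read_streamline_csv
#' @export
write_streamline_csv <- function(tract, path) {
  readr::write_csv(streamline_points(tract), path)
  invisible(path)
}

#' Read a landmark set from JSON, CSV or a NIfTI label volume
#'
#' * JSON: an array of records with fields `label`, `x`, `y`, `z`
#'   (optionally `subject_id`).
#' * CSV: columns `label,x,y,z` or the long-form header
#'   `label_id,label_name,x_mm,y_mm,z_mm`.
#' * NIfTI (`.nii` / `.nii.gz`, requires the RNifti package): an integer
#'   label volume; landmarks are ROI centers of gravity via
#'   [landmarks_from_labels()] and `label_ids` is required.
#'
#' When `label_ids` is given the landmarks are reordered to that canonical
#' order (identical across subjects of a cohort); a missing label is an
#' error naming the id.
#'
#' @param path File path.
#' @param label_ids Optional ordered label ids defining the canonical order.
#' @return A landmark tibble.
#' @export
read_landmarks <- function(path, label_ids = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  ext <- tolower(sub("^.*?(\\.nii\\.gz|\\.[^.]*)$", "\\1", path))
  lm <- if (ext == ".json") {
    as_tibble(jsonlite::fromJSON(path))
  } else if (ext %in% c(".csv", ".tsv")) {
    df <- if (ext == ".csv") readr::read_csv(path, show_col_types = FALSE)
          else readr::read_tsv(path, show_col_types = FALSE)
    if ("label_id" %in% names(df)) {
      need <- c("label_id", "x_mm", "y_mm", "z_mm")
      miss <- setdiff(need, names(df))
      if (length(miss)) abort(paste0("Missing landmark column(s): ",
                                     paste(miss, collapse = ", ")))
      tibble(label = df$label_id, x = df$x_mm, y = df$y_mm, z = df$z_mm)
    } else df
  } else if (ext %in% c(".nii", ".nii.gz")) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      abort("Reading NIfTI label volumes requires the RNifti package.")
    }
    if (is.null(label_ids)) abort("`label_ids` is required for NIfTI label volumes.")
    img <- RNifti::readNifti(path)
    return(landmarks_from_labels(array(as.integer(img), dim = dim(img)),
                                 affine = RNifti::xform(img), label_ids))
  } else {
    abort(paste0("Unknown landmark format: ", ext))
  }
  lm <- landmark_set(lm)
  if (!is.null(label_ids)) {
    idx <- match(label_ids, lm$label)
    if (anyNA(idx)) {
      abort(paste0("Landmark label(s) missing from ", path, ": ",
                   paste(label_ids[is.na(idx)], collapse = ", ")))
    }
    lm <- lm[idx, , drop = FALSE]
  }
  lm
}

#' Write per-subject cluster assignments as TSV
#'
#' Columns `fiber_index`, `cluster_id`, `kept`, `cohesiveness`; the first
#' line is a `#` comment carrying the subject and the config hash so
#' provenance survives in the file itself.
#'
#' @param clustering A `subject_clustering`.
#' @param path Output path.
#' @param config_hash Provenance string (default: hash of the clustering's
#'   dominant-set config).
#' @export
write_assignments_tsv <- function(clustering, path,
                                  config_hash = rlang::hash(clustering$config)) {
  df <- tidy(clustering)
  out <- tibble(fiber_index = df$fiber_id, cluster_id = df$cluster,
                kept = df$kept, cohesiveness = df$cohesiveness)
  writeLines(paste0("# fibersets subject=", clustering$subject_id,
                    " config_hash=", config_hash), path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read an assignments TSV back
#'
#' @param path Path written by [write_assignments_tsv()].
#' @return A tibble with `fiber_index`, `cluster_id`, `kept`, `cohesiveness`.
#' @export
read_assignments_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Write the cross-subject cluster manifest as JSON
#'
#' One record per cluster: `cluster_id`, `complete`, `cohesiveness`, and the
#' `subject -> bundle` membership map; the envelope carries the config hash
#' and subject roster.
#'
#' @param clusters A `cross_clustering`.
#' @param path Output path.
#' @param config_hash Provenance string.
#' @export
write_manifest_json <- function(clusters, path, config_hash = "") {
  recs <- lapply(seq_len(nrow(clusters)), function(i) {
    m <- clusters$members[[i]]
    list(cluster_id = clusters$cluster[i],
         complete = clusters$complete[i],
         cohesiveness = clusters$cohesiveness[i],
         members = as.list(setNames(m$bundle_id, m$subject_id)))
  })
  jsonlite::write_json(
    list(config_hash = config_hash,
         n_subjects = attr(clusters, "n_subjects"),
         subjects = attr(clusters, "subjects"),
         clusters = recs),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
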