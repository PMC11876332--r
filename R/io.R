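ANNOTATION_SCHEMA <- "1.0"

#' Write a per-recording annotation file
#'
#' One JSON per recording: identifier, temperature labels, the L1-L4 event
#' timestamps in seconds, and the generating seed. The file carries a
#' `schema_version`; loaders reject unknown major versions.
#'
#' @param path Output path (`.json`).
#' @param recording An `annotated_recording`.
#' @param seed Seed used to generate the recording (optional bookkeeping).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(path, recording, seed = NA_integer_) {
  rec <- list(schema_version = ANNOTATION_SCHEMA,
              recording_id = recording$recording_id,
              temperature_group = recording$temperature_group,
              measured_temperature = recording$measured_temperature,
              L1 = recording$L1, L2 = recording$L2,
              L3 = recording$L3, L4 = recording$L4,
              speed_mm_s = recording$speed_mm_s,
              seed = seed)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

validate_annotation <- function(a, where) {
  need <- c("recording_id", "temperature_group", "measured_temperature",
            "L1", "L2", "L3", "L4")
  miss <- setdiff(need, names(a))
  if (length(miss) > 0) {
    stop("annotation ", where, " missing field(s): ",
         paste(miss, collapse = ", "))
  }
  sv <- a$schema_version %||% ANNOTATION_SCHEMA
  if (strsplit(as.character(sv), ".", fixed = TRUE)[[1]][1] !=
      strsplit(ANNOTATION_SCHEMA, ".", fixed = TRUE)[[1]][1]) {
    stop("annotation ", where, ": unsupported schema version ", sv,
         " (this package reads major version ",
         strsplit(ANNOTATION_SCHEMA, ".", fixed = TRUE)[[1]][1], ")")
  }
  ok <- 0 < a$L1 && a$L1 < a$L2 && a$L2 <= a$L3 && a$L3 < a$L4
  if (!isTRUE(ok)) {
    stop("annotation for record '", a$recording_id, "' (", where,
         ") violates 0 < L1 < L2 <= L3 < L4: L = [",
         paste(c(a$L1, a$L2, a$L3, a$L4), collapse = ", "), "]")
  }
  invisible(a)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and validate annotation records
#'
#' Accepts one or more per-recording JSON files, or a single manifest CSV
#' with the same columns. Each record is validated (required fields, the
#' `0 < L1 < L2 <= L3 < L4` ordering) and errors name the offending record.
#'
#' @param paths Character vector of `.json` annotation paths, or one `.csv`
#'   manifest path.
#' @return data.frame of validated annotation records.
#' @export
load_annotations <- function(paths) {
  if (length(paths) == 1 && grepl("\\.csv$", paths, ignore.case = TRUE)) {
    df <- utils::read.csv(paths, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(df))) {
      validate_annotation(as.list(df[i, ]), paste0(paths, " row ", i))
    }
    return(df)
  }
  rows <- lapply(paths, function(p) {
    a <- jsonlite::read_json(p, simplifyVector = TRUE)
    validate_annotation(a, p)
    data.frame(recording_id = a$recording_id,
               temperature_group = a$temperature_group,
               measured_temperature = a$measured_temperature,
               L1 = a$L1, L2 = a$L2, L3 = a$L3, L4 = a$L4,
               speed_mm_s = a$speed_mm_s %||% NA_real_,
               seed = a$seed %||% NA_integer_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a dataset manifest CSV
#'
#' @param path Path to `manifest.csv` written by [generate_dataset()].
#' @return data.frame, one row per recording.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("recording_id", "temperature_group", "measured_temperature",
            "L1", "L2", "L3", "L4")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("manifest ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}

#' Map the deposited dataset layout onto a manifest
#'
#' The public deposit organizes recordings into folders named by
#' temperature group (20 to 55 in steps of 5), each holding WAV files with
#' same-stem JSON annotations. This adapter walks that layout and returns
#' the package's internal manifest.
#'
#' @param root Root directory of a local copy of the deposited dataset.
#' @return data.frame manifest with `audio_path`/`annotation_path` columns.
#' @export
load_deposited_layout <- function(root) {
  if (!dir.exists(root)) {
    stop(structure(class = c("vibrotemp_dataset_missing", "error",
                             "condition"),
                   list(message = paste0(
                     "deposited dataset not found at '", root, "'"),
                     call = sys.call(-1))))
  }
  dirs <- list.dirs(root, recursive = FALSE)
  groups <- suppressWarnings(as.numeric(basename(dirs)))
  dirs <- dirs[!is.na(groups)]
  groups <- groups[!is.na(groups)]
  if (length(dirs) == 0) stop("no temperature-group folders under ", root)
  rows <- list()
  for (i in seq_along(dirs)) {
    wavs <- list.files(dirs[i], pattern = "\\.wav$", full.names = TRUE)
    for (w in wavs) {
      ann <- sub("\\.wav$", ".json", w)
      if (!file.exists(ann)) next
      a <- jsonlite::read_json(ann, simplifyVector = TRUE)
      validate_annotation(a, ann)
      rows[[length(rows) + 1L]] <- data.frame(
        recording_id = a$recording_id, audio_path = w,
        annotation_path = ann, temperature_group = groups[i],
        measured_temperature = a$measured_temperature,
        L1 = a$L1, L2 = a$L2, L3 = a$L3, L4 = a$L4,
        speed_mm_s = a$speed_mm_s %||% NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no annotated recordings found under ", root)
  do.call(rbind, rows)
}

#' Full-scale evaluation on the deposited recordings
#'
#' Runs the complete pipeline -- peak detection, peak-centred chunking,
#' grouped fivefold cross-validation at the full training schedule --
#' against a local copy of the publicly deposited recordings. This is an
#' extended, compute-heavy run; it is not part of the synthetic desk-scale
#' validation. When no local copy exists the function signals a typed
#' `vibrotemp_dataset_missing` condition so callers can detect the
#' situation programmatically.
#'
#' @param root Root directory of the deposited dataset (default: the
#'   `VIBROTEMP_DATA` environment variable).
#' @param cfg A [train_config()]; defaults to the full 70-epoch schedule.
#' @return A list with the `cv_result`, the [group_table()] and chunk-level
#'   RMSE of the held-out predictions.
#' @export
evaluate_deposited <- function(root = Sys.getenv("VIBROTEMP_DATA", ""),
                               cfg = train_config(arch = "resnet18",
                                                  pretrained = TRUE)) {
  if (!nzchar(root) || !dir.exists(root)) {
    stop(structure(class = c("vibrotemp_dataset_missing", "error",
                             "condition"),
                   list(message = paste0(
                     "deposited dataset not available",
                     if (nzchar(root)) paste0(" at '", root, "'") else
                       " (set VIBROTEMP_DATA to a local copy)"),
                     call = sys.call(-1))))
  }
  manifest <- load_deposited_layout(root)
  recordings <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    w <- read_wav(m$audio_path, expect_rate = 48000,
                  on_rate_mismatch = "resample")
    structure(list(waveform = w$waveform, sample_rate = w$sample_rate,
                   L1 = m$L1, L2 = m$L2, L3 = m$L3, L4 = m$L4,
                   temperature_group = m$temperature_group,
                   measured_temperature = m$measured_temperature,
                   true_event_times = numeric(0),
                   speed_mm_s = m$speed_mm_s,
                   recording_id = m$recording_id),
              class = "annotated_recording")
  })
  set.seed(cfg$seed)
  chunks <- peak_chunks(recordings)
  folds <- make_folds(chunk_index(chunks))
  lookup <- stats::setNames(manifest$temperature_group, manifest$recording_id)
  cv <- train_model(chunks, folds, cfg, group_lookup = lookup)
  list(cv = cv,
       group_table = group_table(cv$predictions),
       chunk_rmse = rmse(cv$predictions$prediction, cv$predictions$truth))
}

#' Save / load a run configuration
#'
#' Serializes the full parameter set of a pipeline run (generator, detector,
#' segmentation and training blocks plus seed and output directory) as
#' JSON; `load_run_config(save_run_config(cfg, path))` restores it exactly.
#'
#' @param config Named list of parameter blocks.
#' @param path JSON file path.
#' @return `save_run_config` returns `path` invisibly; `load_run_config`
#'   the restored list.
#' @export
save_run_config <- function(config, path) {
  jsonlite::write_json(c(list(schema_version = ANNOTATION_SCHEMA), config),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_run_config
#' @export
load_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$schema_version <- NULL
  cfg
}
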