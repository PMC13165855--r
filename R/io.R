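# Plain-text readers and writers for the array-dump interchange formats:
# a continuous recording is a channels x time CSV plus a JSON sidecar with
# sampling rate, channel names and subject id; behavioral streams are flat
# CSVs. EDF and HDF5 containers are not supported by this build.

#' Read a continuous recording from CSV + JSON sidecar
#'
#' The CSV holds one channel per row (no header, time along columns); the
#' sidecar JSON must provide `fs` and may provide `channel_names` and
#' `subject_id`.
#'
#' @param csv_path Path to the samples CSV.
#' @param sidecar_path Path to the JSON sidecar; defaults to the CSV path
#'   with extension `.json`.
#' @return List with `samples` (C x T matrix), `fs`, `channel_names`,
#'   `subject_id`.
#' @export
read_eeg_csv <- function(csv_path, sidecar_path = NULL) {
  if (is.null(sidecar_path)) {
    sidecar_path <- sub("\\.csv$", ".json", csv_path)
  }
  if (!file.exists(sidecar_path)) {
    stop("sidecar JSON not found: ", sidecar_path)
  }
  meta <- jsonlite::fromJSON(sidecar_path)
  if (is.null(meta$fs)) stop("sidecar must provide 'fs'")
  x <- as.matrix(utils::read.csv(csv_path, header = FALSE))
  dimnames(x) <- NULL
  if (!is.null(meta$channel_names)) {
    if (length(meta$channel_names) != nrow(x)) {
      stop("sidecar lists ", length(meta$channel_names),
           " channel names but the CSV has ", nrow(x), " rows")
    }
    rownames(x) <- meta$channel_names
  }
  list(samples = x, fs = meta$fs,
       channel_names = meta$channel_names,
       subject_id = if (is.null(meta$subject_id)) NA_character_ else
         meta$subject_id)
}

#' @rdname read_eeg_csv
#' @param samples C x T numeric matrix.
#' @param fs Sampling rate (Hz).
#' @param path Output CSV path (sidecar written next to it).
#' @param channel_names,subject_id Stored in the sidecar.
#' @export
write_eeg_csv <- function(samples, fs, path, channel_names = NULL,
                          subject_id = NA_character_) {
  utils::write.table(samples, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(fs = fs, subject_id = subject_id)
  if (!is.null(channel_names)) meta$channel_names <- channel_names
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read deviation-event streams
#'
#' CSV with columns `subject_id`, `dep_s`, `act_s`; returns one
#' [session_events()] per subject, in order of first appearance.
#'
#' @param path CSV path.
#' @return Named list of `session_events`.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "dep_s", "act_s")
  if (!all(need %in% names(df))) {
    stop("events CSV must have columns ", paste(need, collapse = ", "))
  }
  ids <- unique(df$subject_id)
  out <- lapply(ids, function(s) {
    d <- df[df$subject_id == s, ]
    session_events(d$dep_s, d$act_s, s)
  })
  names(out) <- ids
  out
}

#' Read per-epoch eye-tracking durations
#'
#' CSV with columns `subject_id`, `epoch_index`, `t_blink`, `t_fixation`,
#' `t_saccade`, `t_closure`.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_eye_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "epoch_index", "t_blink", "t_fixation",
            "t_saccade", "t_closure")
  if (!all(need %in% names(df))) {
    stop("eye-tracking CSV must have columns ", paste(need, collapse = ", "))
  }
  df
}

#' Write derived labels
#'
#' @param df Data frame with at least `subject_id`, `epoch_index`,
#'   `label`.
#' @param path Output CSV path.
#' @export
write_labels_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding the configuration and all weight arrays
#' plus batch-norm running statistics; the round trip is exact, so a
#' reloaded model produces bit-identical forward outputs.
#'
#' @param model A `dcamnet_model`.
#' @param path Checkpoint path (`.rds`).
#' @export
save_dcamnet <- function(model, path) {
  stopifnot(inherits(model, "dcamnet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_dcamnet
#' @export
load_dcamnet <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dcamnet_model")) stop("not a model checkpoint: ", path)
  model
}

#' Export a model configuration as JSON
#'
#' @param cfg A `dcamnet_config`.
#' @param path Output path.
#' @export
write_config_json <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
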