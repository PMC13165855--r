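#' A single EEG epoch
#'
#' One fixed-length segment of preprocessed EEG, channels x time, treated as
#' an independent classification sample. Values are in microvolts.
#'
#' @param samples Numeric matrix, channels x time; all values finite.
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject label (free-form).
#' @param label Optional class label: 0 (alert), 1 (fatigued) or `NA`.
#' @param channel_names Optional character vector, one name per row.
#' @return An `eeg_epoch` object.
#' @export
eeg_epoch <- function(samples, fs, subject_id = NA_character_,
                      label = NA_integer_, channel_names = NULL) {
  stopifnot(is.matrix(samples), is.numeric(samples),
            nrow(samples) >= 1L, ncol(samples) >= 1L)
  if (!all(is.finite(samples))) stop("epoch contains non-finite samples")
  if (!is.na(label) && !label %in% c(0L, 1L)) {
    stop("label must be 0, 1 or NA")
  }
  if (!is.null(channel_names)) {
    stopifnot(length(channel_names) == nrow(samples))
    rownames(samples) <- channel_names
  }
  structure(list(samples = samples, fs = fs,
                 subject_id = as.character(subject_id),
                 label = if (is.na(label)) NA_integer_ else as.integer(label)),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("EEG epoch: %d channels x %d samples @ %g Hz, subject %s, label %s\n",
              nrow(x$samples), ncol(x$samples), x$fs, x$subject_id,
              ifelse(is.na(x$label), "?", x$label)))
  invisible(x)
}

#' Segment a continuous recording into epochs
#'
#' Without anchors, the recording is cut into contiguous non-overlapping
#' windows of `epoch_seconds`, the trailing remainder discarded. With
#' anchors (event-locked mode), each epoch is the window
#' `[anchor - epoch_seconds, anchor)` immediately preceding the event;
#' anchors too close to the recording start are skipped with a warning.
#' Time windows are half-open in seconds; sample indices are 0-based, so an
#' anchor at `t` seconds maps to sample `round(t * fs)` (exclusive end).
#'
#' @param continuous Numeric matrix, channels x time.
#' @param fs Sampling rate in Hz.
#' @param epoch_seconds Epoch length in seconds; `epoch_seconds * fs` must
#'   be a whole number of samples.
#' @param anchors Optional numeric vector of event times in seconds.
#' @param subject_id,channel_names Passed through to each [eeg_epoch()].
#' @return List of `eeg_epoch` objects.
#' @export
segment_epochs <- function(continuous, fs, epoch_seconds, anchors = NULL,
                           subject_id = NA_character_, channel_names = NULL) {
  stopifnot(is.matrix(continuous), fs > 0, epoch_seconds > 0)
  tlen_f <- epoch_seconds * fs
  tlen <- as.integer(round(tlen_f))
  if (abs(tlen_f - tlen) > 1e-9) {
    stop("epoch_seconds * fs = ", tlen_f, " is not a whole number of samples")
  }
  total <- ncol(continuous)
  if (is.null(anchors)) {
    n <- total %/% tlen
    return(lapply(seq_len(n), function(i) {
      eeg_epoch(continuous[, ((i - 1L) * tlen + 1L):(i * tlen), drop = FALSE],
                fs, subject_id, channel_names = channel_names)
    }))
  }
  out <- list()
  for (a in anchors) {
    end0 <- as.integer(round(a * fs))      # exclusive, 0-based
    start0 <- end0 - tlen
    if (start0 < 0L || end0 > total) {
      warning("anchor at ", a, " s skipped: window [", a - epoch_seconds,
              ", ", a, ") s not fully inside the recording")
      next
    }
    out[[length(out) + 1L]] <-
      eeg_epoch(continuous[, (start0 + 1L):end0, drop = FALSE], fs,
                subject_id, channel_names = channel_names)
  }
  out
}

#' Bundle epochs into a labeled dataset
#'
#' The dataset container used by the training and evaluation protocols:
#' a list of same-shape epochs with aligned label and subject vectors.
#'
#' @param epochs List of channels x time matrices (or `eeg_epoch` objects,
#'   whose samples are extracted).
#' @param labels Integer vector of 0/1 labels, one per epoch.
#' @param subjects Character vector of subject ids, one per epoch.
#' @param fs Sampling rate in Hz.
#' @param channel_names Optional channel names shared by all epochs.
#' @return An `eeg_dataset` object.
#' @export
eeg_dataset <- function(epochs, labels, subjects, fs, channel_names = NULL) {
  epochs <- lapply(epochs, function(e) if (inherits(e, "eeg_epoch")) e$samples else e)
  n <- length(epochs)
  stopifnot(n >= 1L, length(labels) == n, length(subjects) == n)
  dims <- vapply(epochs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all epochs must share the same channels x time shape")
  }
  if (is.null(channel_names)) channel_names <- rownames(epochs[[1]])
  if (!is.null(channel_names)) stopifnot(length(channel_names) == dims[1, 1])
  structure(list(epochs = epochs, labels = as.integer(labels),
                 subjects = as.character(subjects), fs = fs,
                 channel_names = channel_names),
            class = "eeg_dataset")
}

#' @export
print.eeg_dataset <- function(x, ...) {
  d <- dim(x$epochs[[1]])
  cat(sprintf("EEG dataset: %d epochs (%d x %d @ %g Hz), %d subjects, %d fatigued / %d alert\n",
              length(x$epochs), d[1], d[2], x$fs,
              length(unique(x$subjects)),
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' Remove channels from a dataset
#'
#' Channel (electrode) ablation: returns a copy of the dataset with the
#' requested channels removed from every epoch, so models configured from
#' it use the reduced channel count. Used for the frontal-channel ablation
#' analysis.
#'
#' @param dataset An [eeg_dataset()].
#' @param channels Channel names (matched against `channel_names`) or
#'   integer row indices to drop. Empty selection returns the dataset
#'   unchanged.
#' @return A new `eeg_dataset` with `C' = C - length(channels)`.
#' @export
drop_channels <- function(dataset, channels) {
  stopifnot(inherits(dataset, "eeg_dataset"))
  if (length(channels) == 0L) return(dataset)
  C <- nrow(dataset$epochs[[1]])
  if (is.character(channels)) {
    if (is.null(dataset$channel_names)) {
      stop("dataset has no channel names; use integer indices")
    }
    miss <- setdiff(channels, dataset$channel_names)
    if (length(miss)) {
      stop("unknown channel name(s): ", paste(miss, collapse = ", "),
           "; available: ", paste(dataset$channel_names, collapse = ", "))
    }
    idx <- match(channels, dataset$channel_names)
  } else {
    idx <- as.integer(channels)
    if (any(idx < 1L | idx > C)) stop("channel index out of range 1..", C)
  }
  keep <- setdiff(seq_len(C), idx)
  if (length(keep) == 0L) stop("cannot drop every channel")
  eeg_dataset(lapply(dataset$epochs, function(e) e[keep, , drop = FALSE]),
              dataset$labels, dataset$subjects, dataset$fs,
              channel_names = dataset$channel_names[keep])
}
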