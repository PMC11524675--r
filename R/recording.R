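#' Multichannel EEG recording
#'
#' The basic data container: a channels x samples numeric matrix of scalp
#' potentials (nominal microvolts), the sampling rate, ordered unique channel
#' labels, a group label and a subject identifier.
#'
#' @param signal Numeric matrix, channels in rows, samples in columns. No
#'   missing values are allowed.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector, one unique label per row of
#'   `signal`.
#' @param group Group label: `"MDD"`, `"HC"` or `"unknown"`.
#' @param subject_id Subject identifier string.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(signal, fs, channel_labels,
                      group = c("unknown", "MDD", "HC"),
                      subject_id = "s01") {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  group <- match.arg(group)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("fs must be a single positive number")
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(signal)) {
    stop("channel_labels length (", length(channel_labels),
         ") must equal the number of signal rows (", nrow(signal), ")")
  }
  if (anyDuplicated(channel_labels)) {
    stop("duplicate channel labels: ",
         paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", "))
  }
  if (anyNA(signal) || any(!is.finite(signal))) {
    stop("signal contains missing or non-finite values")
  }
  rownames(signal) <- channel_labels
  structure(
    list(signal = signal, fs = fs, channel_labels = channel_labels,
         group = group, subject_id = as.character(subject_id)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", x$subject_id, " [", x$group, "]: ",
      nrow(x$signal), " channels x ", ncol(x$signal), " samples @ ",
      x$fs, " Hz (", round(ncol(x$signal) / x$fs, 2), " s)\n", sep = "")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Length in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$signal) / rec$fs

#' Analysis window
#'
#' A fixed-length segment of a recording, produced by [segment_recording()].
#' Carries the same fields as an `eeg_recording` plus `window_index`.
#'
#' @param rec An `eeg_recording` (segment-sized).
#' @param window_index 1-based index of the window within its recording.
#' @return An object of classes `eeg_window` and `eeg_recording`.
#' @export
as_window <- function(rec, window_index) {
  stopifnot(inherits(rec, "eeg_recording"))
  rec$window_index <- as.integer(window_index)
  class(rec) <- c("eeg_window", class(rec))
  rec
}
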