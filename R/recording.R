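#' Multichannel EEG recording
#'
#' Container for a continuous multichannel recording: a channels x samples
#' signal matrix in microvolts, the sampling rate, the ordered channel
#' labels, an event table and the label of the recording reference
#' electrode.  Time is expressed as 0-based seconds from the first sample.
#'
#' The recording reference (by default `Cz`) is kept in the data as an
#' explicit all-zero channel rather than being dropped: common-average
#' re-referencing is only correct when the reference electrode participates
#' in the across-channel mean.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channels Character vector of channel labels; defaults to
#'   `rownames(data)`.
#' @param events Data frame with columns `onset_s` (seconds from recording
#'   start) and `label` (one of `eyes_open`, `eyes_closed`, `stim`,
#'   `session_boundary`).
#' @param reference Label of the recording reference electrode.
#' @return An object of class `eeg_recording`.
#' @examples
#' x <- matrix(rnorm(2 * 100), nrow = 2,
#'             dimnames = list(c("O1", "O2"), NULL))
#' rec <- eeg_recording(x, fs = 100)
#' @export
eeg_recording <- function(data, fs, channels = rownames(data),
                          events = empty_events(), reference = "Cz") {
  if (is.null(channels)) stop("channel labels are required", call. = FALSE)
  rec <- structure(
    list(
      data = unname(as.matrix(data)),
      fs = as.numeric(fs),
      channels = as.character(channels),
      events = events,
      reference = reference
    ),
    class = "eeg_recording"
  )
  validate_recording(rec)
}

event_labels <- function() c("eyes_open", "eyes_closed", "stim",
                             "session_boundary")

#' @rdname eeg_recording
#' @export
empty_events <- function() {
  data.frame(onset_s = numeric(0), label = character(0),
             stringsAsFactors = FALSE)
}

validate_events <- function(events, duration = NULL) {
  if (!is.data.frame(events) ||
      !all(c("onset_s", "label") %in% names(events))) {
    stop("events must be a data.frame with columns onset_s, label",
         call. = FALSE)
  }
  bad <- setdiff(unique(events$label), event_labels())
  if (length(bad)) {
    stop("unknown event labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(events) > 1 && any(diff(events$onset_s) <= 0)) {
    stop("event onsets must be strictly increasing", call. = FALSE)
  }
  if (!is.null(duration) && nrow(events) &&
      (any(events$onset_s < 0) || any(events$onset_s >= duration))) {
    stop("event onsets must lie within the recording duration",
         call. = FALSE)
  }
  invisible(events)
}

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(rec$fs) || length(rec$fs) != 1 || rec$fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  if (anyDuplicated(rec$channels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  if (nrow(rec$data) != length(rec$channels)) {
    stop("data row count must equal the number of channel labels",
         call. = FALSE)
  }
  if (anyNA(rec$data)) stop("recording contains NA samples", call. = FALSE)
  validate_events(rec$events, duration = recording_duration(rec))
  rec
}

recording_duration <- function(rec) ncol(rec$data) / rec$fs

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events, ref %s\n",
    nrow(x$data), ncol(x$data), x$fs, recording_duration(x),
    nrow(x$events), x$reference
  ))
  invisible(x)
}

#' Read / write event tables
#'
#' Events are stored next to the signal file as a tab-separated table with
#' columns `onset_s` (seconds from recording start) and `label`.
#'
#' @param path Path of the TSV file.
#' @param events Event data.frame (see [eeg_recording()]).
#' @return `read_events()` returns the event data.frame.
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("numeric", "character"))
  validate_events(ev)
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  validate_events(events)
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a recording from an EDF file with a sidecar event table
#'
#' All channels must share one sampling rate; a mixed-rate file is a format
#' error.  Channel labels not in the standard montage trigger a warning but
#' the channel is kept.  The signal is returned in microvolts.
#'
#' @param path EDF signal file.
#' @param events_path Optional TSV event table (columns `onset_s`, `label`).
#' @param reference Label of the recording reference electrode.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, events_path = NULL, reference = "Cz") {
  edf <- read_edf(path)
  events <- if (!is.null(events_path)) read_events(events_path)
            else empty_events()
  unknown <- setdiff(edf$channels, standard_montage()$label)
  if (length(unknown)) {
    warning("channel labels not in the standard montage: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  eeg_recording(edf$data, fs = edf$fs, channels = edf$channels,
                events = events, reference = reference)
}

#' Write a recording to an EDF file with a sidecar event table
#'
#' The physical range of each EDF signal is chosen symmetric around zero and
#' wide enough to cover the data, so nothing is ever silently clipped; if an
#' explicit `phys_max` is given and the signal exceeds it, writing fails.
#' Samples are quantized to the 16-bit EDF grid; the round-trip error is at
#' most one quantization step.
#'
#' @param rec An [eeg_recording()].
#' @param path Output EDF file.
#' @param events_path Optional output TSV for the event table (written only
#'   when given).
#' @param phys_max Optional physical range bound in microvolts (applies to
#'   all channels).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, events_path = NULL, phys_max = NULL) {
  validate_recording(rec)
  write_edf(rec$data, rec$fs, rec$channels, path, phys_max = phys_max)
  if (!is.null(events_path)) write_events(rec$events, events_path)
  invisible(path)
}
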