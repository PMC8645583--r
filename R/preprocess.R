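# Deterministic signal conditioning shared by both analysis branches:
# zero-phase Butterworth filtering, common-average referencing, epoching
# and baseline correction.

# Forward-backward IIR filtering with odd-reflection padding and
# steady-state initial conditions (so a step input produces no start-up
# transient).  Net phase response is zero; the magnitude response is the
# squared single-pass response.
zero_phase_filter <- function(x, b, a) {
  n <- length(x)
  p <- min(3L * max(length(a), length(b)), n - 1L)
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  dc_gain <- sum(b) / sum(a)
  pass <- function(v) {
    as.numeric(signal::filter(b, a, v,
                              init.x = rep(v[1], length(b) - 1),
                              init.y = rep(v[1] * dc_gain, length(a) - 1)))
  }
  y <- rev(pass(rev(pass(xp))))
  y[(p + 1):(p + n)]
}

filter_recording <- function(rec, b, a) {
  validate_recording(rec)
  rec$data <- t(apply(rec$data, 1, zero_phase_filter, b = b, a = a))
  rec
}

#' Zero-phase Butterworth high-pass filter
#'
#' A Butterworth high-pass applied forward and backward (zero net phase
#' shift, effective magnitude order `2 * order`), removing the DC offset.
#' Applied to the continuous recording before epoching.
#'
#' @param rec An [eeg_recording()].
#' @param cutoff Cutoff frequency, Hz.
#' @param order Filter order of the single pass.
#' @return The filtered recording.
#' @export
highpass_zero_phase <- function(rec, cutoff = 0.1, order = 3) {
  if (cutoff >= rec$fs / 2) stop("cutoff must be below fs/2", call. = FALSE)
  bt <- signal::butter(order, cutoff / (rec$fs / 2), type = "high")
  filter_recording(rec, bt$b, bt$a)
}

#' Zero-phase Butterworth band-stop (notch) filter
#'
#' Used in the stimulation branch to remove mains interference (default
#' stop band 48--52 Hz).
#'
#' @param rec An [eeg_recording()].
#' @param band Two-element stop band in Hz.
#' @param order Filter order of the single pass.
#' @return The filtered recording.
#' @export
bandstop_zero_phase <- function(rec, band = c(48, 52), order = 3) {
  if (band[1] >= band[2]) stop("inverted stop band", call. = FALSE)
  if (band[1] <= 0 || band[2] >= rec$fs / 2) {
    stop("stop band must lie inside (0, fs/2)", call. = FALSE)
  }
  bt <- signal::butter(order, band / (rec$fs / 2), type = "stop")
  filter_recording(rec, bt$b, bt$a)
}

#' Common-average reference
#'
#' Subtracts, at every sample, the mean across all channels.  The recording
#' reference electrode must still be present (as its all-zero channel) for
#' the re-referencing to be exact.
#'
#' @param rec An [eeg_recording()].
#' @return The re-referenced recording (`reference` set to `"CAR"`).
#' @export
common_average_reference <- function(rec) {
  validate_recording(rec)
  if (nrow(rec$data) < 2) {
    stop("common average reference needs at least 2 channels",
         call. = FALSE)
  }
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec$reference <- "CAR"
  rec
}

#' Cut a recording into event-locked epochs
#'
#' One trial is cut per matching event over the half-open window
#' `[tmin, tmax)` relative to the event onset.  Trials that would reach
#' beyond either end of the recording are dropped (with a message), never
#' zero-padded.
#'
#' @param rec An [eeg_recording()].
#' @param label Event label(s) to epoch on.
#' @param tmin,tmax Window in seconds relative to the event onset
#'   (half-open, `tmax` excluded).
#' @return An object of class `eeg_epochs`: a trials x channels x samples
#'   array plus `fs`, `tmin`, `tmax`, `channels` and per-trial `metadata`
#'   (`label`, `onset_s`).
#' @export
epoch <- function(rec, label, tmin, tmax) {
  validate_recording(rec)
  stopifnot(tmax > tmin)
  ev <- rec$events[rec$events$label %in% label, , drop = FALSE]
  if (nrow(ev) == 0) {
    stop("no events with label ", paste(label, collapse = "/"),
         call. = FALSE)
  }
  n_samp <- round((tmax - tmin) * rec$fs)
  start <- round((ev$onset_s + tmin) * rec$fs) + 1L
  ok <- start >= 1L & (start + n_samp - 1L) <= ncol(rec$data)
  if (!all(ok)) {
    message(sum(!ok), " trial(s) dropped at the recording boundaries")
  }
  ev <- ev[ok, , drop = FALSE]
  start <- start[ok]
  if (nrow(ev) == 0) stop("all matching trials fall outside the recording",
                          call. = FALSE)
  data <- array(0, dim = c(nrow(ev), nrow(rec$data), n_samp),
                dimnames = list(NULL, rec$channels, NULL))
  for (i in seq_along(start)) {
    data[i, , ] <- rec$data[, start[i]:(start[i] + n_samp - 1L)]
  }
  structure(
    list(data = data, fs = rec$fs, tmin = tmin, tmax = tmax,
         channels = rec$channels,
         metadata = data.frame(label = ev$label, onset_s = ev$onset_s,
                               stringsAsFactors = FALSE)),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz, window [%g, %g) s\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs, x$tmin, x$tmax
  ))
  invisible(x)
}

# times of epoch samples relative to the event onset
epoch_times <- function(epochs) {
  epochs$tmin + (seq_len(dim(epochs$data)[3]) - 1) / epochs$fs
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, a summary statistic (default: the
#' median) of the samples in a pre-stimulus window from the whole epoch.
#' The default window covers the first 40 ms of the pre-stimulus span,
#' i.e. `[tmin, tmin + 0.04)` -- for the standard stimulation epoch of
#' [-50, +300) ms this is [-50, -10) ms, which keeps any stimulation
#' artifact ringing just before onset out of the baseline.
#'
#' @param epochs An `eeg_epochs` object (see [epoch()]).
#' @param window Half-open baseline window in seconds, within `[tmin, 0)`.
#' @param statistic Summary function applied over the window.
#' @return The baseline-corrected epochs.
#' @export
baseline_correct <- function(epochs, window = NULL, statistic = stats::median) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (is.null(window)) window <- c(epochs$tmin, epochs$tmin + 0.04)
  if (window[1] < epochs$tmin || window[2] > 0 || window[1] >= window[2]) {
    stop("baseline window must be half-open, inside [tmin, 0)",
         call. = FALSE)
  }
  t <- epoch_times(epochs)
  idx <- which(t >= window[1] - 1e-9 & t < window[2] - 1e-9)
  if (!length(idx)) stop("baseline window contains no samples",
                         call. = FALSE)
  base <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), statistic)
  epochs$data <- epochs$data - as.vector(base)  # recycles over samples
  epochs
}
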