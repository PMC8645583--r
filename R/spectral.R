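# Frequency-domain branch: per-trial FFT power spectra, across-trial
# medians, time-resolved relative (eyes-closed / eyes-open) spectra,
# subject-specific alpha-band summaries and differential artifact peaks.

# one-sided power of a samples x series matrix (rectangular window):
# P_k = (2/N^2)|X_k|^2 at interior bins, (1/N^2)|X_k|^2 at DC and Nyquist,
# so a sinusoid of amplitude a at a bin frequency carries a^2/2 there.
one_sided_power <- function(x) {
  n <- nrow(x)
  X <- stats::mvfft(x)
  n_bins <- floor(n / 2) + 1L
  p <- abs(X[seq_len(n_bins), , drop = FALSE])^2 * (2 / n^2)
  p[1, ] <- p[1, ] / 2
  if (n %% 2 == 0) p[n_bins, ] <- p[n_bins, ] / 2
  p
}

#' Per-trial power spectra
#'
#' Computes, for every trial and channel, the one-sided FFT power spectrum
#' of the complete epoch (rectangular window, no tapering or segment
#' averaging).  With the scaling used, a sinusoid of amplitude `a`
#' microvolts at a bin frequency contributes `a^2 / 2` square-microvolts at
#' that bin, and the frequency axis extends to the Nyquist frequency with a
#' resolution of one over the epoch duration.
#'
#' @param epochs An `eeg_epochs` object (see [epoch()]).
#' @return An object of class `eeg_spectra`: `freqs` (Hz), `power`
#'   (trials x channels x bins, square-microvolts), `channels`, `metadata`.
#' @examples
#' cfg <- test_generator_config(seed = 1)
#' rec <- simulate_berger_session(cfg, "No-VR")
#' sp <- power_spectrum(epoch(rec, "eyes_closed", 0, 10))
#' @export
power_spectrum <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  if (d[1] < 1) stop("no trials", call. = FALSE)
  n <- d[3]
  # samples x (trial*channel) matrix, FFT once
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n)
  p <- one_sided_power(flat)
  n_bins <- nrow(p)
  power <- aperm(array(t(p), dim = c(d[1], d[2], n_bins)), c(1, 2, 3))
  dimnames(power) <- list(NULL, epochs$channels, NULL)
  structure(
    list(freqs = (seq_len(n_bins) - 1) * epochs$fs / n,
         power = power, channels = epochs$channels,
         metadata = epochs$metadata),
    class = "eeg_spectra"
  )
}

#' Across-trial median spectrum
#'
#' @param specs An `eeg_spectra` object (see [power_spectrum()]).
#' @return Channels x bins matrix of element-wise medians over trials.
#' @export
median_spectrum <- function(specs) {
  stopifnot(inherits(specs, "eeg_spectra"))
  out <- apply(specs$power, c(2, 3), stats::median)
  rownames(out) <- specs$channels
  out
}

# power spectra of all sliding windows of all trials:
# array [trial, window, channel, bin] plus window-center times
sliding_power <- function(epochs, window_s, step_s) {
  d <- dim(epochs$data)
  wlen <- round(window_s * epochs$fs)
  step <- round(step_s * epochs$fs)
  if (wlen > d[3]) stop("sliding window longer than the epoch", call. = FALSE)
  starts <- seq(1L, d[3] - wlen + 1L, by = step)
  n_bins <- floor(wlen / 2) + 1L
  out <- array(0, dim = c(d[1], length(starts), d[2], n_bins))
  for (w in seq_along(starts)) {
    seg <- epochs$data[, , starts[w]:(starts[w] + wlen - 1L), drop = FALSE]
    flat <- matrix(aperm(seg, c(3, 1, 2)), nrow = wlen)
    out[, w, , ] <- array(t(one_sided_power(flat)),
                          dim = c(d[1], d[2], n_bins))
  }
  list(power = out,
       times = epochs$tmin + (starts - 1 + wlen / 2) / epochs$fs,
       freqs = (seq_len(n_bins) - 1) * epochs$fs / wlen)
}

#' Time-resolved relative (eyes-closed / eyes-open) spectrum
#'
#' Slides a window (default 2,500 ms, step 250 ms) over every eyes-closed
#' trial, computes the window power spectrum, divides it bin-wise by an
#' eyes-open baseline spectrum -- the across-trial, across-window median
#' spectrum of all eyes-open trials at the same window length -- and takes
#' the across-trial median ratio per time, channel and bin.
#'
#' @param closed,open `eeg_epochs` objects with the eyes-closed and
#'   eyes-open trials.
#' @param window_s Sliding-window length, seconds.
#' @param step_s Window step, seconds.
#' @return An object of class `relative_spectrogram`: `times` (window
#'   centers, s), `freqs` (Hz), `ratio` (times x channels x bins),
#'   `channels`.
#' @export
sliding_relative_spectrogram <- function(closed, open, window_s = 2.5,
                                         step_s = 0.25) {
  stopifnot(inherits(closed, "eeg_epochs"), inherits(open, "eeg_epochs"),
            identical(closed$channels, open$channels),
            closed$fs == open$fs)
  sc <- sliding_power(closed, window_s, step_s)
  so <- sliding_power(open, window_s, step_s)
  d <- dim(so$power)
  # baseline: median over (trial, window) pairs -> channels x bins
  flat_open <- array(so$power, dim = c(d[1] * d[2], d[3], d[4]))
  baseline <- apply(flat_open, c(2, 3), stats::median)
  if (any(baseline == 0)) {
    stop("degenerate eyes-open baseline: zero power bin", call. = FALSE)
  }
  dc <- dim(sc$power)
  ratio <- array(0, dim = dc)
  for (tr in seq_len(dc[1])) {
    for (w in seq_len(dc[2])) {
      ratio[tr, w, , ] <- sc$power[tr, w, , ] / baseline
    }
  }
  med <- apply(ratio, c(2, 3, 4), stats::median)
  dimnames(med) <- list(NULL, closed$channels, NULL)
  structure(
    list(times = sc$times, freqs = sc$freqs, ratio = med,
         channels = closed$channels),
    class = "relative_spectrogram"
  )
}

#' Subject-specific alpha-band summary
#'
#' Finds the peak alpha frequency as the argmax, over a search range
#' (default 7--14 Hz), of the relative spectrum averaged over window times
#' and occipital electrodes, then summarizes the per-electrode mean
#' relative power in the band peak +/- 2 Hz (the subject- and
#' measurement-specific alpha band).
#'
#' @param rel A `relative_spectrogram` (see
#'   [sliding_relative_spectrogram()]).
#' @param search Two-element search range in Hz.
#' @return A list of class `alpha_summary`: `peak_freq` (Hz), `band`
#'   (Hz), `topography` (named per-electrode mean band ratio).
#' @export
alpha_summary <- function(rel, search = c(7, 14)) {
  stopifnot(inherits(rel, "relative_spectrogram"))
  in_range <- which(rel$freqs >= search[1] & rel$freqs <= search[2])
  if (!length(in_range)) stop("search range outside the frequency axis",
                              call. = FALSE)
  occ <- which(channel_regions(rel$channels) == "occipital")
  if (!length(occ)) occ <- seq_along(rel$channels)
  prof <- apply(rel$ratio[, occ, in_range, drop = FALSE], 3, mean)
  if (max(prof) - min(prof) < 1e-12) {
    warning("flat relative spectrum in the alpha search range; ",
            "peak set to the range midpoint", call. = FALSE)
    peak_freq <- mean(search)
  } else {
    peak_freq <- rel$freqs[in_range[which.max(prof)]]
  }
  band <- c(peak_freq - 2, peak_freq + 2)
  in_band <- which(rel$freqs >= band[1] & rel$freqs <= band[2])
  topo <- apply(rel$ratio[, , in_band, drop = FALSE], 2, mean)
  names(topo) <- rel$channels
  structure(list(peak_freq = peak_freq, band = band, topography = topo),
            class = "alpha_summary")
}

#' Differential artifact peaks between VR and No-VR spectra
#'
#' Groups contiguous runs of frequency bins that are significant on at
#' least one electrode (runs separated by at most `gap_bins` bins are
#' merged, since spectral leakage can split one line across neighbouring
#' bins).  Each group is reported at the bin maximizing the
#' electrode-median VR / No-VR power ratio, together with that ratio and
#' the number of electrodes significant there; groups are sorted by ratio,
#' descending.
#'
#' @param median_vr,median_novr Channels x bins median spectra (see
#'   [median_spectrum()]) on the same frequency axis as `sig_map`.
#' @param sig_map A `significance_map` (see
#'   [spectral_significance_map()]).
#' @param min_freq,max_freq Restrict to frequencies strictly between these
#'   bounds (Hz); `NULL` means unbounded.
#' @param gap_bins Maximum bin gap merged into one peak group.
#' @return Data frame with columns `freq`, `ratio`,
#'   `n_electrodes_significant`, sorted by `ratio` descending (zero rows if
#'   nothing is significant).
#' @export
differential_peaks <- function(median_vr, median_novr, sig_map,
                               min_freq = NULL, max_freq = NULL,
                               gap_bins = 2) {
  stopifnot(inherits(sig_map, "significance_map"),
            ncol(median_vr) == length(sig_map$freqs),
            ncol(median_novr) == length(sig_map$freqs))
  freqs <- sig_map$freqs
  keep <- rep(TRUE, length(freqs))
  if (!is.null(min_freq)) keep <- keep & freqs > min_freq
  if (!is.null(max_freq)) keep <- keep & freqs < max_freq
  sig_bins <- which(keep & colSums(sig_map$reject) > 0)
  empty <- data.frame(freq = numeric(0), ratio = numeric(0),
                      n_electrodes_significant = integer(0))
  if (!length(sig_bins)) return(empty)

  grp <- cumsum(c(1, diff(sig_bins) > gap_bins + 1))
  ratio_bin <- apply(median_vr / median_novr, 2, stats::median)
  out <- do.call(rbind, lapply(split(sig_bins, grp), function(bins) {
    best <- bins[which.max(ratio_bin[bins])]
    data.frame(freq = freqs[best], ratio = ratio_bin[best],
               n_electrodes_significant = sum(sig_map$reject[, best]))
  }))
  out <- out[order(-out$ratio), , drop = FALSE]
  rownames(out) <- NULL
  out
}
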