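# Synthetic paired VR / No-VR EEG sessions.
#
# The generator produces the statistical structure the benchmark probes:
# 1/f background activity, an occipitally dominant alpha oscillation whose
# amplitude depends on eye state, 50 Hz mains interference plus harmonics,
# optional headset-specific artifact line profiles, and jittered
# median-nerve stimulation trains carrying N20/P37 component templates
# concentrated at C6/CP4.

#' Generator configuration
#'
#' Default values reproduce the benchmark's study conditions: 64 channels
#' sampled at 5,000 Hz, 50 trials of 10 s per eye state, European 50 Hz
#' mains, and an alpha rhythm near 10 Hz that is stronger with closed eyes.
#' [test_generator_config()] gives a reduced preset (19 channels, 500 Hz,
#' 10 trials per eye state) used throughout the test suite; the reduced
#' scale changes nothing structural, only runtime and memory.
#'
#' @param fs Sampling rate in Hz.
#' @param channels Channel labels (subset of [standard_montage()]).
#' @param n_trials_per_task Eyes-open trials and eyes-closed trials per
#'   session.
#' @param trial_s Trial duration in seconds.
#' @param background_exponent Spectral slope gamma of the 1/f^gamma
#'   background (gamma = 0 is white noise).
#' @param background_scale Background RMS amplitude per channel, microvolts.
#' @param alpha_freq Nominal alpha frequency, Hz.
#' @param alpha_jitter Half-width of the uniform per-session alpha frequency
#'   jitter, Hz.
#' @param alpha_gain_closed,alpha_gain_open Peak alpha amplitude in
#'   microvolts during eyes-closed and eyes-open trials (closed > open).
#' @param mains_freq Mains frequency, Hz.
#' @param mains_amp Mains line RMS amplitude, microvolts.
#' @param mains_harmonics Number of harmonics above the fundamental.
#' @param mains_harmonic_decay Multiplicative amplitude decay per harmonic.
#' @param hmd_profile `NULL` or an [artifact_profile()]; applied only to VR
#'   sessions.
#' @param sep A [sep_config()].
#' @param seed Integer seed; identical config + seed gives a byte-identical
#'   session.
#' @param subject_seed Integer seed for subject- and setup-level parameters
#'   that are shared between the paired VR and No-VR sessions of one
#'   subject: the realized alpha frequency and the per-channel spatial
#'   weights of mains and headset lines.  Sessions simulated with the same
#'   `subject_seed` but different `seed`s emulate two recordings of the
#'   same subject in the same room.
#' @return A list of class `generator_config`.
#' @examples
#' cfg <- test_generator_config(seed = 1)
#' rec <- simulate_berger_session(cfg, "No-VR")
#' @export
generator_config <- function(fs = 5000,
                             channels = standard_montage()$label,
                             n_trials_per_task = 50,
                             trial_s = 10,
                             background_exponent = 1,
                             background_scale = 5,
                             alpha_freq = 10,
                             alpha_jitter = 1,
                             alpha_gain_closed = 8,
                             alpha_gain_open = 2,
                             mains_freq = 50,
                             mains_amp = 5,
                             mains_harmonics = 3,
                             mains_harmonic_decay = 0.3,
                             hmd_profile = NULL,
                             sep = sep_config(),
                             seed = NULL,
                             subject_seed = 1001L) {
  cfg <- structure(as.list(environment()), class = "generator_config")
  validate_generator_config(cfg)
}

#' @rdname generator_config
#' @param ... Overrides passed on to [generator_config()].
#' @export
test_generator_config <- function(...) {
  preset <- c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "T7", "C3", "Cz",
              "C6", "CP4", "P3", "P4", "Pz", "P7", "O1", "Oz", "O2", "POz")
  args <- list(fs = 500, channels = preset, n_trials_per_task = 10,
               sep = sep_config(n_sessions = 2, n_stim_per_session = 100))
  override <- list(...)
  args[names(override)] <- override
  do.call(generator_config, args)
}

validate_generator_config <- function(cfg) {
  if (cfg$background_exponent < 0) {
    stop("background_exponent must be >= 0", call. = FALSE)
  }
  if (!(cfg$alpha_gain_closed > cfg$alpha_gain_open)) {
    stop("alpha_gain_closed must exceed alpha_gain_open", call. = FALSE)
  }
  if (anyNA(match(cfg$channels, standard_montage()$label))) {
    stop("config channels must belong to the standard montage",
         call. = FALSE)
  }
  line_freqs <- cfg$mains_freq
  if (!is.null(cfg$hmd_profile)) {
    line_freqs <- c(line_freqs, cfg$hmd_profile$lines$freq)
  }
  if (any(cfg$fs <= 2 * line_freqs)) {
    stop("fs must exceed twice the highest injected line frequency",
         call. = FALSE)
  }
  cfg
}

#' Median-nerve stimulation configuration
#'
#' Defaults follow standard clinical practice: 5 sessions of 100
#' stimulations each, inter-stimulus intervals drawn uniformly from
#' 0.2--0.5 s (a 2--5 Hz stimulation rate), a negative N20 component at
#' 20 ms and a positive P37 at 37 ms, both concentrated at C6/CP4
#' (contralateral to left-wrist stimulation), plus a brief stimulation
#' artifact spike at onset.
#'
#' @param n_sessions Number of stimulation sessions.
#' @param n_stim_per_session Stimulations per session.
#' @param isi_range Inter-stimulus interval range in seconds.
#' @param components List of component templates; each a list with
#'   `polarity` (+1/-1), `latency_ms`, `width_ms` (FWHM of the Gaussian
#'   bump), `amplitude` (microvolts, positive), and `weights` (named
#'   electrode weights, normalized to max 1; unnamed electrodes get
#'   `spill`).
#' @param spill Weight applied to electrodes not named in a component's
#'   weight map.
#' @param artifact_amplitude Stimulation-artifact spike amplitude at t = 0,
#'   microvolts (0 disables).
#' @param artifact_width_ms Spike FWHM in milliseconds.
#' @return A list of class `sep_config`.
#' @export
sep_config <- function(n_sessions = 5,
                       n_stim_per_session = 100,
                       isi_range = c(0.2, 0.5),
                       components = list(
                         N20 = list(polarity = -1, latency_ms = 20,
                                    width_ms = 5, amplitude = 8,
                                    weights = c(C6 = 1, CP4 = 0.7,
                                                C4 = 0.5, CP6 = 0.4)),
                         P37 = list(polarity = 1, latency_ms = 37,
                                    width_ms = 10, amplitude = 8,
                                    weights = c(CP4 = 1, C6 = 0.6,
                                                P4 = 0.5, CPz = 0.4))
                       ),
                       spill = 0.05,
                       artifact_amplitude = 100,
                       artifact_width_ms = 1) {
  cfg <- structure(as.list(environment()), class = "sep_config")
  for (nm in names(cfg$components)) {
    comp <- cfg$components[[nm]]
    if (comp$latency_ms <= 0 || comp$latency_ms / 1000 >= isi_range[1]) {
      stop("component latency must be positive and below the minimum ISI",
           call. = FALSE)
    }
    w <- comp$weights
    if (max(w) != 1) cfg$components[[nm]]$weights <- w / max(w)
  }
  cfg
}

#' Headset artifact line profiles
#'
#' A profile is a named set of spectral lines (frequency, RMS amplitude,
#' harmonic count, harmonic decay).  Built-ins:
#' \describe{
#'   \item{`oculus_like`}{lines at 52 and 90 Hz with harmonics, plus
#'     high-amplitude lines above 100 Hz.}
#'   \item{`vive_like`}{no headset lines (near-clean).}
#'   \item{`env_87`}{a single 87 Hz environmental line, e.g. for a No-VR
#'     session contaminated by nearby equipment.}
#' }
#' Line amplitudes are not calibrated to any particular device; they are
#' chosen for reliable detectability by the downstream statistics.
#' Per-channel spatial weights are drawn (seeded) at injection time, making
#' the lines affect different electrodes to a different degree.
#'
#' @param name Profile name, or `"none"`/`NULL` for no profile.
#' @return A list of class `artifact_profile` with a `lines` data.frame
#'   (`freq`, `amp_rms`, `n_harmonics`, `harmonic_decay`).
#' @export
artifact_profile <- function(name = c("oculus_like", "vive_like", "env_87",
                                      "none")) {
  name <- match.arg(name)
  lines <- switch(name,
    oculus_like = data.frame(
      freq = c(52, 90, 125, 150, 220),
      amp_rms = c(2, 3, 4, 3, 5),
      n_harmonics = c(2, 1, 0, 0, 0),
      harmonic_decay = c(0.4, 0.5, 0, 0, 0)
    ),
    vive_like = data.frame(freq = numeric(0), amp_rms = numeric(0),
                           n_harmonics = integer(0),
                           harmonic_decay = numeric(0)),
    env_87 = data.frame(freq = 87, amp_rms = 2, n_harmonics = 0,
                        harmonic_decay = 0),
    none = NULL
  )
  if (is.null(lines)) return(NULL)
  if (any(lines$amp_rms < 0)) stop("line amplitudes must be >= 0",
                                   call. = FALSE)
  structure(list(name = name, lines = lines), class = "artifact_profile")
}

# expand a profile into individual (freq, amp) lines, dropping harmonics at
# or above Nyquist; base lines at/above Nyquist are an error
expand_profile_lines <- function(profile, fs) {
  if (is.null(profile) || nrow(profile$lines) == 0) {
    return(data.frame(freq = numeric(0), amp_rms = numeric(0)))
  }
  if (any(profile$lines$freq >= fs / 2)) {
    stop("artifact line frequency at or above Nyquist (fs/2)",
         call. = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(profile$lines)), function(i) {
    ln <- profile$lines[i, ]
    k <- 0:ln$n_harmonics
    data.frame(freq = ln$freq * (k + 1),
               amp_rms = ln$amp_rms * ln$harmonic_decay^k)
  }))
  out[out$freq < fs / 2 & out$amp_rms > 0, , drop = FALSE]
}

# evaluate a seeded expression without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Simulate 1/f background activity
#'
#' White Gaussian noise is shaped in the frequency domain so that the
#' expected one-sided power spectral density is proportional to
#' `1/f^gamma` above 1 Hz (flat below 1 Hz, zero at DC), then scaled to the
#' requested RMS.  Channels are independent.
#'
#' @param config A [generator_config()] (fields `background_exponent`,
#'   `background_scale`, `fs` are used).
#' @param n_channels Number of channels.
#' @param duration Seconds.
#' @return Matrix, channels x samples, microvolts.
#' @export
simulate_background <- function(config, n_channels, duration) {
  stopifnot(duration > 0)
  gamma <- config$background_exponent
  if (gamma < 0) stop("background_exponent must be >= 0", call. = FALSE)
  fs <- config$fs
  n <- round(duration * fs)
  if (config$background_scale == 0) {
    return(matrix(0, nrow = n_channels, ncol = n))
  }
  freqs <- seq(0, fs, length.out = n + 1)[1:n]
  freqs[freqs > fs / 2] <- fs - freqs[freqs > fs / 2]  # fold to [0, fs/2]
  shape <- 1 / pmax(freqs, 1)^(gamma / 2)
  shape[1] <- 0
  out <- matrix(0, nrow = n_channels, ncol = n)
  for (ch in seq_len(n_channels)) {
    w <- stats::rnorm(n)
    x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
    x <- x - mean(x)
    out[ch, ] <- x / stats::sd(x) * config$background_scale
  }
  out
}

#' Inject fixed-frequency spectral lines
#'
#' Adds a sinusoid per line per channel with independent uniform random
#' phases; the amplitude of each line is its RMS value times sqrt(2), scaled
#' by a per-channel spatial weight.
#'
#' @param signal Channels x samples matrix, microvolts.
#' @param profile An [artifact_profile()] (or `NULL` for identity).
#' @param fs Sampling rate, Hz.
#' @param weights Optional channels x lines weight matrix; defaults to 1
#'   for every channel and line.
#' @param phases Optional channels x lines phase matrix (radians); drawn
#'   uniformly at random when `NULL`.
#' @return The signal with lines added.
#' @export
inject_lines <- function(signal, profile, fs, weights = NULL,
                         phases = NULL) {
  lines <- expand_profile_lines(profile, fs)
  if (nrow(lines) == 0) return(signal)
  n <- ncol(signal)
  t <- (seq_len(n) - 1) / fs
  if (is.null(weights)) {
    weights <- matrix(1, nrow = nrow(signal), ncol = nrow(lines))
  }
  if (is.null(phases)) {
    phases <- matrix(stats::runif(nrow(signal) * nrow(lines), 0, 2 * pi),
                     nrow = nrow(signal))
  }
  for (li in seq_len(nrow(lines))) {
    a <- lines$amp_rms[li] * sqrt(2)
    wave <- outer(phases[, li], 2 * pi * lines$freq[li] * t,
                  function(p, wt) sin(wt + p))
    signal <- signal + (a * weights[, li]) * wave
  }
  signal
}

# occipital-to-frontal alpha weight gradient over the montage: strongest at
# the back of the head (y = -0.9), weakest frontally
alpha_channel_weights <- function(channels) {
  y <- standard_montage()$y[match(channels, standard_montage()$label)]
  w <- 0.1 + 0.9 * ((0.9 - y) / 1.8)^2
  names(w) <- channels
  w
}

# slow positive amplitude-modulation envelope (about 0.5 Hz bandwidth)
slow_envelope <- function(n, fs, depth = 0.25) {
  n_slow <- max(ceiling(n / fs * 2), 4)
  z <- stats::rnorm(n_slow)
  env <- stats::approx(seq(0, 1, length.out = n_slow), z,
                       xout = seq(0, 1, length.out = n))$y
  env <- env / stats::sd(env) * depth
  pmax(1 + env, 0.2)
}

# re-reference to the configured reference electrode if present (the
# reference channel becomes an explicit all-zero row)
apply_reference <- function(data, channels, reference) {
  idx <- match(reference, channels)
  if (!is.na(idx)) data <- sweep(data, 2, data[idx, ])
  data
}

# mains + (optionally) headset lines.  The heterogeneous per-channel
# weights AND the across-channel phase pattern are subject/setup-level
# coupling properties: they are drawn under subject_seed so that the
# paired VR and No-VR sessions of one subject share them.  (The phase
# pattern matters because common-average referencing cancels the
# across-channel mean of each line; with per-session phases that
# cancellation, and hence the post-CAR line amplitude, would differ
# between two otherwise identical sessions, breaking the null.)
inject_session_lines <- function(data, cfg, condition) {
  n_ch <- nrow(data)
  mains <- structure(list(
    name = "mains",
    lines = data.frame(freq = cfg$mains_freq, amp_rms = cfg$mains_amp,
                       n_harmonics = cfg$mains_harmonics,
                       harmonic_decay = cfg$mains_harmonic_decay)
  ), class = "artifact_profile")
  ml <- expand_profile_lines(mains, cfg$fs)
  hl <- expand_profile_lines(cfg$hmd_profile, cfg$fs)
  setup <- with_seed(cfg$subject_seed, list(
    w_mains = matrix(stats::runif(n_ch * nrow(ml), 0.8, 1.2), nrow = n_ch),
    p_mains = matrix(stats::runif(n_ch * nrow(ml), 0, 2 * pi),
                     nrow = n_ch),
    w_hmd = matrix(stats::runif(n_ch * max(nrow(hl), 1), 0.5, 1.5),
                   nrow = n_ch),
    p_hmd = matrix(stats::runif(n_ch * max(nrow(hl), 1), 0, 2 * pi),
                   nrow = n_ch)
  ))
  data <- inject_lines(data, mains, cfg$fs, weights = setup$w_mains,
                       phases = setup$p_mains)
  if (condition == "VR" && !is.null(cfg$hmd_profile) && nrow(hl)) {
    data <- inject_lines(data, cfg$hmd_profile, cfg$fs,
                         weights = setup$w_hmd, phases = setup$p_hmd)
  }
  data
}

# subject-level realized alpha frequency, shared across a session pair
subject_alpha_freq <- function(cfg) {
  with_seed(cfg$subject_seed,
            cfg$alpha_freq + stats::runif(1, -1, 1) * cfg$alpha_jitter)
}

#' Simulate an eyes-open / eyes-closed session
#'
#' Produces a continuous recording of `2 * n_trials_per_task` trials of
#' `trial_s` seconds in seeded pseudo-random eye-state order.  The alpha
#' component is a sinusoid at the (jittered) alpha frequency whose amplitude
#' switches between `alpha_gain_closed` and `alpha_gain_open` with the eye
#' state, modulated by a slow random envelope and weighted across channels
#' by an occipital-dominant gradient.  Mains lines are always present; the
#' headset profile is applied only when `condition = "VR"`.  The result is
#' referenced to the montage reference (Cz), stored as an all-zero channel.
#'
#' @param config A [generator_config()].
#' @param condition `"VR"` or `"No-VR"`.
#' @return An [eeg_recording()] with one event per trial onset, labelled
#'   `eyes_open` / `eyes_closed`.
#' @export
simulate_berger_session <- function(config, condition = c("No-VR", "VR")) {
  condition <- match.arg(condition)
  validate_generator_config(config)
  with_seed(config$seed, {
    cfg <- config
    n_trials <- 2L * cfg$n_trials_per_task
    duration <- n_trials * cfg$trial_s
    n <- round(duration * cfg$fs)
    n_ch <- length(cfg$channels)

    states <- sample(rep(c("eyes_open", "eyes_closed"),
                         each = cfg$n_trials_per_task))
    onsets <- (seq_len(n_trials) - 1) * cfg$trial_s

    data <- simulate_background(cfg, n_ch, duration)

    f_alpha <- subject_alpha_freq(cfg)
    gain_t <- rep(ifelse(states == "eyes_closed",
                         cfg$alpha_gain_closed, cfg$alpha_gain_open),
                  each = round(cfg$trial_s * cfg$fs))
    t <- (seq_len(n) - 1) / cfg$fs
    alpha <- gain_t * slow_envelope(n, cfg$fs) *
      sin(2 * pi * f_alpha * t + stats::runif(1, 0, 2 * pi))
    data <- data + alpha_channel_weights(cfg$channels) %o% alpha

    data <- inject_session_lines(data, cfg, condition)
    data <- apply_reference(data, cfg$channels, "Cz")

    events <- data.frame(onset_s = onsets, label = states,
                         stringsAsFactors = FALSE)
    eeg_recording(data, fs = cfg$fs, channels = cfg$channels,
                  events = events, reference = "Cz")
  })
}

#' Simulate a median-nerve stimulation session
#'
#' Produces `n_sessions * n_stim_per_session` stimulation events with
#' inter-stimulus intervals drawn uniformly from `isi_range` (responses of
#' neighbouring stimuli deliberately overlap when epochs are longer than
#' the ISI).  Each stimulus adds the configured Gaussian-windowed component
#' templates (N20, P37) and a brief stimulation-artifact spike at onset.
#' Background and line noise are generated as in
#' [simulate_berger_session()].
#'
#' @inheritParams simulate_berger_session
#' @return An [eeg_recording()] with one `stim` event per stimulation and a
#'   `session_boundary` event at the start of each session block.
#' @export
simulate_sep_session <- function(config, condition = c("No-VR", "VR")) {
  condition <- match.arg(condition)
  validate_generator_config(config)
  with_seed(config$seed, {
    cfg <- config
    sep <- cfg$sep
    n_stim <- sep$n_sessions * sep$n_stim_per_session
    lead_in <- 1
    session_gap <- 2

    onsets <- numeric(n_stim)
    bounds <- numeric(sep$n_sessions)
    t_cur <- lead_in
    i <- 0L
    for (s in seq_len(sep$n_sessions)) {
      bounds[s] <- t_cur - 0.5
      for (k in seq_len(sep$n_stim_per_session)) {
        i <- i + 1L
        onsets[i] <- t_cur
        t_cur <- t_cur + stats::runif(1, sep$isi_range[1], sep$isi_range[2])
      }
      t_cur <- t_cur + session_gap
    }
    duration <- ceiling(t_cur + 1)
    n <- round(duration * cfg$fs)
    n_ch <- length(cfg$channels)

    data <- simulate_background(cfg, n_ch, duration)

    # component templates, truncated at 4 sigma
    for (nm in names(sep$components)) {
      comp <- sep$components[[nm]]
      sigma <- comp$width_ms / 1000 / 2.355
      half <- ceiling(4 * sigma * cfg$fs)
      tt <- (-half:half) / cfg$fs
      shape <- comp$polarity * comp$amplitude *
        exp(-(tt - 0)^2 / (2 * sigma^2))
      w <- rep(sep$spill, n_ch)
      names(w) <- cfg$channels
      known <- intersect(names(comp$weights), cfg$channels)
      w[known] <- comp$weights[known]
      center <- round((onsets + comp$latency_ms / 1000) * cfg$fs) + 1L
      for (c0 in center) {
        idx <- (c0 - half):(c0 + half)
        ok <- idx >= 1 & idx <= n
        data[, idx[ok]] <- data[, idx[ok]] +
          w %o% shape[ok]
      }
    }

    if (sep$artifact_amplitude > 0) {
      sigma <- sep$artifact_width_ms / 1000 / 2.355
      half <- max(ceiling(4 * sigma * cfg$fs), 1L)
      shape <- sep$artifact_amplitude *
        exp(-((-half:half) / cfg$fs)^2 / (2 * sigma^2))
      center <- round(onsets * cfg$fs) + 1L
      for (c0 in center) {
        idx <- (c0 - half):(c0 + half)
        ok <- idx >= 1 & idx <= n
        data[, idx[ok]] <- data[, idx[ok]] + rep(1, n_ch) %o% shape[ok]
      }
    }

    data <- inject_session_lines(data, cfg, condition)
    data <- apply_reference(data, cfg$channels, "Cz")

    events <- rbind(
      data.frame(onset_s = onsets, label = "stim",
                 stringsAsFactors = FALSE),
      data.frame(onset_s = bounds, label = "session_boundary",
                 stringsAsFactors = FALSE)
    )
    events <- events[order(events$onset_s), ]
    rownames(events) <- NULL
    eeg_recording(data, fs = cfg$fs, channels = cfg$channels,
                  events = events, reference = "Cz")
  })
}
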