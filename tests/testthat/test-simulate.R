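# log-log spectral slope of a Welch-averaged periodogram, the independent
# oracle for the 1/f background shape
welch_slope <- function(x, fs, fmin = 5, fmax = 100, seg_s = 2) {
  seg <- round(seg_s * fs)
  n_seg <- floor(length(x) / seg)
  p <- 0
  for (k in seq_len(n_seg)) {
    xk <- x[((k - 1) * seg + 1):(k * seg)]
    p <- p + abs(stats::fft(xk))[seq_len(seg / 2 + 1)]^2
  }
  f <- (0:(seg / 2)) * fs / seg
  keep <- f >= fmin & f <= fmax
  unname(stats::coef(stats::lm(log(p[keep]) ~ log(f[keep])))[2])
}

test_that("background with gamma = 0 is spectrally flat", {
  cfg <- test_generator_config(background_exponent = 0, seed = NULL)
  set.seed(1)
  x <- simulate_background(cfg, 1, 120)
  expect_lt(abs(welch_slope(x[1, ], cfg$fs)), 0.1)
})

test_that("background with gamma = 1 has log-log slope -1 within 0.15", {
  cfg <- test_generator_config(seed = NULL)
  set.seed(2)
  x <- simulate_background(cfg, 2, 120)
  expect_equal(welch_slope(x[1, ], cfg$fs), -1, tolerance = 0.15)
  expect_equal(welch_slope(x[2, ], cfg$fs), -1, tolerance = 0.15)
  expect_equal(sd(x[1, ]), cfg$background_scale, tolerance = 1e-6)
  expect_equal(mean(x[1, ]), 0, tolerance = 1e-9)
})

test_that("zero background scale gives an all-zero signal", {
  cfg <- test_generator_config(background_scale = 0)
  expect_true(all(simulate_background(cfg, 3, 5) == 0))
  expect_error(generator_config(background_exponent = -1), "exponent")
})

test_that("an injected line carries its closed-form power", {
  fs <- 500
  zeros <- matrix(0, 1, fs * 10)
  prof <- structure(list(name = "x", lines = data.frame(
    freq = 50, amp_rms = 3, n_harmonics = 0, harmonic_decay = 0
  )), class = "artifact_profile")
  set.seed(3)
  x <- inject_lines(zeros, prof, fs)
  ep <- toy_epochs(x, fs = fs, tmin = 0, channels = "Cz")
  sp <- power_spectrum(ep)
  b50 <- which(sp$freqs == 50)
  # sinusoid with RMS a has one-sided bin power a^2
  expect_equal(as.numeric(sp$power[1, 1, b50]), 9, tolerance = 1e-9)
  expect_lt(max(sp$power[1, 1, -b50]), 1e-10)
  # identity for an empty profile
  expect_identical(inject_lines(zeros, artifact_profile("vive_like"), fs),
                   zeros)
  # aliased line errors
  bad <- structure(list(name = "bad", lines = data.frame(
    freq = 300, amp_rms = 1, n_harmonics = 0, harmonic_decay = 0
  )), class = "artifact_profile")
  expect_error(inject_lines(zeros, bad, fs), "Nyquist")
})

test_that("the oculus-like profile injects exactly its line set", {
  fs <- 500
  zeros <- matrix(0, 1, fs * 10)
  set.seed(4)
  x <- inject_lines(zeros, artifact_profile("oculus_like"), fs)
  sp <- power_spectrum(toy_epochs(x, fs = fs, tmin = 0, channels = "Cz"))
  found <- sp$freqs[sp$power[1, 1, ] > 1e-6]
  expected <- c(52, 104, 156, 90, 180, 125, 150, 220)
  expect_setequal(found, expected)
})

test_that("a Berger session has the configured trial structure", {
  cfg <- tiny_config(seed = 10)
  rec <- simulate_berger_session(cfg, "No-VR")
  expect_equal(nrow(rec$events), 2 * cfg$n_trials_per_task)
  expect_equal(sum(rec$events$label == "eyes_closed"),
               cfg$n_trials_per_task)
  expect_equal(ncol(rec$data) / rec$fs,
               2 * cfg$n_trials_per_task * cfg$trial_s)
  # the reference channel is explicitly zero
  expect_true(all(rec$data[rec$channels == "Cz", ] == 0))
})

test_that("sessions are byte-identical under a fixed seed", {
  cfg <- tiny_config(seed = 11)
  a <- simulate_berger_session(cfg, "VR")
  b <- simulate_berger_session(cfg, "VR")
  expect_identical(a, b)
  s1 <- simulate_sep_session(cfg, "No-VR")
  s2 <- simulate_sep_session(cfg, "No-VR")
  expect_identical(s1, s2)
})

test_that("equal eye-state gains give a flat relative spectrum", {
  cfg <- test_generator_config(seed = 12, n_trials_per_task = 8,
                               alpha_gain_closed = 3.0001,
                               alpha_gain_open = 3)
  rec <- common_average_reference(simulate_berger_session(cfg, "No-VR"))
  rel <- sliding_relative_spectrogram(epoch(rec, "eyes_closed", 0, 10),
                                      epoch(rec, "eyes_open", 0, 10))
  in_band <- rel$freqs >= 5 & rel$freqs <= 30
  med <- median(rel$ratio[, , in_band])
  expect_gt(med, 0.8)
  expect_lt(med, 1.25)
})

test_that("occipital relative alpha power exceeds frontal", {
  cfg <- test_generator_config(seed = 13)
  rec <- common_average_reference(simulate_berger_session(cfg, "No-VR"))
  rel <- sliding_relative_spectrogram(epoch(rec, "eyes_closed", 0, 10),
                                      epoch(rec, "eyes_open", 0, 10))
  al <- alpha_summary(rel)
  regions <- hmdeeg:::channel_regions(rel$channels)
  occ <- mean(al$topography[regions == "occipital"])
  fro <- mean(al$topography[regions == "frontal"])
  expect_gt(occ, fro)
})

test_that("no unconfigured narrowband peaks appear in a session spectrum", {
  cfg <- tiny_config(seed = 14, trial_s = 10, n_trials_per_task = 2)
  rec <- simulate_berger_session(cfg, "No-VR")
  sp <- power_spectrum(epoch(rec, c("eyes_open", "eyes_closed"), 0, 10))
  ms <- median_spectrum(sp)
  f <- sp$freqs
  o1 <- ms[which(rec$channels == "O1"), ]
  # local spectral median over +/- 2 Hz
  half <- round(2 / (f[2] - f[1]))
  configured <- c(cfg$alpha_freq, 50, 100, 150, 200)
  for (b in which(f >= 3 & f <= 245)) {
    if (min(abs(f[b] - configured)) < 2.5) next
    loc <- o1[max(1, b - half):min(length(f), b + half)]
    expect_lt(o1[b], 5 * median(loc))
  }
})

test_that("a SEP session has the configured stimulation count and timing", {
  cfg <- test_generator_config(seed = 15)
  rec <- simulate_sep_session(cfg, "No-VR")
  stim <- rec$events[rec$events$label == "stim", ]
  expect_equal(nrow(stim),
               cfg$sep$n_sessions * cfg$sep$n_stim_per_session)
  isi <- diff(stim$onset_s)
  isi <- isi[isi < 1]  # drop the session gaps
  expect_true(all(isi >= cfg$sep$isi_range[1] - 1e-9))
  expect_true(all(isi <= cfg$sep$isi_range[2] + 1e-9))
})

test_that("default SEP configuration yields 500 stimulations", {
  cfg <- test_generator_config(seed = 16, sep = sep_config())
  rec <- simulate_sep_session(cfg, "No-VR")
  expect_equal(sum(rec$events$label == "stim"), 500)
})

test_that("a noise-free stimulus puts the C6 minimum at the N20 latency", {
  cfg <- test_generator_config(
    seed = 17, background_scale = 0, mains_amp = 0,
    sep = sep_config(n_sessions = 1, n_stim_per_session = 5,
                     isi_range = c(0.4, 0.5), artifact_amplitude = 0)
  )
  rec <- simulate_sep_session(cfg, "No-VR")
  rec <- common_average_reference(rec)
  ep <- baseline_correct(epoch(rec, "stim", -0.05, 0.30))
  c6 <- ep$data[1, which(ep$channels == "C6"), ]
  t_ms <- (ep$tmin + (seq_along(c6) - 1) / ep$fs) * 1000
  expect_equal(t_ms[which.min(c6)], 20, tolerance = 1000 / cfg$fs)
})

test_that("disabling components leaves a near-zero median response", {
  cfg <- test_generator_config(
    seed = 18,
    sep = sep_config(n_sessions = 1, n_stim_per_session = 50,
                     components = list(), artifact_amplitude = 0)
  )
  # empty component list: bypass the latency validation loop naturally
  rec <- simulate_sep_session(cfg, "No-VR")
  rec <- common_average_reference(rec)
  ep <- baseline_correct(epoch(rec, "stim", -0.05, 0.30))
  wf <- median_sep_waveform(ep, "C6")
  post <- wf$median[wf$time_ms > 0]
  expect_lt(max(abs(post)), 2 * cfg$background_scale / sqrt(50) * 3)
})
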