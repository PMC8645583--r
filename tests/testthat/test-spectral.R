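test_that("a bin-frequency sinusoid carries a^2/2 at its bin", {
  fs <- 250
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  ep <- toy_epochs(matrix(2 * sin(2 * pi * 10 * t), nrow = 1),
                   fs = fs, tmin = 0, channels = "O1")
  sp <- power_spectrum(ep)
  b10 <- which(sp$freqs == 10)
  expect_equal(as.numeric(sp$power[1, 1, b10]), 2, tolerance = 1e-9)
  expect_lt(max(sp$power[1, 1, -b10]), 1e-10)
  z <- power_spectrum(toy_epochs(matrix(0, 1, 100), fs = fs, tmin = 0))
  expect_true(all(z$power == 0))
})

test_that("the frequency axis reaches Nyquist (2.5 kHz at 5 kHz)", {
  ep <- toy_epochs(matrix(rnorm(50000), nrow = 1), fs = 5000, tmin = 0)
  sp <- power_spectrum(ep)
  expect_equal(max(sp$freqs), 2500)
  expect_equal(sp$freqs[2] - sp$freqs[1], 0.1)
})

test_that("one-sided power satisfies Parseval's identity", {
  set.seed(40)
  for (n in c(200, 201)) {  # even and odd lengths
    x <- rnorm(n)
    sp <- power_spectrum(toy_epochs(matrix(x, nrow = 1), fs = 100,
                                    tmin = 0))
    expect_equal(sum(sp$power) * n, sum(x^2), tolerance = 1e-9)
  }
})

test_that("the across-trial median is robust to an outlier trial", {
  arr <- array(0, dim = c(3, 1, 4))
  arr[, 1, ] <- rbind(rep(1, 4), rep(2, 4), rep(100, 4))
  sp <- structure(list(freqs = 0:3, power = arr, channels = "Cz",
                       metadata = NULL), class = "eeg_spectra")
  expect_true(all(median_spectrum(sp) == 2))
  one <- sp
  one$power <- arr[1, , , drop = FALSE]
  expect_true(all(median_spectrum(one) == 1))
  ms <- median_spectrum(sp)
  expect_true(all(ms <= apply(arr, c(2, 3), max) &
                    ms >= apply(arr, c(2, 3), min)))
})

test_that("10-s trials give 31 sliding-window positions", {
  cfg <- test_generator_config(seed = 41, n_trials_per_task = 2)
  rec <- common_average_reference(simulate_berger_session(cfg, "No-VR"))
  rel <- sliding_relative_spectrogram(epoch(rec, "eyes_closed", 0, 10),
                                      epoch(rec, "eyes_open", 0, 10))
  expect_equal(length(rel$times), 31)
  expect_equal(rel$times[1], 1.25)
  expect_equal(rel$times[31], 8.75)
  expect_equal(rel$freqs[2] - rel$freqs[1], 0.4)
})

test_that("doubling the alpha amplitude quadruples the alpha-bin ratio", {
  fs <- 100
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  set.seed(43)
  floor_noise <- function() matrix(rnorm(3 * length(t), sd = 1e-4),
                                   nrow = 3)
  closed <- toy_epochs(matrix(rep(4 * sin(2 * pi * 10 * t), 3),
                              nrow = 3, byrow = TRUE) + floor_noise(),
                       fs = fs, tmin = 0, channels = "O1")
  open <- toy_epochs(matrix(rep(2 * sin(2 * pi * 10 * t), 3),
                            nrow = 3, byrow = TRUE) + floor_noise(),
                     fs = fs, tmin = 0, channels = "O1")
  rel <- sliding_relative_spectrogram(closed, open)
  b10 <- which(rel$freqs == 10)
  expect_equal(max(rel$ratio[, 1, b10]), 4, tolerance = 1e-3)
  # zero baseline errors out
  zero <- toy_epochs(matrix(0, 3, length(t)), fs = fs, tmin = 0,
                     channels = "O1")
  expect_error(sliding_relative_spectrogram(closed, zero), "degenerate")
})

test_that("the generator's alpha frequency is recovered within one bin", {
  for (f_alpha in c(8, 10, 12)) {
    cfg <- test_generator_config(seed = 42 + f_alpha, alpha_freq = f_alpha,
                                 alpha_jitter = 0, n_trials_per_task = 5)
    rec <- common_average_reference(simulate_berger_session(cfg, "No-VR"))
    rel <- sliding_relative_spectrogram(epoch(rec, "eyes_closed", 0, 10),
                                        epoch(rec, "eyes_open", 0, 10))
    al <- alpha_summary(rel)
    expect_equal(al$peak_freq, f_alpha, tolerance = 0.4 + 1e-9)
  }
})

test_that("a flat ratio warns and reports the range midpoint", {
  rel <- structure(list(
    times = 1, freqs = seq(0, 20, 0.4),
    ratio = array(1, dim = c(1, 1, 51)), channels = "O1"
  ), class = "relative_spectrogram")
  expect_warning(al <- alpha_summary(rel), "flat")
  expect_equal(al$peak_freq, 10.5)
  expect_true(all(abs(al$topography - 1) < 1e-12))
})

test_that("differential peaks are empty for identical inputs", {
  freqs <- seq(1, 100, 0.5)
  m <- matrix(1, nrow = 2, ncol = length(freqs))
  sig <- structure(list(
    channels = c("Cz", "O1"), freqs = freqs,
    p = matrix(1, 2, length(freqs)),
    statistic = matrix(0, 2, length(freqs)),
    reject = matrix(FALSE, 2, length(freqs)),
    q = 0.01, threshold = 0, n_vr = 5, n_novr = 5
  ), class = "significance_map")
  expect_equal(nrow(differential_peaks(m, m, sig)), 0)
})

test_that("peak grouping merges leakage-split bins and ranks by ratio", {
  freqs <- seq(1, 100, 1)
  nvr <- matrix(1, nrow = 1, ncol = length(freqs),
                dimnames = list("Cz", NULL))
  vr <- nvr
  vr[1, freqs %in% c(49, 50, 51)] <- c(3, 10, 3)   # one leaky peak
  vr[1, freqs == 90] <- 5
  rej <- matrix(FALSE, 1, length(freqs))
  rej[1, freqs %in% c(49, 50, 51, 90)] <- TRUE
  sig <- structure(list(
    channels = "Cz", freqs = freqs, p = 1 - rej, statistic = rej * 0,
    reject = rej, q = 0.01, threshold = 0.01, n_vr = 5, n_novr = 5
  ), class = "significance_map")
  pk <- differential_peaks(vr, nvr, sig)
  expect_equal(nrow(pk), 2)
  expect_equal(pk$freq, c(50, 90))       # sorted by ratio, descending
  expect_equal(pk$ratio, c(10, 5))
  expect_equal(pk$n_electrodes_significant, c(1, 1))
})
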