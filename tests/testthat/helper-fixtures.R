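# Small shared fixtures.  Everything is generated in code; sizes are kept
# minimal so each file's tests run in seconds.

tiny_config <- function(...) {
  test_generator_config(n_trials_per_task = 3, trial_s = 2, ...)
}

# a bare two-channel recording carrying an arbitrary signal
toy_recording <- function(x, fs = 100, channels = c("O1", "O2")) {
  data <- matrix(rep(x, each = length(channels)), nrow = length(channels))
  eeg_recording(data, fs = fs, channels = channels)
}

# epochs built directly from a trials x samples matrix on one channel
toy_epochs <- function(mat, fs = 500, tmin = -0.05, channels = "C6") {
  arr <- array(mat, dim = c(nrow(mat), 1, ncol(mat)),
               dimnames = list(NULL, channels, NULL))
  structure(
    list(data = arr, fs = fs, tmin = tmin,
         tmax = tmin + ncol(mat) / fs, channels = channels,
         metadata = data.frame(label = rep("stim", nrow(mat)),
                               onset_s = seq_len(nrow(mat)))),
    class = "eeg_epochs"
  )
}
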