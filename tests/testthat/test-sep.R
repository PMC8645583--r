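test_that("median waveform identities hold", {
  mat <- matrix(rep(sin(seq(0, 2 * pi, length.out = 175)), 4),
                nrow = 4, byrow = TRUE)
  ep <- toy_epochs(mat)
  wf <- median_sep_waveform(ep, "C6")
  expect_equal(wf$median, mat[1, ])
  expect_true(all(wf$se == 0))

  flip <- toy_epochs(rbind(mat[1, ], -mat[1, ]))
  expect_true(all(abs(median_sep_waveform(flip, "C6")$median) < 1e-12))
  expect_error(median_sep_waveform(ep, "POz"), "missing")
})

test_that("the simulated SEP waveform dips at N20 on C6", {
  cfg <- test_generator_config(seed = 60)
  rec <- simulate_sep_session(cfg, "No-VR")
  rec <- common_average_reference(
    highpass_zero_phase(exclude_channels(rec), cutoff = 0.1)
  )
  rec <- bandstop_zero_phase(rec)
  ep <- baseline_correct(epoch(rec, "stim", -0.05, 0.30))
  wf <- median_sep_waveform(ep, "C6")
  in_resp <- wf$time_ms > 5  # skip the stimulation artifact at t = 0
  tmin <- wf$time_ms[in_resp][which.min(wf$median[in_resp])]
  expect_gte(tmin, 15)
  expect_lte(tmin, 25)
})

test_that("components are extracted at template latencies", {
  # noise-free template: one Gaussian dip at 20 ms, one bump at 37 ms
  fs <- 500
  t_ms <- (-25:149) * 1000 / fs
  trace <- -8 * exp(-(t_ms - 20)^2 / (2 * 2.1^2)) +
    6 * exp(-(t_ms - 37)^2 / (2 * 4.2^2))
  ep <- toy_epochs(matrix(rep(trace, 3), nrow = 3, byrow = TRUE), fs = fs)
  tab <- extract_components(ep, "C6")
  n20 <- tab[tab$component == "N20", ]
  p37 <- tab[tab$component == "P37", ]
  expect_true(all(abs(n20$latency_ms - 20) <= 1000 / fs))
  expect_true(all(abs(p37$latency_ms - 36) <= 1000 / fs))
  expect_true(all(n20$amplitude < 0))
  expect_true(all(p37$amplitude > 0))
  expect_error(extract_components(ep, "C6",
                                  windows = list(N20 = c(400, 500))),
               "outside the epoch")
})

test_that("pure-noise latencies are uniform over the search window", {
  set.seed(61)
  ep <- toy_epochs(matrix(rnorm(400 * 175), nrow = 400))
  tab <- extract_components(ep, "C6")
  lat <- tab$latency_ms[tab$component == "P37"]
  # argmax of exchangeable noise is uniform over the window's sample grid
  grid <- seq(30, 44, by = 2)
  counts <- table(factor(lat, levels = grid))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("an all-zero epoch takes the tie-rule latency and amplitude 0", {
  ep <- toy_epochs(matrix(0, 2, 175))
  tab <- extract_components(ep, "C6")
  expect_true(all(tab$amplitude == 0))
  expect_equal(tab$latency_ms[tab$component == "N20"], c(16, 16))
  expect_equal(tab$latency_ms[tab$component == "P37"], c(30, 30))
})

test_that("IQR-based SNR matches the Gaussian closed form", {
  set.seed(62)
  rows <- data.frame(
    epoch = 1:10000, electrode = "C6", component = "N20",
    latency_ms = 20, amplitude = rnorm(10000, mean = 5, sd = 1),
    snr = NA_real_
  )
  out <- component_snr(rows)
  # median |amp| / IQR = 5 / 1.349 for N(5, 1)
  expect_equal(out$summary$median_snr, 5 / 1.349, tolerance = 0.015)
  # scale and sign invariance
  rows2 <- rows
  rows2$amplitude <- -2 * rows2$amplitude
  expect_equal(component_snr(rows2)$rows$snr, out$rows$snr,
               tolerance = 1e-12)
  # degenerate distribution errors
  rows3 <- rows[1:10, ]
  rows3$amplitude <- 1
  expect_error(component_snr(rows3), "degenerate")
})

test_that("median N20 latency is recovered within 2 ms over 200 epochs", {
  cfg <- test_generator_config(seed = 63)
  rec <- simulate_sep_session(cfg, "No-VR")
  rec <- common_average_reference(
    highpass_zero_phase(exclude_channels(rec), cutoff = 0.1)
  )
  rec <- bandstop_zero_phase(rec)
  ep <- baseline_correct(epoch(rec, "stim", -0.05, 0.30))
  tab <- extract_components(ep, "C6")
  lat <- tab$latency_ms[tab$component == "N20"]
  expect_gte(length(lat), 200)
  expect_lt(abs(median(lat) - 20), 2)
})

test_that("condition comparison rejects a shifted latency, not SNR", {
  set.seed(64)
  base <- function(n) {
    do.call(rbind, lapply(c("C6", "CP4"), function(el) {
      do.call(rbind, lapply(c("N20", "P37"), function(cp) {
        data.frame(epoch = 1:n, electrode = el, component = cp,
                   latency_ms = rnorm(n, 20, 2),
                   amplitude = rnorm(n, 5, 1), snr = NA_real_)
      }))
    }))
  }
  vr <- base(100)
  novr <- base(100)
  novr$amplitude <- novr$amplitude * 2   # scales out of the SNR
  vr$latency_ms <- vr$latency_ms + 5
  cmp <- compare_conditions(vr, novr, q = 0.001, n_boot = 500)
  expect_equal(nrow(cmp), 8)
  expect_true(all(cmp$rejected[cmp$measure == "latency"]))
  expect_false(any(cmp$rejected[cmp$measure == "snr"]))

  ident <- compare_conditions(vr, vr, q = 0.001, n_boot = 200)
  expect_true(all(ident$p == 1))
  expect_error(compare_conditions(vr[vr$component == "N20", ], novr),
               "missing")
})

test_that("same-distribution conditions stay null across replicates", {
  set.seed(65)
  rejections <- replicate(30, {
    make <- function() {
      do.call(rbind, lapply(c("C6", "CP4"), function(el) {
        do.call(rbind, lapply(c("N20", "P37"), function(cp) {
          data.frame(epoch = 1:60, electrode = el, component = cp,
                     latency_ms = rnorm(60, 20, 2),
                     amplitude = rnorm(60, 5, 1), snr = NA_real_)
        }))
      }))
    }
    any(compare_conditions(make(), make(), q = 0.001,
                           n_boot = 500)$rejected)
  })
  expect_lte(mean(rejections), 0.1)
})
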