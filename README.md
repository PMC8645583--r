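# hmdeeg

Benchmarking EEG signal quality during use of a virtual-reality
head-mounted display (HMD).

A headset worn over an EEG cap can couple electromagnetic interference
into the recording — most prominently narrowband spectral lines at the
mains frequency (50 Hz), at display refresh rates (90 Hz) and their
harmonics.  Whether a specific headset harms the frequency band a study
cares about should be established before any VR–EEG experiment.
`hmdeeg` implements a structured benchmark for that question, for
researchers running concurrent VR–EEG setups:

* **Frequency domain (Berger effect).**  Eyes-open vs. eyes-closed
  sessions; per-trial FFT power spectra `P_k = (2/N²)|X_k|²` (a sinusoid
  of amplitude *a* at a bin carries *a²/2* µV²); across-trial median
  spectra; time-resolved relative spectra (2.5-s windows, 250-ms steps,
  eyes-open median baseline); subject-specific alpha band (peak ±2 Hz in
  7–14 Hz) and its scalp topography.
* **Mass-univariate statistics.**  A Wilcoxon rank-sum test per
  (electrode, frequency-bin) cell on single-trial powers between the VR
  and No-VR conditions — midranks, tie-corrected normal approximation
  with continuity correction, exact enumeration for pooled n ≤ 12 —
  pooled into one Benjamini–Hochberg FDR family at q = 0.01, and a
  differential-peak extractor that reports each run of significant bins
  at its maximal VR/No-VR power-ratio bin.
* **Time domain (median-nerve SEPs).**  Per-epoch N20 (minimum in
  15–25 ms) and P37 (maximum in 30–45 ms) latency/amplitude at C6 and
  CP4; SNR = |amplitude| / IQR(amplitudes) per condition; condition
  comparisons (rank-sum for latency, a bootstrap-studentized test for
  the SNR functional) under BH-FDR at q = 0.001.
* **A synthetic session generator** (1/f background, eye-state-switched
  occipital alpha, mains + headset artifact line profiles, jittered
  stimulation trains with N20/P37 templates) so the entire pipeline is
  testable without any recorded data.  Built-in artifact profiles:
  `oculus_like` (lines at 52 and 90 Hz plus harmonics and strong lines
  above 100 Hz), `vive_like` (near-clean), `env_87`.

Recordings are exchanged as 16-bit EDF files plus a tab-separated event
table (`onset_s`, `label`).

## Worked example

Simulate a paired benchmark (an "Oculus-like" VR session against a clean
No-VR session, 19-channel/500 Hz preset with 50 trials per eye state)
and run everything:

```r
library(hmdeeg)

cfg <- run_config(
  out_dir = "report", seed = 2024,
  generator = test_generator_config(
    n_trials_per_task = 50,
    sep = sep_config(n_sessions = 2, n_stim_per_session = 100)
  ),
  vr_profile = "oculus_like"
)
res <- run_benchmark(cfg)

head(res$peaks, 5)
#>   freq      ratio n_electrodes_significant
#> 1  220 19815.3630                       19
#> 2  125  7575.8224                       19
#> 3   90  3001.5805                       19
#> 4  180  1474.9909                       19
#> 5   52   714.7319                       19
```

The differential-peak table recovers exactly the injected headset lines:
the 90 Hz refresh-rate artifact, the 52 Hz line and the high-amplitude
lines above 100 Hz, each significant on all 19 electrodes, ranked by
their VR/No-VR median-power ratio.  The shared 50 Hz mains line is — as
it should be — absent from the table.

The physiological benchmark is unaffected by the headset:

```r
vapply(res$alpha, function(a) a$peak_freq, 0)
#>   vr novr
#> 10.8 10.8
```

with an occipitally dominant relative-power topography (mean band ratio
3.78 occipital vs. 2.91 frontal in the No-VR run).  SEP latencies do not
differ between conditions (all latency tests non-significant); one SNR
cell (P37 at C6) is flagged, reflecting the genuinely increased
high-frequency noise floor of the simulated VR session:

```r
subset(res$sep_comparison, rejected)
#>   electrode component measure statistic            p rejected
#> 6        C6       P37     snr  1.179814 1.554015e-07     TRUE
```

All tables are also written as TSV files under `report/`, alongside a
JSON manifest of every parameter; reruns with the same seed are
byte-identical.

A command-line wrapper with `simulate`, `spectral-qa`, `sep-qa` and
`run-all` subcommands is installed at `inst/cli/hmdeeg`.

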