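---
title: "Benchmarking EEG signal quality under a VR head-mounted display"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking EEG signal quality under a VR head-mounted display}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A head-mounted display (HMD) sits millimetres away from an EEG cap.  Its
display drivers, cables and power electronics can couple electromagnetic
interference into the recording, and its weight and straps press on
electrodes.  Whether a given headset harms EEG signal quality — and in
which frequency range — is an empirical question that should be answered
*before* running a VR-EEG study.  `hmdeeg` implements a structured,
two-branch benchmark for exactly that question, comparing paired sessions
recorded with ("VR") and without ("No-VR") a headset:

* a **frequency-domain branch** built on the Berger effect (alpha
  blockade): eyes-open vs. eyes-closed trials, full-trial FFT power
  spectra, time-resolved relative spectra, and a mass-univariate
  electrode-by-frequency comparison of the two conditions;
* a **time-domain branch** built on median-nerve somatosensory evoked
  potentials (SEPs): per-epoch N20 and P37 latency and amplitude at C6 and
  CP4, an interquartile-range based signal-to-noise ratio, and per-subject
  condition comparisons.

Because a benchmark without data is untestable, the package also contains
a first-class synthetic session generator that emulates the statistical
structure both branches probe.  Every pipeline stage is exercised against
it in the test suite.

## The simulator: what it emulates, and what it does not

`simulate_berger_session()` and `simulate_sep_session()` build sessions
from four ingredients:

1. **1/f background.**  White Gaussian noise is shaped in the frequency
   domain to an expected one-sided PSD proportional to `1/f^gamma`
   (default `gamma = 1`, flat below 1 Hz), then scaled to a per-channel
   RMS of `background_scale` (default 5 µV).  The inverse-FFT shaping
   method makes the target PSD exact, so the spectral slope is testable
   directly.
2. **Alpha rhythm.**  A sinusoid at the subject's alpha frequency
   (nominally 10 Hz with a uniform ±1 Hz per-subject draw), amplitude
   switched between `alpha_gain_closed` (8 µV) and `alpha_gain_open`
   (2 µV) with the cued eye state and modulated by a slow random
   envelope.  Channel weights fall off from occipital to frontal sites.
   An amplitude-switched sinusoid (rather than band-filtered noise) keeps
   the peak frequency exact, which the alpha-recovery tests rely on.
3. **Line interference.**  Mains at 50 Hz plus decaying harmonics,
   always; a headset profile only in VR sessions.  The built-in
   `oculus_like` profile injects lines at 52 and 90 Hz with harmonics and
   high-amplitude lines above 100 Hz; `vive_like` injects nothing;
   `env_87` models a stray environmental 87 Hz line.  Line amplitudes are
   chosen for reliable detectability — no published amplitudes exist for
   any headset, so they are not calibrated to a device.
4. **SEP trains.**  5 × 100 stimulations with inter-stimulus intervals
   drawn uniformly from 0.2–0.5 s (2–5 Hz), each adding Gaussian-windowed
   component templates — a negative N20 at 20 ms (5 ms FWHM) and a
   positive P37 at 37 ms (10 ms FWHM), concentrated at C6/CP4 — plus a
   brief high-amplitude stimulation artifact at onset.  Epochs are longer
   than the shortest ISI, so neighbouring responses overlap, as they do
   in real recordings.

Two seeds control the randomness.  `seed` fixes a *session*; `subject_seed`
fixes *subject- and setup-level* parameters that paired sessions of one
subject share: the realized alpha frequency and the per-channel weights
**and phases** of every interference line.  The phase pattern matters more
than it may appear: the common-average reference subtracts each line's
across-channel mean, so the post-CAR line amplitude at every electrode
depends on the phase pattern.  If phases were redrawn per session, two
sessions with *identical* settings would differ systematically at the
line bins and the null calibration of the statistics would be destroyed.
Treating coupling weights and phases as setup constants is both the
physically sensible choice and the one that makes "same settings" mean
"same distribution".

What the generator does **not** emulate: eye blinks and other ocular
artifacts, EMG, electrode drift and impedance fluctuations, the
anti-aliasing hardware filter, or any biophysically realistic topography
(channel weights are simple geometric gradients or seeded random draws).
Passing tests therefore show that the *pipeline* recovers the structure it
claims to recover; they do not certify behaviour under every real-world
artifact.

### Scale presets

The scientific conditions are 64 channels at 5,000 Hz with 50 trials per
eye state and 500 stimulations.  `generator_config()` defaults to exactly
that.  Analyses in the test suite and the acceptance script run on the
reduced preset `test_generator_config()` — 19 channels (including all
analysis electrodes Cz, O1/Oz/O2, C6, CP4), 500 Hz, 10 trials per eye
state, 2 × 100 stimulations — which preserves every structural property
(bin widths relative to trial length, Nyquist above all injected lines,
epoch counts per event) at a fraction of the memory and time.  Where a
statistical property needs the full trial count (the differential-peak
detection below), the preset is run with `n_trials_per_task = 50`.

## Preprocessing

Both branches share the same conditioning: a zero-phase (forward–
backward) third-order Butterworth high-pass at 0.1 Hz on the continuous
recording, channel exclusion (`Fz`, `F1`, `F2` unrecordable under the
headset; `M1`, `M2` chronically high-impedance), and a common-average
reference.  The SEP branch adds a zero-phase third-order 48–52 Hz
band-stop.  Forward–backward filtering uses odd-reflection padding with
steady-state initial conditions, so a constant input produces an exactly
settled (zero) output and the impulse response is time-symmetric.  Note
that a 0.1 Hz high-pass has a multi-second transient: amplitude fidelity
holds in the interior of long recordings (the filter is applied to the
continuous session, never to 10-s epochs).

The recording reference Cz is stored as an explicit all-zero channel.
How the original reference should enter the common average is genuinely
underdetermined; keeping it in the channel set makes CAR an exact
re-referencing operation, which is the interpretation adopted here.

Epochs are half-open windows `[tmin, tmax)` on a 0-based time axis;
boundary trials are dropped (and counted), never zero-padded.  SEP epochs
span [−50, +300) ms around stimulation onset.  Baseline correction
subtracts the per-trial, per-channel *median* over the first 40 ms of the
pre-stimulus span, i.e. [−50, −10) ms — the last 10 ms before onset are
deliberately excluded so stimulation-artifact ringing cannot leak into
the baseline.

## The frequency-domain branch

Power spectra are bare FFTs of the complete 10-s trial — rectangular
window, no tapering, no segment averaging — scaled so that a sinusoid of
amplitude *a* at a bin frequency carries *a²⁄2* µV² at its bin (and
`sum(P) * N = sum(x^2)`, the corresponding Parseval identity).  Spectral
leakage is accepted; condition spectra are summarized by the
across-trial median, which is robust to occasional high-power trials.

The relative (eyes-closed / eyes-open) spectrum slides a 2.5-s window in
250-ms steps over each closed trial (31 positions on a 10-s trial) and
divides bin-wise by the eyes-open baseline: the median over all open
trials × window positions.  A median (not mean) baseline was chosen for
consistency with the median-over-trials convention elsewhere.  The peak
alpha frequency is the argmax over 7–14 Hz of the time- and
occipital-averaged ratio — a search range wide enough for ±1 Hz subject
jitter without capturing theta or beta — and the subject's alpha band is
that peak ±2 Hz.

The VR vs. No-VR comparison runs a two-sided Wilcoxon rank-sum test per
(electrode, frequency-bin) cell on single-trial powers of one eye state,
with midranks for ties, a tie-corrected normal approximation with
continuity correction, and exact enumeration when the pooled sample size
is ≤ 12 (enumeration is cheap there and anchors the approximation in the
tests).  All electrode × bin p-values of one comparison form a single
Benjamini–Hochberg family at `q = 0.01`; pooling is the conservative
reading of a per-subject, per-eye-state analysis and matches a single
significance map per comparison.  Reported maps can union the two eye
states' rejection masks.

`differential_peaks()` turns a map into an artifact line list: contiguous
runs of bins significant on any electrode (runs separated by ≤ 2 bins are
merged, since leakage can split a line) are each reported at the bin
maximizing the electrode-median VR/No-VR power ratio.

## The time-domain branch

N20 is the trace minimum in a 15–25 ms window, P37 the maximum in
30–45 ms, measured **per epoch** (not on the median waveform), with ties
broken toward the earliest sample.  The search windows follow component
nomenclature conventions; they are configurable.  The per-epoch SNR
within one condition/electrode/component cell is the absolute amplitude
divided by the interquartile range of that cell's amplitudes
(linear-interpolation quantiles); for Gaussian amplitudes the median SNR
is `|mu| / (1.349 sigma)`, a closed form the tests check.  Summaries are
medians with a standard error of `1.2533 * sd / sqrt(n)` (the normal
approximation of a median's standard error — simple and adequate at the
epoch counts involved).

Latencies are compared between conditions with the rank-sum test.  The
SNR needs more care: because each condition's SNR shares an *estimated*
IQR divisor, IQR sampling error shifts an entire condition's SNR values
multiplicatively, and a rank-sum test on per-epoch SNRs rejects far above
its nominal level under the strict null — at any epoch count (measured:
over half of same-distribution pairs "significant" at the 0.001 level).
Epoch-permutation variants were measured and remain miscalibrated,
because relabeled groups under-disperse the divisor noise.  The SNR is
therefore treated as what it is — a group-level shape functional,
`median(|amp|) / IQR(amp)` — and its between-condition difference is
tested with a bootstrap-studentized z statistic, resampling each
condition independently (500 resamples by default).  This measured
calibrated under the null and is invariant to per-condition amplitude
scaling, so a pure gain difference between sessions is (correctly) not an
"SNR difference".  All 8 tests (2 electrodes × 2 components × 2
measures) form one BH family at `q = 0.001`.

## Orchestration and reproducibility

`run_benchmark()` chains the whole pipeline — simulate or load both task
pairs, preprocess, both branches — and writes plain TSV tables plus a
JSON manifest of every parameter; with a fixed seed the TSV outputs are
byte-identical across reruns.  Recordings travel as 16-bit EDF files with
a tab-separated sidecar event table (`onset_s`, `label`); events live in
the sidecar rather than EDF+ annotations to keep round trips bit-exact
and simple.  The EDF physical range is chosen symmetric and
data-covering, so the write–read round trip errs by at most one
quantization step and clipping is impossible by construction (an
explicit, too-narrow range is an error instead).

A thin command-line wrapper is installed under `inst/cli/hmdeeg` with
`simulate`, `spectral-qa`, `sep-qa` and `run-all` subcommands over these
same functions.

## Numerical choices and degenerate inputs

* Zero-valued baseline bins in the relative spectrum raise an error
  (possible only on degenerate synthetic input, e.g. an identically zero
  channel before re-referencing).
* A flat alpha search profile warns and reports the range midpoint.
* All-tied rank-sum samples give `p = 1` at the null-mean statistic.
* A zero IQR (noise-free amplitudes) is an explicit "degenerate
  amplitude distribution" error rather than an infinite SNR.
* Aliased artifact lines (at or above Nyquist) are configuration errors;
  harmonics falling above Nyquist are silently dropped when a profile is
  realized at a lower sampling rate.

## Known limitations

The simulator's fidelity gaps listed above bound what green tests mean
for real recordings.  The 10-trial preset cannot reach significance
through a 47,000-test BH family at `q = 0.01` (the smallest attainable
rank-sum p at 10 + 10 trials is too large), which is why
differential-peak analyses use the full 50-trial count.  The
anti-aliasing hardware filter of the reference acquisition chain is not
modelled; it is irrelevant below the Nyquist frequency of any preset
used here.  Artifact *correction* is intentionally out of scope — the
benchmark's purpose is to measure contamination, not to remove it.
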