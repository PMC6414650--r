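---
title: "Modeling frequency-specific optoacoustic stimulation of the auditory system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling frequency-specific optoacoustic stimulation of the auditory system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optopulse)
library(dplyr)
```

## The problem

Short laser pulses delivered to the tympanic membrane deposit energy that
converts into mechanical vibration (the optoacoustic effect), offering a
contact-free way to drive the middle ear. A single carrier of laser pulses,
however, vibrates the ear at the pulse rate, far above the main audible
range. The strategy modelled here borrows amplitude modulation from radio
engineering: a fixed laser pulse rate (LPR, 32 or 50 kHz — the carrier) is
amplitude-modulated by a raised sinusoid at the laser modulation rate
(LMR, 1–10 kHz — the target acoustic frequency). If the ear behaves as a
linear time-invariant (LTI) system, the umbo (the central point of the
tympanic membrane) should vibrate predominantly at the LMR, and the
auditory midbrain should respond at the tonotopic place corresponding to
the LMR.

`optopulse` implements this computation end to end:

1. **Stimulus synthesis** (`stimulus_params()`, `make_pulse_train()`):
   pulses on the carrier grid with envelope weights
   $\sin(2\pi\,\mathrm{LMR}\,t) + 1 \in [0, 2]$ and per-pulse energies
   anchored so the envelope maximum carries the stated peak power
   (energy/pulse = peak power / LPR; mW/kHz = µJ).
2. **Forward model** (`build_input_sequence()`, `convolve_model()`,
   `predict_spectrum()`): the model input is the envelope sampled at
   $\Delta t = 1/\mathrm{LPR}$; the predicted umbo displacement is its
   convolution with the displacement impulse response measured (or here,
   synthesised) for a single 50 µJ pulse,
   $y[n] = f[n] * h[n]$.
3. **Vibrometry pipeline** (`bandpass_vibration()`, `average_runs()`,
   `analyze_vibration()`): zero-phase 300–12000 Hz band-pass, averaging of
   at least 17 runs, velocity-to-displacement integration, single-sided
   amplitude spectra, extraction of the fundamental (f0), second harmonic
   (h2), carrier (LPR) and sideband (LPR ± LMR) peaks, and
   signal-to-noise quality control
   ($\mathrm{SNR} = 20\log_{10}(A_\mathrm{signal}/A_\mathrm{noise})$,
   measurements with f0-SNR below 6 dB discarded).
4. **Synthetic neural stage** (`synth_tonotopy()`, `synth_trial()`,
   `detect_block()`): 16-channel extracellular recordings along a
   log-spaced tonotopic gradient with inhomogeneous-Poisson multi-unit
   spiking, and the analysis chain — 300–3000 Hz filtering, 3.5-SD spike
   detection with negative-peak timestamps, PSTHs, driven spike rates
   (DSR = TSR − SSR), frequency response maps (FRM), best frequency (BF)
   at 10 dB above threshold, the LMR↔BF correlation, and acoustic
   equivalent-level estimation.

## The synthetic umbo impulse response

No measured umbo response ships with the package, so
`synth_impulse_response()` provides a phenomenological stand-in: a sum of
damped harmonic modes. Each mode contributes the *velocity of a damped
sinusoidal displacement*,
$$v_i(t) = g_i\,e^{-a_i t}\left(\cos\omega_{d,i}t -
\frac{a_i}{\omega_{d,i}}\sin\omega_{d,i}t\right),\qquad
a_i = 2\pi f_i \zeta_i,\ \omega_{d,i} = 2\pi f_i\sqrt{1-\zeta_i^2},$$
whose integral — the mode displacement — is a damped sinusoid returning to
zero. That constraint matters: a bare damped-sine velocity has nonzero net
integral, i.e. a transiently struck eardrum that stays permanently
deflected. The resulting step in the displacement impulse response floods
the model spectrum with onset-transient energy near the lowest mode and
misplaces the fundamental at high modulation rates; the zero-net-displacement
form restores the behaviour a physical middle ear shows.

The default mode table (1.2, 3.5, 8 kHz dominant modes plus a broad,
heavily damped 41 kHz shoulder; damping ratios 0.05–0.30; gains scaled to
nanometre-range displacements) was chosen once to give a broadband
response: audible-range modes so every tested LMR is transduced, and
enough carrier-band response that the measured spectra resolve the
LPR ± LMR sidebands above the measurement noise floor, as real umbo
spectra do. These values are package conventions, not measured claims.

Two numerical choices in the model route:

* `predict_spectrum()` evaluates the **steady-state segment** of the
  convolution — from the end of the impulse response (25 ms) to the end of
  the input (100 ms). Over this 75 ms window every tested LMR, LPR and
  sideband frequency is an exact multiple of the 13.33 Hz bin width, and
  onset-transient leakage is excluded. The full record is available with
  `steady_state = FALSE`.
* The fundamental is *found, not assumed*: the lowest-frequency local
  maximum (≥ 100 Hz) reaching at least half the global spectral maximum.
  The tests then verify it coincides with the LMR bin.

```{r model-route}
ir <- velocity_to_displacement(synth_impulse_response())
params <- stimulus_params(lpr = 50, lmr = 8, peak_power = 200)
spec <- predict_spectrum(convolve_model(build_input_sequence(params), ir))
attr(spec, "f0_hz")
```

## The vibrometry measurement generator

`synth_vibration_runs()` emulates what a laser Doppler vibrometer would
record: the pulse train convolved with the *velocity* impulse response, a
weak second harmonic at −20 dB relative to the fundamental (`h2_ratio =
0.1`, emulating the mild nonlinearity measured spectra show — the LTI
model itself produces none), and independent white Gaussian velocity noise
per run, with matched no-stimulus runs for the SNR reference. The noise SD
default (2·10⁻³ m/s per raw run) was calibrated once so that, after
17-run averaging, the worst LPR/LMR combination lands near the upper end
of the 20-dB f0-SNR range typical of umbo vibrometry; the −20 dB harmonic
keeps the f0-vs-h2 SNR margin comfortably above the 7 dB the study design
requires.

Two estimator details proved necessary:

* **Hann taper by default** in `analyze_vibration()`. The band-pass
  attenuates the carrier region by ~100 dB while the fundamental passes
  unattenuated; with a rectangular window the onset-transient leakage
  skirt of the fundamental (a spectral-estimation artifact, not filtered
  content) exceeds the attenuated carrier lines. The Hann sidelobes fall
  fast enough that the sidebands re-emerge; amplitudes are corrected for
  the window's coherent gain. SNRs are unaffected because signal and noise
  records pass through the identical pipeline.
* **Noise-floor averaging** in `extract_peaks()`: the noise reference at a
  peak is the mean noise amplitude over ±3 bins. A single noise bin is
  Rayleigh-distributed with ~5.6 dB log-amplitude SD, which would make any
  fixed SNR margin a coin flip; averaging seven bins stabilises it while
  leaving the SNR definition (20·log₁₀ amplitude ratio at the same
  frequency) unchanged.

```{r measured-route}
session <- synth_vibration_runs(params, ir, seed = 1)
glance(analyze_vibration(session))
```

## The neural generator and what it does (and does not) emulate

`synth_tonotopy()` places 16 best frequencies log-spaced over 1–22 kHz
(the low-frequency electrode position; 2–32 kHz for the high-frequency
position), with Gaussian tuning of 0.3 octave SD on the log₂ axis and a
20 dB SPL acoustic threshold. `response_model()` sets multi-unit
spontaneous rate 40 spikes/s, driven-rate growth 3 spikes/s per dB above
threshold saturating at a 100 spikes/s increment, 5 ms onset latency, and
a linear optical gain anchoring 80 mW to a 41 dB SPL acoustic equivalent —
the midpoint of the 34.6–47.8 dB SPL range the in-vivo comparison
reports. Traces are sampled at 25 kHz (ample for the 300–3000 Hz spike
band): Gaussian background noise of 10 µV SD plus a 0.8 ms
negative-leading biphasic template at 6 noise-SD amplitude, inserted at
Poisson times with a 1 ms refractory period (greedy thinning — a renewal
process with dead time, so the realised rate is $r/(1 + r\tau)$, the
oracle the tests use). Templates at record edges are clipped rather than
dropped, keeping the spike rate unbiased in every analysis window. Every
inserted spike's negative-peak time is retained as ground truth, so the
detector can be scored for precision and recall.

The generator reproduces the *statistical structure the analysis chain
assumes* — tonotopy, rate-level growth, Poisson variability, realistic
template SNR — and deliberately not: spike-waveform diversity or sorting
ambiguity, bursting or adaptation, correlated network noise, electrode
drift, or any cochlear mechanics. Passing tests therefore certify the
analysis chain and its statistical calibration, not performance on animal
recordings.

Analysis choices worth flagging:

* **Detection polarity**: threshold crossings are negative-going at 3.5
  background SDs (estimated robustly by MAD, pooled across a block's
  pre-trigger segments), with the timestamp at the negative extremum and a
  1 ms merge window. Negative-going triggering is the convention for
  extracellular multi-unit thresholding; a two-sided trigger would double
  the false-positive rate (~8/s vs ~4/s in this band, by the Rice
  crossing-rate formula) and drag detection precision below the 0.9 the
  study design demands at this template SNR.
* **Spontaneous rate estimation**: `block_rates()` pools the pre-trigger
  window with the late 150–250 ms post-stimulus window, and
  `measure_frm()` pools further across the whole session, since the
  spontaneous rate is a property of the recording site. Estimating it per
  12-trial cell leaves ±5 spikes/s of shared noise in every DSR of that
  cell — enough to corrupt threshold estimates occasionally.
* **Threshold surrogate**: the visually determined threshold is automated
  as the lowest level whose maximal normalised DSR reaches 0.25, *required
  to persist at the next level* (`confirm = TRUE`) — the automated
  analogue of a rater ignoring a single noisy map cell. BF is then the
  argmax over frequency at 10 dB above that threshold, with a
  deterministic geometric-mean tie rule.
* The acoustic FRM protocol uses 12 runs per frequency–level cell (the
  in-vivo minimum is 7); the extra runs stabilise per-cell DSR means.
* Equivalent-level estimation interpolates linearly in dB on the
  increasing region of the acoustic rate-level curve, and discards
  sessions whose most-activated channel at maximal acoustic level differs
  from the threshold-level channel by more than one channel.

## Problem sizes and reproducibility

The package-default study sizes are the ones its tests and the acceptance
script run: 10 LPR × LMR combinations with 17 vibration runs each; 4
synthetic subjects × 5 modulation rates × 100 optical trials with a
28-frequency × 9-level × 12-run acoustic map per subject; and 20
equivalent-level sessions. All randomness flows from explicit seeds
through `derive_seed()`, so every trial, block and subject is
reproducible in isolation.

## Known limitations

* The impulse response is phenomenological; absolute displacement and SNR
  magnitudes are conventions, and only structural claims (peak locations,
  SNR orderings, recovery of generator parameters) are tested.
* The LTI model predicts no harmonic distortion by construction; the
  measured-route h2 is injected by the generator at a fixed ratio.
* The spike detector is multi-unit threshold crossing; no spike sorting.
* Acoustic stimulation is represented only through its effect on firing
  rates; there is no cochlear or middle-ear acoustic transfer model.
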