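---
title: "Monitoring sleep breathing states from breathing-sound audio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring sleep breathing states from breathing-sound audio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melbreath)
```

## The problem

During sleep, breathing disorders show up in a nose-level sound recording in
two complementary ways. Timing: apnea is a breathing stop longer than 10 s,
and a typical hypopnea shows as a 6–10 s stop. Spectrum: quiet normal
breathing concentrates its energy in a mid band around 500–1500 Hz, snoring
adds a loud harmonic component below 500 Hz, and obstructed ("abnormal")
breathing adds energy both below 500 Hz and high in the spectrum, well above
the normal band. `melbreath` turns a whole night of single-channel audio
into per-cycle state labels (normal/abnormal, with a snore flag),
apnea/hypopnea event calls, and the night-level quality ratio
`R_Sleep = T_Normal / T_Monitoring` — all with deterministic signal
processing, so the whole night can be processed in about real-time/20 on a
single core.

## The model and its assumptions

**Signal model.** The recorded signal is `y(t) = r(t) + n(t)`: breathing
sound plus stationary background noise, with bursts (inspiration plus
expiration, about 2.5 s together) separated by quieter gaps, a full cycle
lasting about 4 s. The noise is assumed broadband and much weaker than the
breath bursts (the generator default is 20 dB band SNR).

**Moment waveforms.** The time characteristic waveform (TCW) is the sliding
variance of `y` over a `±δ` window; with `δ = 0.1` s (about a tenth of a
phase) it tracks breath energy while flattening the sub-100 ms structure.
The characteristic moment waveform (CMW) weighs the TCW by the squared time
distance over a `±l` window. With `l` about half a cycle (default 2 s,
sensible range 1.5–3 s), the CMW is low at a burst centre — the weight
suppresses nearby energy — and high between bursts, where both neighbours
sit at large `|τ − t|`. Cycle boundaries are therefore CMW maxima, adjusted
to the quietest TCW point between adjacent burst peaks. Both waveforms are
computed exactly with running sums (O(N)); edge windows are truncated rather
than padded, and the first/last `l` seconds are accordingly less reliable.

**Per-cycle spectral labels.** Frames of 1024 samples (≈93 ms at the
11.025 kHz analysis rate) with 50 % overlap give roughly 50 frames for a
2.5 s active phase. Per frame, a Yule–Walker AR(32) model supplies a smooth
power spectral density; a 20-filter triangular Mel bank (edges uniform on
the Mel scale, each filter peaking where the next begins) integrates it into
band energies; `log10` compresses them. The frame's Mel-scale label (MsL) is
the index of the strongest band, and the per-cycle counts `N_MsL` summarise
where the cycle's energy lives. Because an AR PSD scales with the square of
the input gain, every matrix entry shifts by `2·log10(g)` under gain `g` and
the argmax — hence everything downstream — is gain-invariant. That is why
amplitude equalization (`equalize_amplitude()`) is optional preprocessing,
off by default.

**Threshold rules.** Label sets `FL = {2}`, `FM = {4..7}`, `FH = {15..17}`
flag the snore, normal and abnormal components. A set fires when *any one*
of its labels occurs strictly more often than its threshold; thresholds are
fractions of a 50-frame reference phase — 40 % (>20 frames) for FM and FH,
20 % (>10 frames) for FL. A cycle is abnormal exactly when FH fires, and
snoring exactly when FL fires; FM is reported (a heavy-breathing indicator)
but does not decide the state, and no separate heavy-breathing subtype is
defined because no operational rule for one exists. Gaps between active
phases are classified by duration: >10 s apnea, 6–10 s (closed interval)
hypopnea.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `delta_s` | 0.1 s | TCW half-window; ~1/10 of a breathing phase |
| `l_s` | 2 s | CMW half-window; ~half a cycle (use 1.5–3 s) |
| `min_cycle_s` | 1.5 s | shortest plausible cycle; also the extrema separation |
| `active_frac` | 0.01 | peak-relative floor of the active-phase threshold |
| `alpha` | 0.2 | weak-cycle merge threshold (fraction of the reference peak amplitude) |
| `win_len`, `hop` | 1024, 512 | analysis frame and hop, samples |
| `order` | 32 | Yule–Walker AR order |
| `n_filters`, `f_low`, `f_high` | 20, 0, fs/2 | Mel bank geometry |
| `ref_frames` | 50 | reference active-phase frame count for the thresholds |
| `frac_FM/FH`, `frac_FL` | 0.4, 0.2 | threshold fractions (→ 20 and 10 frames) |

## Numerical and design choices

Genuinely open points were resolved as follows; each is a package design
choice, not something the underlying method prescribes.

* **Discretization.** The integrals are Riemann sums with `dt = 1/fs`.
  Correctness of the running-sum forms is pinned by brute-force double-loop
  oracles in the test suite (1e-9 relative agreement on random signals).
* **Extrema search.** Strict local extrema with a minimum separation of
  `min_cycle_s`, ranked by prominence. The search runs on a 10 ms decimated
  grid — breathing structure lives at the second scale — and active-phase
  edges are then refined at full resolution.
* **Burst-peak deduplication.** Two `T_max` peaks closer than one minimum
  cycle are the inspiration and expiration lobes of a single breath; only
  the stronger is kept, so a boundary can never be placed in the shallow
  dip between the lobes of one cycle.
* **Active-phase threshold.** `max(3 × background TCW, active_frac × segment
  peak)`, with the background estimated as the 10th percentile of the TCW.
  A purely peak-relative threshold truncates the faint lobe of a cycle whose
  other lobe is very loud (e.g. an obstruction component on expiration);
  the noise-referenced floor keeps such cycles intact. Segments whose peak
  is within 5× the background are noise and produce no cycle.
* **Pause-duration measurement.** Each active-phase edge is located where
  the TCW crosses 5 % of the local lobe peak — a level *relative to the
  nearest lobe*, so the crossing position does not depend on how loud the
  breath is. The remaining constant bias of the crossing (the TCW window
  smears edges by a fixed fraction of `delta_s`) is removed by
  `edge_correction = -0.12`, calibrated once on clean two-burst fixtures of
  both normal and abnormal flavour; the unit tests verify unbiasedness to
  within 0.05 s on fresh fixtures. This matters because the apnea/hypopnea
  boundary is a hard 10 s threshold.
* **Weak-cycle merging.** The reference level is the mean of per-cycle peak
  envelope amplitudes *restricted to peaks at least half the maximum*, so
  noise-only "cycles" segmented inside a long apnea cannot drag the
  reference down and save themselves.
* **AR estimation.** Biased autocovariance (divide by frame length), which
  guarantees a stable model; one-sided PSD normalization. MsL is an argmax,
  so PSD scaling conventions are immaterial downstream. All-zero frames have
  no AR model and are given a flat epsilon PSD with a warning.
* **Logs and ties.** Base-10 logarithm with a floor of 1e-12 on band
  energies; argmax ties break to the lowest label so results are
  deterministic.
* **Mel bank edges.** `f_low = 0`, `f_high = fs/2`: the full analysis band,
  so the 20 filters cover everything the 11.025 kHz rate can represent.
* **No cepstrum.** The analysis deliberately stops after the logarithm: the
  point is the relationship between frequency-energy occupancy and time, so
  the conventional DCT/cepstral step of MFCC processing is not implemented.
* **WAV input.** Lossless PCM WAV keeps tests bit-exact; convert compressed
  recordings externally. The reader is a minimal base-R RIFF parser (16-bit
  scaling `x/32768`, first channel of multi-channel files).
* **Downsampling.** Zero-phase Butterworth low-pass at 0.8 × the new Nyquist
  before decimation (the anti-alias filter is otherwise unspecified by the
  method).
* **Amplitude equalization.** "Contrast diminution" is realised as
  sliding-RMS gain normalization (2 s window, RMS floor 1e-4, silence left
  unamplified). No formula for this step is prescribed anywhere, so it is
  optional and off by default; the gain-invariance of MsL makes it
  unnecessary for the core pipeline.

## What the synthetic generator emulates — and what it does not

`gen_night()` builds nights from the assumptions above: breath bursts of
band-limited (500–1500 Hz, downward-tilted) noise under a two-lobe
inspiration/expiration envelope; a harmonic snore component (fundamental
50–120 Hz, formant-like envelope peaking near 170 Hz, >70 % of power below
500 Hz) on the inspiration lobe of snoring cycles; an obstruction component
(flat sub-500 Hz noise plus a high-band resonance centred near 3.4 kHz whose
power extends past 3500 Hz; >60 % of power outside 500–3500 Hz) on the
expiration lobe of abnormal cycles, which also carry a snore component with
probability 0.8 since obstructed breathing and snoring usually co-occur.
Apnea gaps are drawn uniformly from 10–25 s, hypopnea gaps from 6–10 s, and
the cycle preceding such a stop is made abnormal. White background noise
sits 20 dB below the breath-band RMS by default; timings jitter with a 10 %
coefficient of variation. A fixed seed reproduces the identical waveform
and truth table.

The generator is deliberately idealized. It does **not** emulate: body
movement and bedding artifacts, position-dependent level drift, room
reverberation, varying noise floors (TV, partner, traffic), microphone
detachment, irregular-breathing-rate episodes as a distinct labelled class,
or the person-to-person variability in snore pitch and breath spectra that
makes real label-set boundaries fuzzy. Passing the end-to-end tests
therefore shows that the pipeline recovers the states and events *implied by
its own signal model* at realistic SNR; it does not certify clinical
accuracy on real recordings, and no diagnostic claim is made.

## Problem sizes used in the checks

The distributed checks use ten synthetic nights of 100 cycles
(≈8.5 minutes of audio each) at the default configuration — enough cycles
for stable accuracy estimates while keeping a full run of the suite at a
few minutes on one core. Oracle comparisons for the moment waveforms run on
1 s random signals at 1 kHz, where the brute-force double loop is cheap.

## Known limitations

* The label sets FL/FM/FH and the 40 %/20 % thresholds are fixed defaults;
  individuals differ, and a practical deployment would tune the sets per
  user (both are plain arguments to `msl_sets()` / `threshold_config()`).
* Cycles shorter than `min_cycle_s` cannot be represented, and frames
  require at least `win_len` samples, so extremely short or faint breaths
  are absorbed into pauses.
* Pauses at the very start and end of a recording are not classified as
  events (a stop needs breathing on both sides).
* Severity indices (AHI), oximetry fusion and any clinical grading are out
  of scope.
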