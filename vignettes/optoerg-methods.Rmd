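---
title: "Dissecting mixed native and optogenetic retinal responses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting mixed native and optogenetic retinal responses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optoerg)
```

## The measurement problem

Optogenetic vision restoration expresses a light-gated channel (here the
red-shifted channelrhodopsin ReaChR, peak sensitivity near 590 nm) in
ON-bipolar cells. When the host retina still contains functional
photoreceptors, a bright flash drives two response systems at once: the
native photoreceptor → bipolar cascade and the directly gated opsin
current. On the corneal ERG the optogenetic pathway produces an early,
fast negative deflection — the a_o-wave, trough near 8 ms — that precedes
the photoreceptor a-wave (trough near 17 ms) because no phototransduction
cascade or synapse lies between photon and current. The same asynchrony
reappears cortically as an early flash-VEP deflection (N1_o, ~27 ms)
ahead of the native N1 (~55 ms). Superposition also works the other way:
the native b-wave is dampened and delayed in opsin-expressing retinas.

`optoerg` turns these observations into a deterministic measurement
pipeline — filtering, trial averaging, wave-marker placement under the
standard clinical conventions, oscillatory-potential (OP) spectra,
photometric classification — together with a parametric simulator that
generates cohorts with known ground truth, so that every stage of the
pipeline can be validated quantitatively without animal recordings.

## Signal model and filters

Traces are sampled at 2 kHz with a 20 ms pre-stimulus baseline; stimulus
onset defines t = 0.

**Band-pass.** Flash ERG uses 0.125–300 Hz, VEP 3–100 Hz, OP extraction
75–300 Hz. Each band is realized as high-pass and low-pass Butterworth
sections applied forward and backward (`signal::filtfilt`), so the filter
is zero-phase: implicit times are not biased by group delay, and a
symmetric pulse keeps its peak to within one sample. The section order is
4. This choice is driven by the OP band: the strongest out-of-band
contaminant there is 50 Hz mains, and a 4th-order section attenuates a
50 Hz tone to below 5% after the two passes while leaving 120 Hz wavelets
within 3% of their amplitude; a 2nd-order section would leave ~16% of the
mains.

**Edge handling.** Epochs are short (320 ms) relative to the 0.125 Hz
high-pass corner, so padding matters. Band-pass stages pad with the edge
value (constant continuation): the recording outside the epoch sits at
baseline, and constant padding models exactly that. Reflection-style
padding was rejected after measurement: it biases the sub-0.5 Hz content
of the epoch and systematically *inflates* pulse amplitudes by about 2%
through the 0.125 Hz stage. Padding length is 3 time constants of the
corner, capped at 4 s.

A subtlety worth knowing: any high-pass with a genuine 0.125 Hz cut
removes the near-DC part of a wave's spectrum — about 0.7% of a b-wave's
area — which reappears as a shallow, nearly constant undershoot across the
whole epoch. Because the undershoot is flat, measuring amplitudes *from
the baseline mean* (the clinical convention) cancels it almost exactly;
measuring from zero would not. This is implemented throughout.

**Mains handling.** The 50 Hz notch is a biquad (Q = 30, ~1.7 Hz wide)
applied zero-phase, and only to light-adapted VEP recordings — ERG traces
are never notched, since 50 Hz lies inside the ERG passband. On a short
epoch a windowed 50 Hz burst is spectrally wider than any narrow notch,
so the notch alone cannot null it; the primary defense is trial averaging
with intertrial intervals that are not multiples of the 20 ms mains
period. At the standard 987 ms interval, 20 trials spread the mains phase
through exactly 19.74 cycles, and the phasor sum cancels essentially
completely (the residual is below 1% in the property tests). The narrow
notch then removes what little steady interference remains, at negligible
waveform distortion — a wide notch (low Q) would visibly ring the narrow
VEP components and displace their troughs.

## Marker placement

Each component is the earliest extremum of the appropriate sign inside a
fixed half-open window: a_o (0.5, 12] ms, a (12, 30], b (20, 120], N1_o
(15, 40], P1 (30, 50], N1 (40, 90] (all configurable). The windows
bracket the reported medians for this preparation with margin. Two
refinements make the extremum rule robust:

- **Edge exclusion.** An extremum on the first or last sample of a window
  is the slope of a neighbouring wave passing through, not a component
  peak (e.g. the dark-adapted a-wave rise crossing the a_o window), and
  does not count as present.
- **Presence gate.** A marker is present when its amplitude exceeds
  3× the pre-stimulus SD of the averaged, filtered trace *and* an
  absolute floor of 2 µV. The floor is required for noise-free synthetic
  traces, where the SD is numerically zero and any sub-microvolt ripple
  would otherwise be declared a component. N1_o — often just above noise
  in real recordings — is accepted from 2× SD with `confidence = "low"`
  below 3× SD.

Amplitude conventions: a and a_o from the baseline mean; dark-adapted b
from the a-trough level (falling back to baseline when no a-wave is
detectable); light-adapted b from baseline (the true a-wave level is
unreliable when optogenetic oscillations superimpose it); VEP N1 from the
preceding P1 peak; N1_o from baseline. All amplitudes are reported as
positive magnitudes with their reference recorded. When a_o is present
the a-wave is still measured but flagged low-confidence rather than
suppressed — the post-a_o oscillations make its amplitude physically
unrecoverable, and downstream code can decide what to do with it.

## Oscillatory potentials

OPs are extracted at 75–300 Hz over 20–230 ms post-stimulus and analyzed
with a plain (rectangular-window) DFT. The power at frequency f is
|X(f)|²/N with N the unpadded window length; the signal is zero-padded to
1 s so the argmax is read off a ~1 Hz grid (the native 210 ms window only
resolves ~4.8 Hz, too coarse to compare principal frequencies). The
normalization is one fixed choice among several defensible ones; the
comparison of interest (between genotypes, at matched windows) is
ratio-based and insensitive to it. Spectral leakage from the rectangular
window is accepted and documented; a taper would trade leakage against
the effective window length on an already short segment.

## Photometry

Full-field flash energy converts to retinal photon flux through a single
linear constant anchored at the equivalence 68 cd·s/m² = 8×10¹⁴
photons·cm⁻²·s⁻¹ — the threshold flux at which ReaChR measurably alters
spiking in this preparation. The threshold comparison is inclusive: the
anchor energy itself classifies as activating. Steady backgrounds are
placed on the same scale by integrating over 1 s, and a background is
called pre-activating above 10¹⁶ photons·cm⁻²·s⁻¹ (the amber
3,500 cd/m² background of the blue-on-amber paradigm qualifies; the
standard 30 cd/m² background does not). Spectral selectivity is reduced
to per-primary scalar weights (red 1.0, green 0.8, blue 0.2, white 1.0,
amber 0.9 — amber being the red+green mixture); no full action-spectrum,
pupil or eye-geometry model is attempted, because every decision the
pipeline makes from these numbers is a threshold comparison spanning
orders of magnitude.

## The simulator

Components are deliberately simple parametric shapes: two-sided Gaussian
pulses (independent rise/decay widths) for a, b, a_o, P1, N1, N1_o and
the slow positive deflection of the degenerate retina, and exponentially
damped sinusoids for OP bursts and the oscillations that follow a_o.
The a_o pulse is cut at t = 0, so its first post-stimulus sample is
already far from baseline — the "instantaneous" onset of a directly gated
current. Waveform-defining defaults are anchored at published group
medians for this mouse model:

| quantity | value | where |
|---|---|---|
| a_o trough / amplitude | 8.0 ms, −33.76 µV (nondegenerate), −6.36 µV (degenerate) | 100 cd·s/m², light-adapted |
| a-wave trough | 17.4 ms (−15 µV at 100 cd·s/m²) | light-adapted |
| b-wave peak / amplitude | 51.62 ms, 61.92 µV at 10 cd·s/m² | light-adapted, wild type |
| b dampening | ×0.556 (standard), ×0.538 (pre-activating amber background) | opsin-expressing |
| b delay | +16.13 ms (= 67.75 − 51.62) for activating flashes | opsin-expressing |
| amber-paradigm b | 107.86 µV (wild type) at 5 cd·s/m² blue | blue-on-amber |
| VEP N1 / N1_o | 55.25 ms / 27.12 ms | light-adapted, 100 cd·s/m² |
| dark b / a | 35.75 ms, 300 µV; 16 ms, −150 µV at 3 cd·s/m² | dark-adapted |

Quantities never reported for this preparation were fixed once at
physiologically ordinary values and exposed in the template: P1 at 40 ms
(+10 µV), N1 −15 µV, N1_o −6 µV (−4 µV degenerate), OP bursts at 110 Hz
(τ = 8 ms, onset 25 ms, 3 µV at the 100 cd·s/m² reference), the post-a_o
oscillation at 140 Hz (τ = 8 ms, onset 11 ms, 10 µV), and the degenerate
retina's slow positive deflection (6 µV, peak 70 ms). Two of these were
placed with the *pipeline* in mind rather than tuned freely: the post-a_o
oscillation starts just after the a_o trough so that its zero-phase
filter precursor cannot contaminate the trough, and the OP burst decays
fast enough that its ripple does not displace the much flatter b-peak by
more than a sample. Pulse widths were likewise chosen so that, after the
mandated filters, each marker recovers its generating value (see below).

Intensity–response follows a saturating Hill curve per component,
anchored at each component's reference energy; optogenetic components are
additionally hard-gated by the photometric activation threshold, so a_o
and N1_o appear from 68 cd·s/m² (white) upward and never below.

Noise model: per-sweep white noise (default SD 3 µV), a 50 Hz mains
sinusoid (default 2 µV) whose per-trial phase follows the protocol's
intertrial spacing, lognormal between-animal amplitude multipliers
(median 1, CV 0.2) and normal peak-time jitter. The time jitter is
parametrized separately (default SD 1 ms) rather than derived from the
amplitude CV: implicit-time variability in anesthetized mice is on the
order of a millisecond or two and does not scale with the mean — a 20%
multiplicative jitter on a 50 ms peak would imply a ±10 ms spread that no
intact preparation shows.

**What the simulator does *not* emulate** — and hence what passing tests
do not certify about real data: electrode drift and movement artifacts,
blink/breathing rhythms, inter-stimulus adaptation carry-over, genuine
waveform-shape variability between animals (only scale and timing vary),
photoreceptor recovery dynamics, and any nonlinear interaction between
the native and optogenetic pathways beyond the fixed dampening/delay of
the b-wave. Recovery results on synthetic cohorts validate the
*measurement machinery*, not biological claims.

## Numerical choices and degenerate inputs

- Plateau ties resolve to the earliest sample (implicit time is
  time-to-peak; earliest attainment is conservative).
- Sampling quantizes implicit times to 0.5 ms at 2 kHz; all timing
  tolerances are stated with this in mind (±0.5 ms ≈ ±1 sample).
- Flat or empty windows, absent markers, and queries on them return
  explicit absent values (`present = FALSE`, `NA`), never exceptions;
  genuinely malformed inputs (unknown genotype or color, invalid band,
  traces shorter than a required window) raise errors.
- Malformed sweep files are skipped with a warning; a sample-rate
  mismatch across recordings is a hard error.
- Identical inputs, configuration and seed give identical outputs; the
  configuration hash is recorded on every analysis table.

## Validation design and problem sizes

The test suite checks every operation against an independent oracle where
one exists: window extrema against a brute-force scan, spectral power
against a directly coded DFT sum, the exact Wilcoxon path against
complete enumeration of rank assignments (combined n ≤ 12), summaries
against closed-form cases, filters against their analytic frequency
response, type-I error and family-wise error against simulation (1,000
replicates each). Template recovery is tested in two regimes: noise-free
(every marker within 0.5 ms / 1% of its generating value for ERG;
VEP amplitudes within 5–15%, since the narrow 3–100 Hz band irreducibly
attenuates pulses a few milliseconds wide — VEP *times* stay within one
sample) and stochastic (default noise, CV 0.2, group sizes 6/11/6, seeds
1–20, group medians within 25% / 2 ms). The stochastic check uses the
three protocol steps that carry the headline markers; the full
ten-step protocol runs in the cohort-level self test
(`reproduce_report()`).

## Known limitations

- The linear photometric constant is a single-anchor calibration; it is
  silent about scotopic/photopic luminous-efficiency differences, pupil
  dilation and preretinal losses. Stimuli near the activation threshold
  should be classified with that in mind.
- The b-wave dampening factors are fixed multipliers, not a mechanistic
  model of the underlying conductance interaction.
- The a-wave in opsin-expressing retinas at bright flashes is reported
  low-confidence by design; no attempt is made to unmix it from the
  superimposed oscillations.
- OP spectra of degenerate-retina recordings contain no structured
  in-band signal; their reported peak frequency is then noise-driven and
  only the (near-zero) power is meaningful.
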