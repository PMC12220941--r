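# optoerg

Quantitative analysis of electroretinogram (ERG) and flash visually evoked
potential (VEP) recordings from retinas that carry **both** native
photoreceptor responses and **optogenetic** responses — the situation created
when a channelrhodopsin such as ReaChR is expressed in ON-bipolar cells of a
retina that still has (some) functional rods and cones. The package is aimed
at visual electrophysiologists and preclinical optogenetic-therapy groups who
need to dissect how the two response systems superimpose and interact in
full-field recordings.

## What it measures

Optogenetic activation of ON-bipolar cells leaves a distinctive signature on
the flash ERG: an early, fast **negative** deflection (the *a_o-wave*,
trough near 8 ms) that precedes the photoreceptor-driven a-wave (trough near
17 ms) and appears only when the flash is bright enough to drive the opsin.
On the cortical side, an analogous early negative VEP deflection (*N1_o*,
near 27 ms) precedes the native N1 (near 55 ms). The package implements:

- **Preprocessing** — zero-phase Butterworth band-pass filtering
  (0.125–300 Hz for flash ERG, 3–100 Hz for VEP), a 50 Hz mains notch for
  light-adapted VEP, and plain trial averaging. Intertrial intervals that
  are not multiples of 20 ms make the averaging itself cancel mains
  interference.
- **Wave markers** — deterministic detection of a, a_o, b, P1, N1 and N1_o
  with the standard clinical measurement conventions: a-wave from baseline;
  dark-adapted b-wave from the a-wave trough
  (`b = V(t_b) − V(t_a)`); light-adapted b-wave from baseline; VEP N1 from
  the preceding P1 peak. Presence is gated at 3× the pre-stimulus noise SD,
  and a-waves superimposed by post-a_o oscillations are flagged
  low-confidence.
- **Oscillatory potentials** — 75–300 Hz extraction over the 20–230 ms
  window and a plain DFT; reported are the principal frequency and the
  spectral power `|X(f)|²/N` at that frequency.
- **Photometry** — linear conversion between flash energy E (cd·s/m²) and
  retinal photon flux, anchored at 68 cd·s/m² = 8×10¹⁴ photons·cm⁻²·s⁻¹
  (the ReaChR activation threshold), with per-primary spectral weights and
  classification of stimuli as sub-threshold / ReaChR-activating and of
  backgrounds as pre-activating.
- **Synthetic cohorts** — a waveform simulator whose genotype templates
  (wild type, ReaChR-expressing, retina-degenerate + ReaChR) are anchored at
  published group medians for this mouse model: a_o 33.76 µV (nondegenerate)
  vs 6.36 µV (degenerate) at 100 cd·s/m², b-wave dampening to 55.6%
  (53.8% under an amber pre-activating background), a +16.13 ms b-wave delay
  for opsin-activating flashes, N1 at 55.25 ms and N1_o at 27.12 ms.
  Components are two-sided Gaussians and damped sinusoids with Hill
  intensity–response scaling; white noise, 50 Hz mains with
  protocol-correct phases, and lognormal between-animal variability are
  added on top. Every cohort ships with its generating truth.
- **Statistics** — Tukey-hinge group summaries, Shapiro–Wilk-gated
  unpaired t / exact Wilcoxon rank-sum comparisons, Tukey HSD for >2
  groups, and the b-wave dampening ratio (100 × treated / control medians).

## Worked example

Simulate a ReaChR-expressing animal's light-adapted response to a
100 cd·s/m² flash on a 30 cd/m² background, then run the standard analysis:

```r
library(optoerg)

stim  <- stimulus_spec(100, background_luminance = 30, adaptation = "light")
ss    <- simulate_sweepset("WT_ReaChR", stim, seed = 42)   # 20 trials
trace <- bandpass(average_trials(ss), 0.125, 300)
place_erg_markers(trace)
#> <marker_set> (light conventions, baseline sd 0.57 uV)
#> # A tibble: 3 × 6
#>   name  present implicit_time_ms amplitude_uV reference confidence
#>   <chr> <lgl>              <dbl>        <dbl> <chr>     <chr>
#> 1 a_o   TRUE                 8           34.1 baseline  clear
#> 2 a     TRUE                16.5         19.0 baseline  low
#> 3 b     TRUE                67.5         74.8 baseline  clear

retinal_flux(100)
#> [1] 1.176471e+15   # photons/cm2/s -- above the 8e14 activation threshold
```

The a_o trough sits at 8 ms with an amplitude near the 33.76 µV template;
the a-wave is present but flagged `low` because the oscillations following
a_o superimpose it; the b-wave peaks at ~68 ms — delayed relative to the
~52 ms wild-type timing because the flash also drives the opsin.

An end-to-end self-check over a full three-genotype cohort (6/11/6 animals,
default noise) is available as:

```r
reproduce_report(seed = 1)
#> Recovery report (seed 1): 12/12 quantities within tolerance
```

A thin command-line front end over the same functions lives in
`inst/cli/optoerg.R` (`simulate-cohort`, `analyze`, `markers`,
`op-spectrum`, `photometry`, `reproduce`).

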