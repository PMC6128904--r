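---
title: "Simulating and analysing coexisting hippocampal theta rhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing coexisting hippocampal theta rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetawave)
```

## The scientific problem

Hippocampal theta is not one rhythm but two. Type 1 theta (roughly 7–12 Hz)
accompanies locomotion and exploration and is atropine-resistant; type 2
theta (roughly 4–9 Hz) is cholinergic, appears during arousal and
emotionally salient states such as exposure to predator odor, and can
coexist with type 1 theta as a second, slower spectral peak. Distinguishing
the two in a ventral-hippocampal LFP — and relating the slower rhythm to
interneuron activity, running speed, arena position, and theta-gamma
coupling — requires a specific chain of analyses: baseline-normalized Welch
spectra, sub-bin peak detection, entropy-based phase–amplitude coupling,
spike–field circular statistics, laminar current-source density,
speed-binned relative power, and an online band-power trigger. `thetawave`
implements that chain end to end, together with a synthetic session
generator that reproduces the statistical structure the analyses assume and
a biophysical single-cell model that reproduces the perisomatic origin of
dendritically driven theta.

Because no public recordings accompany this problem, the generator is a
first-class module: every downstream stage is validated against sessions
whose ground truth (oscillator frequencies, coupling depths, spike phase
locking, zone occupancy, stimulation epochs) is known exactly.

## The synthetic session generator

A session (`generate_session()`) is built from:

* **1/f background.** White Gaussian noise spectrally shaped to a power-law
  spectrum (`noise_exponent`, default α = 1), scaled to an RMS of
  `noise_amplitude` (default 0.3 mV). The default level is matched to the
  millivolt scale of ventral CA1 recordings and matters for coupling
  analyses: an unrealistically silent background makes every gamma sub-band
  equally modulated and de-localizes comodulograms.
* **Gated oscillators.** Each `oscillator_spec()` has an instantaneous
  frequency `base_freq + speed_slope * speed(t)`; phase is the cumulative
  integral of instantaneous frequency, so speed changes produce smooth
  frequency transitions without phase slips. Gates: `always`, `stim_on`
  (inside stimulation epochs), `zone_set` (inside named arena zones) and
  `immobility` (speed < 5 cm/s). A laminar profile (per-channel gain and
  phase) defaults to a phase reversal on SLM channels, mimicking the
  polarity flip across the pyramidal layer seen on linear probes.
* **Theta-modulated gamma.** A `pac_spec()` multiplies a carrier by the
  envelope `amplitude · (1 + depth · cos(φ_theta − φ_pref))/2`. The carrier
  is band-limited Gaussian noise (default 70 ± 10 Hz, i.e. the 60–80 Hz
  gamma band) rather than a sinusoid: amplitude-modulating a coherent
  sinusoid concentrates the modulation in two discrete sidebands, which is
  neither what cortical gamma looks like nor resolvable by 10-Hz-wide
  amplitude windows when the modulation rate (~7 Hz) exceeds half the
  window. A sub-band of a multiplicatively modulated noise process is
  equally modulated everywhere, so it is the unmodulated background that
  makes the comodulogram maximum coincide with the carrier band — another
  reason the background level above is part of the model, not a nuisance.
* **Spike trains.** Each `unit_spec()` is an inhomogeneous Poisson process
  whose rate is a von Mises function of the driving oscillator's phase. The
  concentration κ is chosen by inverting |R| = I₁(κ)/I₀(κ), so the target
  mean resultant vector length is the exact expectation of the generated
  phases; thinning against the rate maximum preserves this. Waveform
  templates are sums of two Gaussians with grid-aligned centers, so the
  generating half-width (FWHM of the principal lobe) and peak/trough ratio
  are recovered exactly by the feature extractor.
* **Trajectories.** `treadmill` runs on a circle at exactly the preset
  speed. `random_walk_in_arena` alternates bouts between zones: a bout
  picks the Wall zone with probability `wall_bias`, moves radially to the
  target annulus at that zone's speed, then circles within it for an
  exponentially distributed dwell (default mean 15 s, truncated to 2–60 s).
  Per-zone speeds default to ~7 cm/s at the Wall and ~25 cm/s in the
  Intermediate zone, the paces reported for those zones.

Everything is a deterministic function of the config seed.

What the generator does *not* emulate: electrode drift, optical artifacts,
volume conduction across channels (each channel is an independently scaled
copy plus independent noise), non-Poisson spike history (refractoriness,
bursting), and anesthesia states. Passing tests therefore demonstrate that
the analysis chain recovers known structure at realistic SNR — not that it
is robust to every artifact of real recordings.

## Spectral analysis

`compute_psd()` is a Welch estimator with 3 s Hamming windows, 2.5 s
overlap and per-segment constant detrending; the one-sided density
integrates to the signal variance (Parseval). `normalize_psd()` divides by
the baseline spectrum's integrated 0–14 Hz power — the convention used to
merge spectra across animals; a baseline normalized by itself integrates to
exactly 1. `detect_theta_peaks()` searches 4–12 Hz for local maxima
exceeding a 1/f trend (log–log fit over 2–20 Hz excluding the search band)
by a prominence factor (default 1.5), returns at most two, and refines each
frequency by quadratic interpolation of log power around the maximum bin —
necessary because a 3 s window quantizes frequency to 1/3 Hz while the
recovery checks work at ±0.2 Hz.

## Cross-frequency coupling

Filtering is zero-phase FIR (forward–backward, Hamming-designed), with the
filter order set to three cycles of the low cutoff — the convention of the
EEG filtering routine this mirrors. The one deliberate departure: amplitude
bands in `comodulogram()` and `mean_theta_gamma_mi()` use a fixed order of
three cycles of 20 Hz. The cycles-of-low-cutoff rule makes a 70 Hz filter
only ~40 taps long, whose stopband barely attenuates a strong theta
component; theta leakage then dominates the gamma envelope and fabricates
coupling. With the fixed order the whole theta range lies in the stopband
of every gamma filter.

The modulation index bins the amplitude envelope by the phase of the slow
band (18 bins of 20°), normalizes the bin means to a distribution and
reports the normalized KL divergence from uniform, in [0, 1]. Comodulograms
use 0.5 Hz phase windows at 0.25 Hz steps and 10 Hz amplitude windows at
2.5 Hz steps; the summary statistic uses 3–10 Hz phase and 30–80 Hz
amplitude. A phase-shuffling surrogate test (`mi_surrogate_test()`,
circular shifts ≥ 1 s, 200 surrogates) is provided for significance since
the analysis convention itself specifies none.

## Units and spike–field coupling

Spikes are detected on the 500–5000 Hz band at a threshold of
`threshold_sd` times the robust noise SD (median(|x|)/0.6745, insensitive
to the spikes themselves), with 1 ms lockout and ±0.8 ms waveform cuts.
Classification is by mean rate: below 10 spikes/s regular-spiking, above
interneuron. The boundary rate of exactly 10 goes to IN — the published
rule uses strict inequalities on both sides and leaves the boundary
undefined, so the package documents (and exposes) this convention.
Waveform half-width is the full width of the principal deflection at half
its extremal amplitude with interpolated crossings; the peak/trough ratio
is oriented so regular-spiking cells score far above 1. Spike–field
coupling assigns each spike the Hilbert phase of the 3–8 Hz filtered LFP
and reports |R| and the preferred phase; fewer than 10 spikes is an error,
not a number.

## Current-source density

The standard second spatial difference, `−(V_{i−1} − 2V_i + V_{i+1})/h²`,
positive plotted as source, edge channels dropped. Vaknin padding and
spatial smoothing exist as options but default off, since no variant is
canonical for this analysis. `band_csd_amplitude()` reports per-channel RMS
of the band-filtered CSD, which is how the pyramidal-layer-versus-SLM
source comparison is quantified.

## Speed–frequency analysis

Sessions are cut into 200 ms time bins (mean speed, majority zone); the
speed distribution is divided into 30 equal bins; each speed bin's member
LFP bins contribute zero-padded periodograms whose average is normalized to
relative power over 1–20 Hz (each row sums to 1). Per frequency, relative
power is regressed on speed-bin center weighted by bin occupancy, and
classified positive/negative at p < 0.001. The published description calls
its test a two-way ANOVA without specifying factors; the weighted
per-frequency regression with an F test is the implemented reading, and a
0.2 s rectangular bin intrinsically blurs frequency by ~5 Hz, which is why
classification bands, not exact edges, are the meaningful output.

## The closed-loop trigger

The controller reproduces an online detector: 30 s baseline, 6–8 Hz band,
1/8 s chunks, trigger when chunk band power strictly exceeds 2.5× the mean
baseline chunk power AND speed is strictly above (movement mode) or below
(immobility mode) 5 cm/s. A 0.125 s chunk has 8 Hz native resolution, so
the chunk periodogram is zero-padded to 1 s for the 6–8 Hz readout — the
chunk-level estimator is otherwise unspecified upstream, and the identical
estimator is used for baseline and online chunks so that scaling a
stationary signal by √k scales the ratio by exactly k (the switching-point
property the tests verify by bisection). The laser decision holds for one
chunk only; `replay()` runs the controller over a recorded session
deterministically and `validate_triggers()` scores it against ground-truth
intervals at chunk resolution.

## Arena zones and segment assignment

Zones are concentric annuli (defaults: Center to 8 cm, Intermediate to
16 cm, Extended Intermediate to 20 cm, Wall to the 25 cm wall — the
geometry is configurable since no dimensions are published); a point on a
boundary belongs to the inner zone. Zone timelines are debounced with a
0.2 s running median before counting crossings. LFP windows (3 s, 2.5 s
overlap) are labeled with the majority zone and mean speed; by default only
windows lying entirely within one zone are kept (`min_purity = 1`), because
a window spanning a bout transition mixes the spectra of two behavioral
states and, with speed-dependent theta, two frequencies. An optional
continuous-walking filter keeps windows fully inside bouts of ≥ 2 s at
≥ 5 cm/s, the movement normalization used for between-group comparisons.

## The biophysical model

`cell_model()` is a soma (20 × 20 µm) plus a 150 µm dendritic cable (10
segments, 2 µm diameter), Ra = 150 Ω·cm, Cm = 1 µF/cm². Channels are
canonical HH-style kinetics — transient Na and delayed rectifier
everywhere, A-type K and M-current at the soma, Ih at the soma and along
the dendrite — with every rate function in one editable list
(`default_kinetics()`); the reference cell model this parameterization
stands in for is published without equations, and the claims the simulation
supports are qualitative (stable rest, rebound, source localization), not
kinetically exact. Ih totals are 0.01 µS for the soma and 0.01 µS for the
dendrite; the dendritic total is spread uniformly along the cable, since
0.01 µS on a single 94 µm² segment would be an implausible ~0.01 S/cm²
density. Synapses are alpha functions (excitatory τ = 0.1 ms, 0 mV;
inhibitory τ = 0.3 ms, −75 mV; 0.05 µS). Untargeted distal inputs (OLM
inhibition, Schaffer/temporoammonic excitation) are distributed over the
distal third of the cable, as those axons arborize across the distal
dendritic domain; basket inhibition targets the soma.

Integration is backward Euler on the cable (Thomas tridiagonal solve) with
Rush–Larsen exponential gating updates, dt ≤ 0.025 ms; halving dt changes
peak responses by under 1%. Transmembrane currents are recovered from the
axial current balance, so they sum to zero across compartments at machine
precision and the extracellular point-source sum
`φ = (1/4πσ) Σ I_k / r_k` (σ = 0.3 S/m) is dipolar at a distance.

Rhythmic OLM drive defaults to a 5-event volley per theta cycle at 2 ms
spacing: OLM cells burst-fire within the cycle, and a single 0.3 ms alpha
conductance carries too little charge to hyperpolarize the dendrite
appreciably. The rebound measure (`rebound_amplitude()`) is the theta-band
(4–12 Hz) RMS of somatic Vm in the driven steady state, after an
input-free settling period; this isolates the rhythmic rebound from the
slow baseline shift that changing g_h itself causes (Ih contributes
standing depolarization, so resting potential moves with g_h, and a
peak-minus-rest measure confounds the two). Under OLM-only drive the
theta-band CSD of a simulated laminar grid is maximal at the perisomatic
electrode with a weaker distal source, and the rebound RMS increases
monotonically over g_h ∈ {0, 0.005, 0.01} µS.

## Problem sizes and numerical tolerances

The package's own validation uses 60–300 s sessions at 1 kHz (the chosen
trade-off between frequency resolution and run time: a 60 s Welch PSD with
3 s windows averages 115 segments, ample for ±0.2 Hz peak recovery), 120 s
for comodulograms, 25 kHz for wideband spike traces, and 0.6–1.2 s
biophysical simulations at dt = 0.025 ms recorded at 2 kHz. Peak detection
tie-breaks by prominence over the fitted 1/f trend; phase wrapping uses
(−π, π] with bin edges inner-exclusive; all strict-versus-non-strict
comparisons at published constants follow the published wording (strict
everywhere in the trigger; the 10 spikes/s boundary documented above).

## Session I/O

Sessions serialize losslessly through R's native serialization
(`write_session()` / `read_session()`), with tracking, stimulation epochs
and trigger logs additionally exported as plain CSV at full double
precision. A thin command-line dispatcher (`theta_cli()`, wrapped by
`inst/exec/thetawave`) exposes the pipeline stages as subcommands over
YAML configs and writes CSV/JSON tables plus a provenance block (config
hash, seed, package version).

## Known limitations

* Single-cell, single-source biophysics: no network, no morphological
  reconstruction, no volume-conduction model linking the cell model to the
  multichannel generator.
* The generator's channels share oscillator sources through fixed gains, so
  cross-channel coherence is unrealistically high.
* The speed–frequency analysis inherits the ~5 Hz spectral blur of 200 ms
  bins; it classifies bands, not exact frequency edges.
* Surrogate-based significance is provided for the modulation index only.
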