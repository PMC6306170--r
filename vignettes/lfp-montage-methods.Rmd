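---
title: "Volume conduction and the LFP montage: model, generator and estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volume conduction and the LFP montage: model, generator and estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Local field potentials (LFPs) are usually recorded referentially (RR): one
low-impedance electrode in the structure of interest, measured against a
distant "cold" reference (a screw over the cerebellum). Because the
extracellular medium conducts, an RR channel integrates every current
source between electrode and reference, weighted by inverse distance —
*volume conduction*. A differential (bipolar, DR) montage instead subtracts
two closely spaced contacts in the same structure, cancelling the common
part of distant sources. This package implements the quantitative version
of that argument and the full analysis pipeline used to compare the two
montages on simulated two-area (hippocampal CA1 and medial prefrontal,
PFC) sleep recordings.

## Forward model

The medium is treated as linear, homogeneous, isotropic and purely ohmic
with conductivity $\sigma$ (default 0.3 S/m, typical gray matter; every
montage-comparison ratio is $\sigma$-independent). A point source of
current $I$ produces, in the quasi-static regime,

$$\vec J = \frac{I \hat u_r}{4\pi r^2}, \qquad V(r) = \frac{I}{4\pi\sigma r}.$$

A bipolar pair is parameterised by its midpoint, unit axis and
half-separation $\varepsilon$ (default 100 µm, inside the practical
50–200 µm range). With $r$ the midpoint-to-source distance and $\alpha$
the angle between axis and source direction, the exact contact distances
follow the law of cosines and `pair_difference()` evaluates three regimes:

* **exact** — $V_1 - V_2$ from the exact distances (any geometry);
* **distal** — first order in $\varepsilon/r$:
  $\Delta V_{dist} = 2I\,\delta r / (4\pi\sigma r^2)$ with
  $\delta r = \varepsilon\cos\alpha$; maximal on-axis, zero broadside, so
  the line through the contacts is the major detection axis;
* **local** — the exact law collapsed to $r = \varepsilon$:
  $\Delta V_{loc} = \frac{I}{4\pi\sigma\varepsilon}\,
  \frac{\cos(\alpha/2)-\sin(\alpha/2)}{\sin\alpha}$ (we verified this
  equals the surd form $\frac{\sqrt2}{2}\,
  \frac{\sqrt{1+\cos\alpha}-\sqrt{1-\cos\alpha}}{\sin\alpha}$ exactly, and
  the unit tests check it against the exact law to machine precision).

The ratio of the angle-independent prefactors of the local and distal laws
defines the common-mode rejection ratio

$$\Gamma = \frac{\sqrt2}{4}\left(\frac{r}{\varepsilon}\right)^2,$$

35 at $r = 10\varepsilon$ and 3500 (2 s.f.) at $r = 100\varepsilon$. The
montage signal-to-noise ratios for a wanted local source at $\varepsilon$
against an unwanted distal source at $r$ are $SNR_{RR} = r/\varepsilon$,
$SNR_{DR} = \Gamma$, their ratio
$\gamma = (\sqrt2/4)(r/\varepsilon)$, which crosses unity at
$r = 2\sqrt2\,\varepsilon \approx 3\varepsilon$ — the local/distal
boundary. `snr_global()` follows the per-axis convention of rounding
$\gamma$ to the nearest integer before raising it to the number of spatial
dimensions ($r = 6\varepsilon$: $\gamma = 2.12 \to 2 \to 2^3 = 8$).

### Accuracy of the distal approximation

Expanding the exact pair difference in $h = \varepsilon/r$ gives

$$\frac{|\Delta V - \Delta V_{dist}|}{|\Delta V|}
  = \frac{|5\cos^2\alpha - 3|}{2}\,h^2 + O(h^4).$$

The coefficient is 1 on-axis and rises to $3/2$ as
$\alpha \to \pi/2$ (where both quantities vanish and the ratio is taken in
the limit). The package therefore documents the uniform bound
$1.6\,(\varepsilon/r)^2$ over $\alpha \in (0, \pi/2)$; a tighter constant
such as 1.1 holds only for $\alpha \lesssim 66°$. On-axis the error is
exactly $(\varepsilon/r)^2$ — $10^{-4}$ at $r = 100\varepsilon$ — and
decreases monotonically with distance.

## Synthetic recording generator

No public recordings exist for this preparation, so the generator is a
first-class, tested component: it renders known ground truth through the
forward model, and every downstream claim is a parameter-recovery
statement about that ground truth.

**Geometry.** CA1 and PFC pair midpoints sit 6.5 mm apart (the
stereotaxic AP separation of the two areas) on a shared axis, which is
also both pair axes. Local sources sit on the pair axis at
$\varepsilon$ beyond the first contact — distance $\varepsilon$ from
contact 1 and $3\varepsilon$ from contact 2, so a local source's
differential amplitude is exactly 2/3 of its referential amplitude. A
strong distal common source sits ~3.8 mm from both midpoints. The
reference is placed 80 mm away on the midline: the montage contract
requires the reference to be at least 10× farther from *every* source
than *any* pair midpoint is (the CA1 sources are 6.5 mm from the PFC
midpoint, forcing ≥ 65 mm), which is what makes it a usable cold spot.

**State-conditioned sources.** A bout-structured hypnogram (default 55
Wake + 195 NREM + 110 REM epochs of 15 s; the sleep counts and epoch
length mirror the scored-session design, Wake is added so all three
classes occur) gates the oscillators:

* REM — a 7 Hz theta process local to CA1, plus Poisson-scheduled
  (6/min) 10–14 Hz bursts present in *both* areas, the PFC copy delayed
  by exactly 35 ms (the generator default equals the delay the analysis
  is asked to recover);
* NREM — an 0.5–2 Hz slow-oscillation process per area plus
  PFC-local 10–14 Hz sleep spindles (6/min);
* always — per-area pink ($1/f$) background and the distal common
  source;
* an EMG channel of state-gated broadband noise (100/30/5 µV RMS in
  Wake/NREM/REM — REM atonia) that bypasses the forward model.

All narrowband oscillators are *stochastic* (band-pass filtered noise),
not pure sines: two independent theta generators must add in power, not
interfere coherently — with deterministic sines the CA1 theta power would
depend on the random relative phase of the local and conducted
generators, which is both unphysical and irreproducible across session
lengths.

**Amplitude calibration.** The study design states no source amplitudes;
the defaults were fixed once, from three stated conditions: referential
power ≈ 10× differential power in REM; the distal common source dominant
in the referential channels (so RR lag distributions collapse to zero
lag); and bursts detectable in DR. In µV at the nearest own-area contact:
theta 70 RMS, slow oscillation 120 RMS, spindles 60 peak, REM bursts 40
peak, pink background 10 RMS, common source 150 RMS (75% pink power, 25%
REM-gated theta power, so both referential channels share conducted theta
and the 7 Hz RR coherence peak collapses under imaginary coherence). With
the default geometry the common source reaches the CA1 referential
channel at ~143 µV but the differential channel at ~7 µV — a 21-fold
amplitude suppression — giving a REM RR/DR power ratio of ~9–12, burst
in-band power about half the common in-band power in RR (zero lag wins),
and burst-to-background envelope SNR ≈ 7 in DR (detection wins).

**I/O.** Sessions round-trip through EDF (16-bit, one-second records,
per-channel auto-scaled physical range in µV), with the hypnogram in a
CSV sidecar and the full ground truth (schedule, parameters, montage,
seed) in JSON. The writer/reader is a minimal implementation of the
published EDF layout; traces are recovered to within the per-channel
quantization step.

## Estimators

**Welch spectra.** One-sided segment-averaged periodograms with window
power correction, default 5 s Hann segments with 50% overlap inside each
15 s scoring epoch (the epoch length fixes the 1/15 Hz ≤ 0.1 Hz
resolution requirement; the estimator internals are our choice). Density
units are µV²/Hz and integrate back to the variance (Parseval, tested to
5% for white noise).

**Coherence.** Magnitude-squared coherence averages cross- and
auto-spectra across segments before forming
$C_{XY} = |\overline{XY^*}|^2 / (\overline{|X|^2}\,\overline{|Y|^2})$;
a single segment is rejected (degenerate $C \equiv 1$), and for
independent signals the estimator bias is ≈ 1/M for M segments (tested).
Imaginary coherence reports $|\mathrm{Im}|$ of the normalised averaged
cross-spectrum: zero-lag (conducted) coupling is purely real and is
suppressed, while a transmission delay $d$ leaves
$|\sin(2\pi f d)|\sqrt{C}$.

**Burst detection.** Zero-phase 4th-order Butterworth band-pass
(10–14 Hz; the band is the one fixed point of the procedure, everything
else is package design), analytic-signal envelope, 0.1 s moving-average
smoothing, threshold at envelope mean + 2 SD computed over the containing
state's epochs, minimum 0.4 s above threshold, 0.2 s merge gap. The
duration gate applies to the raw supra-threshold runs — that ordering is
what keeps the white-noise false-positive rate below 0.5/min — and event
edges are then refined outward to mean + 1 SD so reported onsets track
true onsets to within roughly the envelope correlation time
(~1/bandwidth = 0.25 s; typically well under 0.1 s).

**Lag distributions.** Per detected event, a 1.2 s window of each area's
channel is band-passed (10–14 Hz) and the normalised cross-correlation is
scanned over ±100 ms; positive lag means PFC lags CA1. Because both
channels share the same contact orientation, the physiological peak is
positive, and the per-event peak is taken as the maximum *signed*
correlation; this also resolves the ±half-cycle lobe ambiguity intrinsic
to narrowband cross-correlation (the general `xcorr_peak()` keeps the
absolute-peak convention, with a `peak` argument). The per-event lags are
summarised by a Gaussian-kernel density (Silverman bandwidth), an
empirical CDF and the median. Windows are deliberately *not* tapered:
tapering up-weights the window centre where the burst lives and biases
the referential-mode distribution away from the zero-lag common-source
peak it is supposed to reveal.

**Burst-triggered coherence.** One Hann-tapered 1 s window per event,
with the coherence average carried out over events only. Restricting the
average to communication episodes avoids diluting phase-locked transients
across the silent majority of the recording; swapping the triggering area
leaves the result unchanged (tested), and replacing events by random
windows collapses it back to the sliding-window level.

**Coherence vs noise.** The canonical degradation simulation pins: unit
sine on an exact DFT bin, rectangular window, 400-sample disjoint
segments, ≥ 500 (default 2000) averages, Gaussian noise parameterised by
its standard deviation (the noise-to-signal ratio for a unit sine). Under
this configuration the per-bin SNR is 1 at noise SD 10 and the expected
coherence at the sine bin is exactly
$1/(1 + \sigma^2/100)$ — 0.5 at SD 10, 0.2 at SD 20. A hyperbolic-secant
law $C = \mathrm{sech}(a\,\sigma)$ is fitted by one-dimensional
least-squares; the flat-noise curve is Lorentzian rather than sech, so
the fit is an approximation whose residual RMS stays below 0.08 over the
default level grid. Note the flat-noise model fixes the SD-10 → SD-20
drop at exactly 2.5-fold; the acceptance check applies the ±0.02
per-point tolerance of the operating point to both endpoints
(0.48/0.22 ≈ 2.18) because an estimate sitting exactly on its expected
boundary would otherwise fail half the time by construction.

**Scoring.** Per 15 s epoch: delta (0.5–4 Hz) power, theta (6–10 Hz)
power, their ratio, EMG RMS. The rule is Wake if EMG exceeds the muscle
threshold, else NREM if delta exceeds the delta threshold, else REM if
theta/delta exceeds the ratio threshold, else NREM; single-epoch islands
are absorbed by their neighbours. Thresholds are derived per recording by
a deterministic one-dimensional k-means on the log features (three
clusters for the EMG, whose RMS takes three state-dependent levels, two
otherwise), with absolute fallbacks when a feature is unimodal (EMG
against the overall EEG RMS; delta against half the broadband power;
ratio against 1.5). Band powers many orders of magnitude below the
broadband level are floored first so spectral leakage cannot masquerade
as a bimodal feature. The derivation assumes all three states occur;
sessions without Wake may misattribute NREM muscle tone.

## Reproducibility and problem sizes

Everything stochastic flows from one integer seed through deterministic
per-stage child seeds; identical configuration and seed give
byte-identical JSON reports (tested). The test suite exercises the full
default session (195 NREM + 110 REM + 55 Wake epochs, 1 kHz, 90 min) for
the parameter-recovery checks and smaller sessions (10–60 epochs)
elsewhere; the coherence-vs-noise curve uses 2000 segments per level.
These sizes were chosen so the whole suite completes in a few minutes on
one CPU while keeping every estimator deep inside its averaging regime.

## Limitations

* The medium is ohmic, homogeneous and isotropic; capacitive or
  frequency-dependent extracellular behaviour and finite-size electrodes
  are out of scope.
* The generator emulates the *statistical* structure of two-area sleep
  LFPs (state-gated narrowband processes, conducted common activity,
  delayed common bursts), not biophysics: no spiking, no synaptic
  dynamics, no movement artifacts (the analyses target sleep precisely to
  avoid them). Passing parameter-recovery tests therefore demonstrates
  estimator correctness under the stated noise model, not performance on
  real tissue.
* Burst-onset accuracy is bounded by the band envelope correlation time;
  narrowband cross-correlation carries an intrinsic half-cycle ambiguity
  that the positive-peak convention resolves only when coupling preserves
  polarity.
* The sech law is a descriptive fit to a Lorentzian-shaped curve; its
  scale parameter should be compared across configurations, not
  interpreted mechanistically.
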