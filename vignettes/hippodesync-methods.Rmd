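---
title: "Methods: synthetic sessions and the desynchrony analysis pipeline"
author: "hippodesync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic sessions and the desynchrony analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippodesync)
```

## The scientific problem

Early postnatal exposure to the NMDA-receptor antagonist MK-801 is a standard
rodent model of schizophrenia. In adulthood such mice are hyperlocomotive, and
their hippocampal CA1 circuit shows a characteristic *desynchrony* signature:
theta (5–12 Hz) and gamma (30–80 Hz) LFP power are elevated, yet single
neurons are *less* phase-locked to the theta rhythm; calcium transients of
individual neurons are more frequent and larger, yet pairwise correlations
between neurons and correlations with running speed are reduced. The atypical
antipsychotic aripiprazole (ARI) partially restores each of these measures.

`hippodesync` implements the complete measurement pipeline for this signature
— band power, spike–field coherence, RS/FS unit classification, calcium
transient statistics, correlation analysis, open-field metrics and group
statistics — together with a synthetic-session generator that emulates the
vehicle, MK-801 and ARI conditions. Because the original recordings are not
publicly deposited, the generator is what makes every stage verifiable: each
analysis is tested against data whose ground truth is known by construction.

## The synthetic-session generator

A session couples five modalities on one clock (t = 0 at session start):

* **LFP**: \(x(t) = \sum_b A_b \sin(2\pi f_b t + \phi_b) + \varepsilon(t)\) with
  delta/theta/beta/gamma components at 2, 8, 20, 40 Hz and pink noise shaped
  in the frequency domain (power \(\propto f^{-1}\), SD 20 µV). The analytic
  theta phase \(\theta(t) = 2\pi f_\theta t + \phi_\theta\) is carried as
  ground truth.
* **Spike units**: inhomogeneous Poisson processes with von Mises-modulated
  intensity \(\lambda(t) = r_0 \exp[\kappa \cos(\theta(t) - \phi_0)] / I_0(\kappa)\),
  sampled exactly by thinning. The \(I_0\) normalization keeps the mean rate
  equal to \(r_0\) for every \(\kappa\): synchrony and rate are decoupled, as in
  the modeled experiment, where coherence changes without rate changes. RS
  units draw \(r_0\) from 1–15 spikes/s with 0.8 ms trough-to-peak waveform
  templates; FS units draw 15–50 spikes/s with templates half as wide.
* **Calcium traces** (10 Hz frames): per neuron, per-frame event counts are
  Poisson with \(\log \lambda_t = c + a L_t + \beta v_t\), where \(L\) is a
  shared standardized AR(1) latent (3 s autocorrelation time), \(v\) the
  running speed, and \(c\) normalizes the mean event rate to
  `transient_rate_hz`. Events get amplitudes from a truncated normal
  (mean 60, SD 15 a.u. — comfortably above the detection height of 20) and
  are convolved with \(e^{-t/\tau}\), \(\tau = 0.7\) s; Gaussian noise of
  SD 5 a.u. is added. The loading \(a\) drives pairwise correlation, \(\beta\)
  drives speed correlation.
* **Treadmill speed**: alternating move/rest bouts (exponential durations,
  mean move bout 8 s, 60% of time moving) with a rectified mean-reverting
  (OU) speed around 8 cm/s during movement.
* **Open-field trajectory**: a smooth heading random walk at OU-regulated
  speed inside the 55 × 40 cm arena with reflecting walls, 30 min at 20 Hz.

Every generator is a pure function of `(config, seed)`; a session is
bit-reproducible from its preset name and seed.

### Condition presets

The experiment reports directions and test statistics, not generative effect
sizes, so the preset effect sizes are free parameters of the emulation,
chosen once to produce clearly resolvable effects at desk-scale session
lengths and documented here:

| parameter | VEHICLE | MK801 | MK801_ARI |
|---|---|---|---|
| theta amplitude | 50 µV | ×1.5 | ×1.25 |
| gamma amplitude | 10 µV | ×1.5 | ×1.25 |
| locking concentration κ | 2 | ×0.35 | ×0.675 |
| transient rate | 0.1 Hz | ×1.4 | ×1.2 |
| transient amplitude | 60 a.u. | ×1.3 | ×1.15 |
| latent loading a | 0.9 | ×0.35 | ×0.675 |
| speed coupling β | 0.15 /(cm/s) | ×0.3 | ×0.65 |
| mean speed | 8 cm/s | ×1.6 | ×1.3 |

Delta and beta amplitudes, the decay constant τ and the RS/FS rate ranges are
deliberately *not* touched by any preset — they are the negative controls.
`MK801_ARI` sits halfway between `MK801` and `VEHICLE` on every perturbed
parameter (partial restoration); `VEHICLE_ARI` equals `VEHICLE`, because the
drug leaves healthy animals unchanged on all emulated metrics.

### What the generator does and does not emulate

The generator reproduces the *statistical* structure the analyses assume:
oscillations plus 1/f background, phase-locked point processes,
latent-driven sparse calcium dynamics, bout-structured locomotion. It does
not emulate place fields, theta–gamma cross-frequency coupling, spike
waveform variability in noise, imaging artifacts, or non-Poisson firing
(bursting, refractoriness). Passing tests therefore certify the estimators
under the stated model, not performance on every pathology of real data.
Locomotion bout statistics on a treadmill are not quantified in the modeled
study; the bout parameters are realistic defaults, not claims.

## Analysis stages and numerical choices

**Band-splitting.** Zero-phase Butterworth filtering (forward–backward),
1–300 Hz for the LFP and 300–5000 Hz for the spike band; the signal is
demeaned first, which removes DC exactly. The 1 Hz corner uses a 2nd-order
section — at normalized frequencies of order 10⁻⁴ higher-order transfer
functions are numerically fragile — while the 300 and 5000 Hz corners use
4th-order sections.

**Power spectra.** Multitaper estimation with Slepian tapers computed from
the symmetric tridiagonal eigenproblem: 2 s windows, time–bandwidth 3,
5 tapers, 50% overlap; conventional parameters recorded in the spectrum's
metadata. Scaling is Parseval-consistent (integral of the PSD = variance,
verified to 5% for tones and 10% for broadband noise). Band power is the
trapezoidal integral over delta (1–4), theta (5–12), beta (13–30) or gamma
(30–80 Hz), with interpolated band edges so adjacent bands are additive;
both absolute (µV²) and relative power are reported, and comparisons use
absolute power.

**RS/FS classification.** Width-primary: trough-to-peak width ≥ 0.45 ms is
RS, below is FS. The published rate ranges (RS up to 15/s, FS 15–50/s)
overlap at the boundary, so rate is used only as a logged consistency check.

**Spike–field coherence.** For each unit, spikes during locomotion
(median-smoothed speed > 1 cm/s over 0.5 s — the threshold is configurable
since the source protocol names no value) are subsampled to the same count
for every unit (the minimum eligible count, seeded and reproducible). The
300 ms of LFP centered on each spike is extracted; coherence at frequency f
is 100 × PSD of the spike-triggered average divided by the mean PSD of the
individual windows, clipped to [0, 100]. Windows use a single Hann-taper
periodogram (≈3.3 Hz resolution — enough to localize a theta peak; the
windows are too short for multitaper averaging). In the fully locked limit
all windows are identical and coherence is 100%; for spikes independent of
the field it concentrates around 100/N. Peak ties (which occur in the exact
locked limit, where the whole spectrum clips at 100%) are broken toward the
frequency with the greater STA power, then toward the lower frequency, so a
pure 8 Hz locking reports its peak in theta rather than at the lowest tied
bin. The theta-band coherence of a unit is the maximum over 5–12 Hz, and
the population summary counts units whose peak exceeds 20%.

**Transient detection.** Local maxima on the raw trace (plateaus reported at
their midpoint), then, in order: height ≥ 20 a.u., greedy-by-height distance
suppression (peaks closer than 10 frames to a taller kept peak are removed),
and topographic prominence ≥ 20 (height above the higher of the two flanking
minima, each flank bounded by the nearest higher sample or the signal edge).
The amplitude of a transient is the raw trace value at its peak — the
near-zero baseline of both the generator and the raw-trace convention makes
this the natural scale for the thresholds. The implementation is verified
against a brute-force enumeration oracle and against the reference
`find_peaks` routine the protocol names.

**Isolation and decay.** The isolation score of a transient is its minimum
frame gap to any neighboring detection (edge transients use their single
neighbor); the 10 best-isolated transients per neuron enter the decay fit
(ties by amplitude, then earlier frame). "Best isolated" is not defined
quantitatively in the source protocol; the minimum-gap score is this
package's operationalization. Each post-peak segment (to the next detected
transient or 3 s) is fit to \(A g^n\) by log-linear least squares in two
passes: an unweighted fit on the first frames gives a preliminary curve,
which then *selects* the samples (fitted value ≥ 20% of the peak) and
supplies the *weights* (squared fitted values — the delta-method inverse
variance of a log-transformed sample). Selecting and weighting on fitted
rather than observed values prevents noise from correlating with the
weights; the peak frame itself is excluded (peak picking selects upward
noise there); the log values carry a first-order Jensen correction
\(+\sigma^2 / 2\hat y^2\) with σ estimated from frame differences; and the
fitted tail is truncated at the first rise of more than 20 a.u. above the
running minimum, which flags events hidden below the detection threshold.
Together these keep the estimator unbiased to within a few percent across
the signal-to-noise range the conditions span — without them,
condition-dependent bias would masquerade as a decay effect. The per-neuron
decay factor is the amplitude-weighted mean over transients, and
τ = −(1/fs)/ln(g). Estimated decays over 2.5 s are flagged as failed
extractions; the neuron is excluded from decay summaries only, not from
rate or amplitude analyses (the source text is ambiguous on this point; the
narrower exclusion is this package's choice).

**Correlations.** Pearson and Spearman on the z-scored traces (constant
traces are excluded, not NaN-propagated), Fisher z = atanh(r) applied
elementwise with clipping at |r| = 1 − 10⁻⁶. Speed is aligned to the frame
clock by linear interpolation. Group comparisons use Fisher-z values —
variance stabilization is the point of the transform; summaries report both.
Speed correlations default to Pearson, with Spearman also available.

**Open field.** Distance is the sum of Euclidean steps (no smoothing —
synthetic paths are already smooth; a smoothing option exists for real
tracking); the center region is the concentric rectangle with half-scaled
sides, exactly 25% of the arena area for any dimensions; center time is
reported as a percentage. The analysis window is 30 min.

**Group statistics.** Single-factor designs use Student's two-sample t-test;
2 × 2 designs (group × treatment) use a two-way ANOVA with Šídák-adjusted
post-hoc contrasts of treatment within group, via `emmeans`. These are
off-the-shelf procedures, deliberately delegated to standard routines.

## Session storage

Sessions are stored as one directory per session: `meta.json` (labels,
sampling rates, provenance) plus CSV files per modality mirroring the
`/lfp`, `/units/<k>`, `/calcium`, `/speed`, `/trajectory` structure. The
format is deliberately plain text: inspectable with any tool, diff-able,
and lossless — numbers are serialized with 17 significant digits, so a
write/read round trip reproduces every double bit-exactly (tested).
Sampling rates are always stored explicitly; nothing is inferred.

## Problem sizes and test design

The test and acceptance runs use desk-scale problem sizes chosen so that
every effect is resolvable yet the whole suite runs in minutes: 120 s
sessions (1000 Hz LFP, 10 units, 15 neurons), cohorts of 10 matched seeds
per condition, 20-seed Monte-Carlo loops for estimator calibration. Matched
seeds across presets share all condition-independent draws (unit base
rates, LFP noise, oscillator phases), so preset contrasts isolate condition
effects. Direction-of-effect checks compare standardized effects at the
level at which the emulated study tests them: band powers per session,
firing rates per unit, calcium statistics per neuron.

## Known limitations

* The SFC normalization can exceed 100% in finite samples; values are
  clipped, which is this package's documented choice.
* "Raw LFP" for the coherence windows is taken to be the 1–300 Hz band, the
  more common reading; wideband can be passed explicitly if preferred.
* The decay estimator assumes a mono-exponential kernel; real indicators
  (GCaMP6s) have a rise time and mild non-linearity that the generator does
  not model.
* Whether published band powers are absolute or normalized is not stated in
  the source protocol; both are computed, and comparisons default to
  absolute.
* NWB import/export is out of scope in this implementation; the plain-text
  session container carries the same information and round-trips losslessly.
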