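---
title: "Methods: single-vesicle TIRF fusion and clustering analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-vesicle TIRF fusion and clustering analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesiclekit)
```

## The two assays

vesiclekit analyses two single-vesicle total internal reflection
fluorescence (TIRF) experiments on proteoliposome mimics of synaptic
vesicles.

**Ca²⁺-triggered content-mixing fusion.** "v-vesicles" (reconstituted
synaptobrevin-2 ± synaptotagmin-1, ~80 nm, carrying self-quenched
sulforhodamine B content dye) dock to surface-immobilized "t-vesicles"
(syntaxin-1A/SNAP-25A). Docked vesicles are diffraction-limited spots;
complete fusion dilutes the content dye about twofold, relieving
self-quenching, so each fusion event is a stepwise *increase* of a spot's
content-dye trace. Events within a 50-s window after Ca²⁺ injection are
counted in 1-s bins, self-normalized by the total event count, and fitted
with a bi-exponential decay
$f(t) = y_0 + A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2}$.
Because the Ca²⁺ arrival time in the evanescent field is not observed
directly, it is defined per field of view as the time of the *first*
content-mixing event; fields are pooled after this post-synchronization.
This convention necessarily places one event in the first bin of every
field — a small left-edge bias we reproduce rather than correct, since it
is part of the assay's published procedure.

**v-/v-vesicle clustering.** A saturated layer of DiD-labeled v-vesicles is
immobilized; after incubation with α-synuclein (wildtype, Parkinson's
disease point mutants, truncations) and buffer exchange, free-floating
DiI-labeled v-vesicles are injected. Clustering activity is read out by
counting DiI spots per imaging location (10–20 random locations per
channel), after confirming block-wise homogeneity of the DiD surface.
Condition contrasts use the classical pooled-variance Student's t-test,
two-tailed, because only that test (without a Welch qualifier) is named in
the source protocol.

## The synthetic microscope

No raw imaging data accompany the experiments, so the package ships a
generator that emulates them with planted ground truth. What it models:

* **Image formation.** Isotropic Gaussian point-spread function
  (`psf_sigma_px = 1.5` px) on a 512×512 16-bit field; each ~80 nm vesicle
  is sub-resolution, so a docked cluster of multiplicity $k$ is a single
  spot of $k$-fold integrated flux (12 000 counts per vesicle). Constant
  background (100 counts) plus Poisson shot noise and Gaussian read noise
  (sd 2).
* **Placement.** Spot centers are uniform over the field interior with a
  minimum separation of 4 PSF sigmas and a 12-px border margin (so every
  spot admits a full integration disc and annulus). The realized spot
  count is Poisson with the preset's mean.
* **Traces.** Content-dye level is constant before the event and multiplied
  by the dequench factor (default 2.0, the simplest model consistent with
  the approximately twofold dilution of the self-quenched dye) from the
  first frame at or after the event time.
* **Event times.** The published fits only give $f(t)$; a density must be
  non-negative, so times are drawn from the positive bi-exponential part on
  [0, 50] s, ignoring the small negative offset (a baseline artifact of the
  fit). Component $i$ has weight $\propto A_i \tau_i (1 - e^{-50/\tau_i})$.
* **Frames.** 1-s frame interval, equal to the histogram bin width (the
  acquisition frame rate is not stated in the protocol; an implementer
  wanting sub-bin localization should raise the synthetic frame rate). Five
  pre-trigger frames precede $t = 0$ so docked spots exist before Ca²⁺
  injection, and one trailing frame at $t = 50$ s is rendered so an event
  falling in the final 1-s bin still has an at-or-after frame — otherwise
  late events would be unobservable by construction.
* **Cluster sizes.** A geometric law on $k = 1..6$ (mean set per condition)
  models the decaying cluster tail; very large aggregates are a separate
  rare process (drawn multiplicity 15–40, doubled PSF width) that the
  analysis must *exclude* from scoring, as in the published counting rule.
* **Conditions.** Presets encode the study conditions: the two fusion
  conditions carry the published kinetic parameters and event/docked ratios
  (166 of ~2000 without α-synuclein; 84 of ~1300 with 2 µM), with the event
  total planted exactly so the detection chain can be audited against it.
  Clustering presets encode the relative contrasts (expected DiI counts
  50 / 150 / 300 for background / 2 µM / 20 µM wildtype; A30P at half of
  matched wildtype; E46K and A53T at wildtype; synaptobrevin-2-free,
  anionic-lipid-free and α-Syn[1–95] conditions at background), since only
  relative differences are reproducible across surface preparations.

What it deliberately does **not** model: vignetting, stage drift, TIRF
evanescent-depth decay, photobleaching (off by default), camera fixed
pattern, or chromatic offsets between the DiI/DiD channels. Passing tests
therefore demonstrate correctness of the *analysis* under idealized but
noise-realistic imaging, not robustness to every instrumental artifact of
real data.

## Analysis choices

**Spot detection.** The protocol never defines "spot" operationally (it
lived in acquisition software), so the package adopts the standard
smoothed-local-maximum detector: tiled-median background estimation
(medians on a coarse grid, bilinearly interpolated — a moving median at
stride), robust pixel noise from the MAD of horizontal first differences,
Gaussian smoothing matched to the PSF, 8-neighbour maxima above
`k_thresh = 5` noise sigmas of the smoothed frame, greedy non-maximum
suppression within 3 px. Centers are refined with an iterated centroid
restricted to a disc of radius 3σ — the restriction matters at the 4σ
packing of a crowded field, where an unmasked window centroid is dragged
~2 px by a neighbour. Intensities are integrated in a 3σ disc minus the
annulus median (3σ–5σ); the annulus *median* is what makes the measurement
robust to a neighbour intersecting the annulus.

**a.u. normalization.** The arbitrary-unit scale anchors the mode of the
spot-intensity distribution — the single-vesicle peak — at 1, located via a
kernel density estimate; below 20 spots the mode is unreliable and the
median is used with a warning. This makes the published thresholds
directly applicable: singles < 1.5 a.u., clusters ≥ 2 a.u. The [1.5, 2)
gap between the two published thresholds is reported as a separate
"intermediate" class and pooled with clusters in summary totals;
"very large" spots (> 6 a.u. or area > 4× the PSF half-max area, both
configurable) are excluded from scoring.

**Step detection.** A two-sided sliding window (w = 5 frames) marks the
boundary maximizing the mean difference; an event requires the difference
to exceed `k_step = 5` robust noise sigmas (MAD of first differences /
√2), to persist `m_sustain = 3` frames, to be upward, and to have a
post/pre ratio of at least `min_ratio = 1.5`. The last criterion is the
package's dequench-consistency floor: at 4σ packing, a spot's integration
disc overlaps a fusing neighbour's halo and inherits a statistically
significant step of ratio ~1.1–1.3, which is not a content-mixing event of
that vesicle; 1.5 is halfway between no step and the twofold dequenching.
At trace edges the windows truncate and the threshold is scaled by
$\sqrt{(1/w_1 + 1/w_2)/(2/w)}$ so truncated windows are not easier to
pass. At most one event is reported per spot ("complete fusion").

**Bi-exponential fitting.** Unweighted least squares on the (bin-center,
probability) pairs, matching the published fitting procedure.
Initialization is a variable-projection grid — for each pair of log-spaced
time constants the linear parameters have a closed-form solution — whose
best cells are polished with Levenberg–Marquardt. The polish is
box-constrained (|y₀| ≤ 1, |A| ≤ 10, τ ∈ [0.05, 500] s): self-normalized
probabilities make larger values unphysical, and a time constant far above
the 50-s window trades off exactly against the offset, producing runaway
fits. Components are reported slow-first (τ₁ ≥ τ₂); the offset may be
negative, as in the published fits. Fits with a vanishing second amplitude
or nearly equal time constants are flagged degenerate.

A caution established by simulation: with only ~166 events, the sampling
noise of a 1-s-binned histogram leaves both time constants poorly
determined — roughly half of seeded replicates recover them within 50%,
and the tails are long. The package's tests assert this simulated envelope
(median relative error, fraction within 50%), not wishful precision;
binning itself introduces no bias in the time constants (an exponential
integrated over equal bins stays exponential in the bin index — verified
noiseless to machine precision).

**Depletion relation.** The decrease in v-/t-vesicle associations when
clustering is switched on is modeled by the simplest mass balance: a fixed
vesicle budget clustered with mean size $E[k]$ yields $n/E[k]$ free
particles. The anti-correlation between per-condition clustering and
association counts is summarized by Spearman rank correlation, because
only ordinal structure is claimed.

## Problem sizes and reproducibility

All randomness flows from explicit seeds; every preset carries a default
seed, so the fusion fixtures are bit-reproducible and their planted event
totals (166, 84) are recovered exactly by the default detection chain.
Unit tests run on 256-px fields with tens to hundreds of spots; the
acceptance computations use the full 512-px, ~2000-spot conditions. The
Monte-Carlo suites use 500–1000 synthetic traces and 60–100 fit
replicates, sizes at which the asserted rates are stable to a few percent.

## Known limitations

* Exact event-count recovery holds at the fixtures' high signal-to-noise
  and 4σ packing; at lower contrast the detector degrades gracefully to the
  ≥99% recall / ≤1% false-event regime, not to exactness.
* The `min_ratio` floor assumes complete fusion with dequench factor ≈ 2;
  partial-fusion or hemifusion intermediates would be rejected by design.
* The a.u. anchor assumes singles dominate the field; a sample that is
  mostly clusters would normalize to the wrong mode.
* Absolute clustering counts are preset conventions; only relative
  contrasts between conditions are meaningful, mirroring the variation
  between surface preparations noted in the source protocol.
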