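---
title: "Quantifying vasomotor oscillations and travelling haemodynamic waves in functional ultrasound movies"
author: "fuswaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vasomotor oscillations and travelling haemodynamic waves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and the model

Functional ultrasound (fUS) Power Doppler imaging records a movie whose
intensity is proportional to local cerebral blood volume (CBV), here at
100 µm pixels and a 0.4 s frame period (Nyquist 1.25 Hz). Under
neuroinflammation the resting haemodynamic signal can reorganise into
high-amplitude, quasi-sinusoidal *vasomotor* oscillations near 0.1 Hz
that travel through the tissue as waves at 0.1–0.8 mm/s, extend from
cortex into subcortical territories, reshape functional connectivity and
concentrate almost all broadband variance in a handful of spatial modes.
`fuswaves` implements the complete resting-state analysis of such movies:

* **fALFF maps** — the fractional amplitude of low-frequency fluctuations,
  defined per series as the one-sided DFT amplitude summed over the band
  of interest (default 0.08–0.15 Hz) divided by the amplitude summed over
  all positive frequencies (DC excluded). Computed on the *raw* movie; per
  ROI it is evaluated on the ROI-mean series (signal extraction before
  analysis), and pixel maps are thresholded at fALFF > 0.075. Following
  the REST-toolbox lineage the ratio uses amplitudes; `power = TRUE`
  switches to squared amplitudes.
* **Static functional connectivity** — Pearson correlation between ROI
  time courses band-passed to 0.0008–0.2 Hz, Fisher z-transformed
  (r clipped to ±(1−10⁻⁷)) before group averaging and differencing.
* **Dynamic seed connectivity** — sliding-window (15 frames = 6 s, step
  1 frame) Pearson correlation between a seed-ROI mean and every pixel of
  the 0.08–0.15 Hz filtered movie, averaged over a target ROI; windows
  are stamped at their centre. The trace aggregates r (not z) by default,
  matching how such heatmaps are displayed; `aggregate = "z"` is available.
* **Oscillatory modes** — each acquisition is band-passed (0.0008–0.2 Hz),
  centred by its global mean and divided by its global sd (one scalar per
  acquisition, preserving relative regional amplitudes — pixelwise
  z-scoring would erase exactly the amplitude structure of interest), and
  reshaped to pixels × time. The pixelwise covariance matrices are
  averaged over a group's acquisitions and eigen-decomposed; components
  with eigenvalue > 0.1 (on this unit-variance scaling) are retained, at
  most 10. Temporal projections, their group-mean amplitude spectra,
  reconstructions from the first k components, and the scree
  (cumulative explained variance over the eigenvalue total) follow.
* **Event detection** — on the 0.08–0.15 Hz filtered movie, each pixel is
  z-scored against a robust noise sd, the z-movie is smoothed with a
  spatial Gaussian (σ = 0.5 px), thresholded at z > 5, grouped into
  spatiotemporal connected components (8-neighbour within frames,
  consecutive frames linked by ≥ 1 px footprint overlap) and filtered to a
  minimum single-frame footprint of 15 px. Event features: z-excess
  weighted per-frame centroid track, propagation distance (the sum of
  consecutive centroid displacements), peak relative-CBV amplitude within
  the footprint, per-pixel peak-time delay map, and mean centroid speed.
  Events travelling more than 5 px are *dynamic* (travelling waves); scan
  summaries average features over the dynamic events.
* **Trajectory taxonomy** — delay maps are binarised and SVD-reduced
  (component cap 3000, bounded by the rank) and k-means clustered into 4
  spatial clusters with k = 2 directional subclusters on the
  (horizontal, vertical) delay-slope vectors; independent of this
  descriptive clustering, every event receives one of six named trajectory
  labels (medio-temporal, temporo-medial, trans-hemispheric,
  cortico-subcortical, cortico-hippocampal, hippocampo-cortical) or
  `UNCLASSIFIED_STATIC`, by an explicit rule (below). Per-scan proportion
  tables are reported with and without the unclassified class.
* **Stimulation blocks** — 30 s dark rest then 4 blocks of 30 s visual
  flicker (3 Hz) separated by 45 s rest; ΔCBV% is computed against the
  initial rest, the four block-aligned ROI time courses are averaged, and
  the scalar response is the mean ΔCBV% over the stimulation epochs.

## The synthetic movie generator

Every stage is validated by parameter recovery on movies whose truth is
known. The generator defines a schematic coronal atlas (five cortical
regions per hemisphere ordered medial→temporal, superior colliculus and
hippocampus beneath, dorsal and ventral midbrain below; mirrored about the
vertical midline) and composes, multiplicatively on a per-region baseline
of order 100 a.u.:

* per-pixel temporal noise: white (sd 4.6) plus 1/f (sd 1.0, exponent 1)
  synthesised by spectral shaping. These defaults put the in-band
  (0.08–0.15 Hz) noise sd near 1.1% of baseline, so that raised-cosine
  waves of 10–30% peak amplitude span detector z-scores of roughly 4–13,
  i.e. they straddle the z > 5 threshold — the working regime the detector
  is meant to resolve;
* **travelling waves**: a Gaussian bump (sd `widthMm`, truncated at 3σ so
  events are exactly local) advancing along a waypoint path at a fixed
  speed while carrying a raised-cosine (nonnegative — CBV increases)
  oscillation at 0.08–0.15 Hz;
* **static events**: the same bump with a fixed centre and one
  raised-cosine cycle of 6–12 s, so their spectral content lies in the
  analysis band;
* **stimulation responses**: block boxcars convolved with exponential
  rise/fall, applied in the visual cortices.

The `VEH-like` arm carries sparse, low-amplitude (10–22%) cortical
medio-temporal/temporo-medial waves and occasional static events. The
`LPS-like` arm adds quasi-periodic oscillatory *trains* — repeated 2–3
cycle sweeps at 60% peak amplitude along fixed cortical and
cortico-hippocampal trajectories, alternating direction between bouts and
separated by 70–100 s gaps — plus frequent discrete waves from all six
patterns (22–38%) and larger static events. Every injected event is
logged with its true centroid track, path length, dynamic flag and an
*expected detector peak z*: amplitude/2 × baseline × band filter gain at
the carrier frequency ÷ in-band noise sd, additionally divided by the
analytically predicted inflation of the noise estimate caused by the
scan's own event schedule at that location (see below). Identical seeds
give bit-identical movies; event modulations compose multiplicatively.

What the generator deliberately does **not** model: spatially coherent
slow physiological fluctuation (the real resting brain's global and
network-structured drift), movement artifacts beyond spike contamination,
ultrasound physics (speckle, clutter filtering), or vascular anatomy.
Consequently the control arm's 10-component explained variance sits far
below the ~80% seen in vivo (its broadband variance is mostly white), and
passing tests demonstrate correctness of the algorithms under the stated
statistical structure, not performance on real acquisitions.

## Numerical and design choices

* **Filtering.** 4th-order Butterworth band-pass applied forward-backward
  (zero phase) with odd-reflection padding and steady-state initial
  conditions, vectorised over pixels in compiled code. A low cut below the
  record's fundamental frequency (0.0008 Hz on ≤ 20-min records) cannot
  act as a high-pass on that record and is implemented as exact temporal
  mean removal plus the upper-edge low-pass; this is also what keeps the
  filter numerically clean and a rank-k movie exactly rank k after
  preprocessing.
* **Noise estimation for z-scoring.** The per-pixel noise sd is estimated
  from a low quantile of the absolute temporal first differences:
  `sd = Q_q(|Δx|) / (Φ⁻¹((1+q)/2) · g)`, with `g` the rms first-difference
  gain of the noise band (`√2` for broadband input — the classic
  MAD-of-differences constant — and ≈ 0.30 for the 0.08–0.15 Hz band at
  dt = 0.4 s, without which z-scores on band-filtered noise would be ~5×
  too large and z > 5 would fire on ~5% of pure-noise voxels). The default
  quantile 0.25 keeps the estimate robust when oscillatory epochs occupy
  up to ~75% of the record, which is precisely the oscillation-rich state
  of interest; `quantile = 0.5` recovers the textbook MAD estimator. The
  residual inflation of this estimator is ≈ 1/(1 − duty), which is why the
  simulator's trains use bout duty cycles near 25% and why the logged
  ground-truth z is duty-corrected.
* **Centroids and propagation.** Centroids are weighted by the
  above-threshold z excess `(z − 5)⁺`, so the track does not wobble with
  the threshold contour, and the track is smoothed with a 3-frame running
  mean before summing displacements: per-frame peak-position noise
  otherwise accumulates linearly into the propagation sum and biases slow
  or static events across the 5 px travelling criterion. Uniform motion is
  unaffected. The stored track is the one the propagation sum is defined
  on, so an independent recomputation from the track reproduces
  `propagationPx` to 10⁻⁹.
* **Trajectory labelling.** The six pattern names are assigned by an
  explicit rule on the centroid trajectory over the atlas territory
  classes (cortex / hippocampus / other subcortex): cortex↔hippocampus
  trajectories are cortico-/hippocampo-cortical by visit order;
  cortex↔other-subcortex is the single direction-agnostic
  cortico-subcortical class (the taxonomy has no reverse class, so time
  reversal maps it to itself); cortical trajectories crossing the midline
  are trans-hemispheric; remaining cortical trajectories are
  medio-temporal or temporo-medial by whether the distance to the midline
  grows or shrinks (margin 3 px). Because the raised-cosine envelope hides
  the first and last stretch of a trajectory below threshold, the
  territory vote extrapolates the track a short distance (scaled to the
  track length) beyond each end. Events failing the margins stay
  unclassified. k-means clustering of the binarised delay maps is kept as
  the descriptive grouping it is; the rule-based labels are what make the
  taxonomy reproducible.
* **Degenerate inputs.** Zero-variance pixels get a floored noise sd (with
  a warning); on *noise-free* synthetic movies the z-score is
  regularised by an explicit detector noise floor (`minNoiseSd`), because
  otherwise machine-epsilon noise floors make zero-phase filter ringing
  "significant". Label-recovery validation uses `minNoiseSd = 0.5` a.u.,
  ~100× below the injected wave amplitudes. Single-frame events report
  zero propagation and speed with a `degenerate` flag. Empty detection
  results and empty scans are valid and propagate as flagged empty rows.
* **Event splitting.** Merged events with multiple z maxima are *not*
  watershed-split; at the simulator's event rates merges are rare and the
  matched-truth evaluation attributes merged events to the trajectory they
  follow. This is a known simplification of the detector.
* **PCA mechanics.** The eigenvalue problem is solved on the pixel×pixel
  covariance when pixels ≤ stacked frames, and on the stacked time×time
  Gram matrix otherwise (identical non-zero spectrum, eigenvectors
  recovered by back-projection). Eigenvector polarity is fixed by making
  each map's largest-magnitude element positive. Explained fractions are
  over the full eigenvalue sum (= trace), so they total 1 to 10⁻⁹.
* **Artifact screening.** Awake-style records are screened with a robust
  one-sided threshold (median + 5 × 1.4826 MAD, the factor-5 default being
  our choice) and the earliest maximal-length clean window of at least
  120 s is selected.

* **Wave speed.** Each event's `speedMmS` is its propagation distance over
  elapsed time. For slow waves this within-event measure is biased upward:
  the 0.08–0.15 Hz filter's impulse response spans ~14 s, and when the
  bump's transit over its own width takes longer than that, the filtered
  above-threshold blob is smeared along the direction of motion and the
  centroid appears to move at a floor of roughly 0.3 mm/s. The wave-level
  estimator [`waveSpeedFromEvents()`] instead regresses the *mean position
  of successive per-cycle events* on their mean times — the smearing
  pattern repeats every cycle and cancels — and recovers speeds down to
  0.2 mm/s within ~10%. At 0.1 mm/s the per-cycle displacement (≈ 1 mm)
  falls below the filter's space–time resolution (bump sd ≈ smear length
  ≈ 1 mm) and even the wave-level estimate compresses about twofold; the
  strict 20% recovery check is expected to fail honestly on that rung.

## A known limit of the acceptance regime

The in-vivo observation that the inflamed state's first 10 components
explain > 99% of variance implies an oscillation-to-broadband-noise
variance ratio near 100. With the detector calibration above (in-band
noise ≈ 1.1% of baseline so that 10–30% events straddle z = 5), the
broadband per-pixel noise variance is bounded below, and oscillatory
trains that remain detectable (bout duty < 50%) would need peak amplitudes
beyond 100% ΔCBV to reach that ratio on synthetic cohorts. With the
defaults (60% trains) the oscillation-rich arm reaches ≈ 98% at 10
components against < 90% (typically < 30%) for the control arm — the
contrast is reproduced, its extreme in-vivo magnitude is not, and the
corresponding strict check is expected to fail honestly at desk scale.

## Problem sizes used in the checks

Module tests run on 64–96 px grids with 300–900 frames. The acceptance
suite uses 20 scans of 128×128×3000 (the full acquisition geometry) for
detection recovery, 3 scans per arm at 64×64×900 for the PCA and
connectivity contrasts, 200×3000 series for the fALFF null, and an
80×80 six-pattern cohort (10 waves per pattern) for the taxonomy.
`scripts/acceptance.R` recomputes the same quantities from scratch with
4 scans per arm at full scan geometry.
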