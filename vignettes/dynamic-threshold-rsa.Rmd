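---
title: "Personalized dynamic-threshold root segmentation and RSA: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalized dynamic-threshold root segmentation and RSA: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynroot)
```

## The measurement model

`dynroot` measures the root surface area (RSA) of an isolated tooth from
an 8-bit CBCT volume.  The model rests on three observations about such
scans:

* an extracted tooth scanned in air gives a volume whose non-air part
  *is* the tooth, so binarization is a one-dimensional thresholding
  problem on the whole-volume intensity histogram;
* the tooth surface consists of exactly two tissues — cementum on the
  root, enamel on the crown — and enamel is always the brighter of the
  two, so the intensity histogram of *surface* pixels is bimodal;
* because CBCT grey values are not standardized across devices, patients
  or even teeth, the cut between the two surface modes must be found per
  tooth ("personalized"), not fixed globally.

The pipeline (`segment_tooth_roots()`) is therefore: binarize →
3D connected components (one per tooth) → per-slice surface-pixel
extraction → surface histogram → dynamic threshold (P, X) → root/crown
classification → RSA.

### Surface pixels and the area rule

A tooth pixel is a **surface (edge) pixel** when at least one of its 8
neighbours *within the same axial slice* is background; pixels beyond the
volume border count as background, so components touching the border
still have a well-defined surface.  Neighbourhoods never cross slices —
the area rule below is built from per-slice circumferences, and the
in-plane rule keeps the two consistent.

The **RSA rule** converts pixel counts to physical area: in slice $z$
the root circumference is $c_z = n_z \cdot s_{px}$ (root-edge-pixel
count times in-plane pixel size), and

$$\mathrm{RSA} = \sum_z c_z \cdot s_{slice}
             = N_{root} \cdot s_{px} \cdot s_{slice},$$

with both forms computed and cross-checked to $10^{-9}$ relative
tolerance.  At the default 0.3 mm isotropic sampling each root edge pixel
contributes 0.09 mm².  Two properties of this rule are deliberate, not
bugs: diagonal boundaries are under-measured relative to their true arc
length (the rule counts pixels, not geometric contour length), and
axially facing surface — the apex cap and the occlusal table — is never
counted, because only in-plane circumference enters the sum.  On
axis-aligned prisms the rule is exact, which is what the phantom-based
exactness tests exploit.

### The dynamic threshold

Let $h$ be the 256-bin surface-pixel histogram.  The per-tooth threshold
is defined by: $P$ = the first (cementum/root) peak of $h$; $X$ = the
valley of $h$ following $P$, before the enamel/crown peak.  Surface
pixels with intensity $< X$ are root, $\geq X$ crown.

Raw 256-bin histograms of a few thousand surface pixels are noisy, so the
literal "first peak, next minimum" rule is wrapped in a robustness layer
with three numerical choices:

1. **Smoothing.** Counts are smoothed by a centered moving average of odd
   width `smoothing_window` (default 5 bins), reflected at the
   boundaries.  Width 1 disables smoothing.
2. **Peak qualification.** Candidate peaks are plateau-aware local maxima
   of the smoothed curve; a peak qualifies if its topographic prominence
   is at least `min_prominence_fraction` (default 0.05) of the smoothed
   curve's *range* (max − min).  Scaling by the range rather than the
   maximum makes P and X exactly invariant to adding a constant to every
   bin.  A peak sitting on bin 0 or 255 has terrain on one side only, and
   its prominence is measured one-sidedly.
3. **Mode-pair and valley selection.** Among qualifying peaks, the root
   and crown peaks are the pair separated by the *deepest* valley
   (ties broken toward the more prominent pair, then leftward), and $X$
   is the minimum of the smoothed curve strictly between them.  When that
   minimum is attained on a plateau — with well-separated modes the
   valley is a long run of exact zeros — the reported $X$ is the minimal
   bin *closest to the midpoint of the two peaks*: the maximum-margin
   cut.

The third choice deserves its rationale spelled out, because it is where
this implementation deviates from the most literal reading ("the minimum
closest to P", i.e. the left edge of the plateau).  The left edge of a
run of empty bins is an extreme-value statistic of the root mode's upper
tail: its position fluctuates by several bins between noise realizations
and drifts with sample size, while every bin of the plateau is an equally
valid cut (no surface pixel lies there, so the classification — and the
RSA — is identical for all of them).  The midpoint-of-peaks tie-break
picks, among these equivalent cuts, the one most stable under noise; in
the package's own simulations (the threshold-recovery acceptance test:
20 noise realizations at sd 8) it stays within ±3 bins of the analytic
mixture valley, where the plateau-edge rule wanders tens of bins.
Likewise, selecting the mode pair by deepest separating valley (rather
than "first two peaks") prevents a low-prominence noise wiggle on a
mode's flank from masquerading as the crown peak.  On clean bimodal
histograms with a unique interior minimum all of these rules coincide
with the literal ones, and `smoothing_window = 1` with
`min_prominence_fraction = 0` recovers the raw-histogram behaviour.

Degenerate inputs are signalled, not guessed at: a histogram with fewer
than two qualifying peaks (a unimodal surface — e.g. a crownless root
fragment, where there is no enamel/cementum contrast to find) raises a
classed `no-peak` error, and a peak pair with no interior bins raises a
`threshold-failure` error.  The pipeline catches these per component,
records the message, and continues with the remaining teeth; a manual
`x_threshold` override lets such components still be measured.

### Binarization

The air/tooth cut is `intensity > air_threshold`.  When no threshold is
given it is chosen by maximizing the between-class variance of the
whole-volume histogram (Otsu's criterion), with plateau ties resolved to
the plateau midpoint.  Two facts about this choice are worth knowing:

* On a *clean* bimodal volume (air vs. tooth) the criterion is exact,
  and the chosen threshold reproduces the brute-force variance scan —
  this is asserted against an independent oracle in the tests.
* On an air-dominated **trimodal** histogram (air, cementum, enamel)
  with noise, between-class variance places the cut near the midpoint of
  the air mean and the pooled tooth mean.  That can land inside the root
  mode's lower tail, punching pinholes into the root that each spawn
  spurious interior "surface" pixels.  This is a well-known property of
  the criterion, not of this implementation.

For this reason `binarize()` keeps the automatic rule but exposes the
manual override, and the package's own phantom studies use the override
with the phantom's analytic air/tooth midpoint (intensity 50 for the
default air mode 10 / root mode 90): in a phantom study the air level is
known by construction, and the quantity under test is the dynamic
threshold X and the RSA arithmetic, not air segmentation.  On clinical
volumes, where the background is much darker and emptier than a Gaussian
air mode, the automatic rule is the sensible default — but inspecting
the resolved `air_threshold` (logged by the CLI in `config.txt`) is part
of sound practice.

### Connected components

Teeth are 3D connected components of the binary mask under
26-connectivity, the most inclusive standard choice; components smaller
than `min_component_voxels` (default 27 = one 3×3×3 voxel cube, i.e.
about 0.7 mm³ at 0.3 mm sampling) are dropped as noise specks.  The
labelling is delegated to `igraph`'s component machinery over the voxel
adjacency graph and is checked against a flood-fill oracle in the tests.
Thresholds are found independently per component: two teeth in one
volume get two different X values, which is the package's core claim.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `pixel_size_mm`, `slice_spacing_mm` | 0.3 | mm | physical sampling; 0.3 mm isotropic is the geometry the method was developed at |
| `air_threshold` | automatic | intensity bin | air/tooth cut; override for reproducible or phantom runs |
| `smoothing_window` | 5 | bins | moving-average width before peak search; 1 = raw rule |
| `min_prominence_fraction` | 0.05 | fraction of smoothed range | minimum peak prominence to count as a mode |
| `min_component_voxels` | 27 | voxels | speck filter for components |
| `x_threshold` | none | intensity bin | manual per-volume X, bypassing the dynamic rule |

## The phantom generator

`phantom_spec()` / `generate_phantom()` build CBCT-like volumes with
known geometry and analytic ground truth, so every stage is testable
without scan data.  The default is a two-part tooth: a root prism 12 px
across and 20 slices tall under a wider crown prism (root + 4 px, 8
slices), intensity modes air 10 / root 90 / crown 190, inside a 6-voxel
air margin.  These defaults were chosen once, for realism: roots are
longer and narrower than crowns, the scan field of view around an
isolated tooth is overwhelmingly air, and the root/crown boundary is a
pure intensity change with no geometric marking — the CEJ analogue.
Intensity noise is Gaussian per voxel around the region mean, rounded
half-up and clipped to 0–255; a spec is solvable by construction only if
the modes are at least 4 noise SDs apart.  Generation is deterministic
given the spec (the seed is part of it) and leaves the caller's RNG state
untouched.

Truth fields are computed combinatorially from the clean geometry before
noise: the root edge count from the per-slice 8-neighbourhood rule, the
RSA from the pixel-count identity, and the true threshold bin as the
integer minimizer of the two-Gaussian mixture density between the modes
(weights = clean edge counts; midpoint of the modes when noise-free).

What the phantom does *not* emulate — and hence what passing tests do
not show about clinical data: anatomically curved surfaces (prisms make
the pixel-count area rule exact, which is the point for arithmetic
checks, but clinical roots have diagonal and curved boundaries where the
rule under-measures); scanner physics (beam hardening, scatter, spatially
correlated noise); partial-volume blur at tissue boundaries; and
non-Gaussian backgrounds.  Agreement with ground truth on phantoms
validates the algorithmic chain, not the clinical accuracy of the
method, which is what the bundled 24-tooth comparison table speaks to.

## Agreement statistics

`rsa_agreement()` compares two paired measurement methods: per-pair
differences, their mean and sample SD, the paired t statistic with
two-sided p and 95 % CI (t distribution, n − 1 df), and Bland–Altman
limits of agreement, which use the conventional fixed 1.96 multiplier
rather than a t quantile.  Zero-SD differences are reported as a
degenerate flag with `NA` t and p, not as infinities.  The bundled
`rsa_table1()` dataset (24 teeth, dynamic-threshold CBCT vs. manually
segmented optical scan) ships with its originally printed difference and
ratio columns so that the reproduction of those columns is itself
testable.

For reliability, `cronbach_alpha()` implements the variance-ratio form
with sample variances, and `icc_agreement()` computes ICC(2,1) — two-way
random effects, absolute agreement, single measure — from the two-way
ANOVA mean squares, with a consistency-type variant available by
parameter.  ICC(2,1) is the standard choice when raters measure the same
physical quantity and a systematic rater offset should count against
agreement; the consistency form is provided because the difference
between the two (offset sensitivity) is itself informative and is
asserted in the tests.

## Problem sizes and runtime

The test and acceptance problem sizes are package choices balancing
coverage against feedback time: 100 random volumes for fixture
round-trips, 50 random slices for the edge-rule oracle, prism sides 3–20
for noise-free exactness, and 20 noise realizations at sd 8 (the largest
noise the default modes tolerate at the 4-SD solvability margin) for
threshold recovery.  Default phantoms are ~28×28×40 voxels; the full
suite runs in well under a minute on one core.

## Known limitations

* Defined for isolated teeth in air: no separation of touching teeth, no
  root vs. alveolar-bone discrimination in vivo.
* The area rule's diagonal under-measurement and missing axial caps
  (above) bias RSA low on curved anatomy relative to mesh-based surface
  area; this is inherent to the pixel-count definition being measured.
* DICOM support is deliberately minimal: single-frame grayscale,
  uncompressed little-endian transfer syntaxes, one series per directory.
  Volumes stored above 8 bits are min–max rescaled to 0–255 (round half
  up) because the entire threshold machinery is defined on the 0–255
  histogram; the vendor's own windowing, if any, is not reproduced.
* Slices are ordered by spatial position (`ImagePositionPatient`, then
  `SliceLocation`, then `InstanceNumber`), never by filename; missing
  spacing metadata falls back to 0.3 mm with a warning.
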