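---
title: "Models and methods behind synaptoglia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind synaptoglia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(synaptoglia)
```

This vignette is the package's own account of its methods: the
measurement models, the synthetic scenes they are validated against,
the numerical choices, and the limits of what the desk-scale tests can
show about real data.

## The scientific setting

Complement component C4 tags synapses for elimination by microglia
during cortical development. The analyses here quantify that process
and its consequences in mouse mPFC at several levels: colocalization of
postsynaptic material (PSD-95) with microglia (Iba1) and their
lysosomes (CD68) in confocal stacks; nanoscale confirmation in expanded
tissue; dendritic spine density and type; miniature synaptic currents
and passive membrane properties; and social/exploratory behavior from
centroid tracking. None of the raw imaging, recording or video data are
required: a ground-truthed generator emulates each modality with the
statistical structure the analyses assume, so every stage is tested
against a known answer.

## Engulfment scoring and the pixel-shift null

A microglia is represented by its traced mask in a single analysis
z-plane (`MicrogliaCell`). A qualifying engulfed punctum is an
8-connected region of the binarized PSD-95 signal that overlaps both
the binarized CD68 signal and the cell mask, with area at least 3 px.
Engulfment area is the summed qualifying area as a percentage of the
cell mask; a cell is engulfment-positive if at least one punctum
qualifies. The null model translates each stained channel — PSD-95,
CD68 *and* Iba1 — independently by 12 µm along a uniformly drawn
cardinal direction (toroidal wrap, so signal density is conserved; a
crop mode exists behind a flag) and rescores against the unshifted cell
masks. Shifting all three channels matters: with only two shifted, a
lysosome displaced 12 µm frequently still lies inside the same cell's
extended mask, and the null is several-fold higher. We run the shift
repeatedly (default 100 rounds; the tissue analysis used a single
round) to get a distribution rather than a point estimate — a
deliberate deviation for statistical stability.

Depth analysis restricts to engulfment-positive cells at cortical depth
≤ 300 µm (L1 and L2/3) and reports the Pearson correlation and linear
fit of engulfment area against depth. Layer densities use closed-upper
bins (a 120-µm soma belongs to L1). Cells deeper than the last bin are
excluded with a message rather than silently dropped.

### Thresholding

`binarize()` offers fixed, Otsu, percentile and background
(median + k·MAD) thresholds, each recording its provenance in the mask.
The engulfment pipeline defaults to the background method with k = 5.
The reason is structural: PSD-95 and CD68 foreground occupies roughly
0.1–3% of pixels in these scenes, and Otsu's between-class variance is
then maximized by splitting the *noise* distribution, which floods the
mask (we measured 100% null positivity under per-stack Otsu). A robust
background statistic is stable regardless of foreground sparsity.
Condition comparisons should pin one fixed threshold across all images
of a batch (`threshold_psd`/`threshold_cd68`), reproducing the
same-settings constraint under which the original measurements were
made.

## The synthetic engulfment scene

Defaults are the study conditions: a 280 × 350 µm transfected-region
ROI (98,000 µm²) sampled at 0.27 µm/px, 14 microglia per ROI, and an
engulfment rate of 0.30 in the control arm with 0.69 (2.3-fold) as the
overexpression arm. Where the study fixes no value we chose once, on
realism grounds, and did not revisit: 5 z-planes at 0.3 µm (engulfment
scoring is single-plane; five planes provide the ±1-plane context the
ExM rules need), Poisson(3) lysosomes per cell, free PSD-95 puncta at
0.3/µm² of tissue spread across planes, PSF sigma 0.2 µm, Gaussian
noise SD 4 on a background offset of 10. Somata are placed with a
25-µm minimum spacing (microglia tile territories). Lysosomes are
solid organelles: candidate positions must clear existing lysosomes by
a PSF-safe margin, and a Poisson draw that finds no room in the soma is
dropped — a soma holds only as many discrete lysosomes as physically
fit, and without this rule the Gaussian blur bridges adjacent blobs
and the rule-based detector correctly (but unhelpfully) reports the
merged object. Lysosomes that receive an engulfed punctum are drawn
1.5-fold larger in area, reproducing the observed size difference
between PSD-95-positive and -negative lysosomes, and engulfed debris
is sized relative to its host lysosome (45–65% of its radius, strictly
inside): engulfed material is an aggregate, larger than a single
neuropil punctum, and the published ROI-mean positivity rule is only
sensitive when the debris occupies a meaningful fraction of the
lysosome cross-section.

Rendering uses anti-aliased ellipses/capsules/discs evaluated at pixel
centers with a ~1 px linear edge ramp, followed by a separable Gaussian
blur and additive Gaussian noise (shot noise is deliberately omitted:
downstream behavior depends on thresholding, not the noise family).
Object amplitudes (60–80) are set so the default analysis threshold
(≈ 30) sits near the blurred objects' half-maximum. This choice makes
the binarized footprint match the geometric ground truth — the
generator-analysis consistency the tests rely on — rather than
including the PSF skirt, which would both break truth recovery and
inflate chance colocalization.

Voxels are stored `[y, x, z, channel]` (column-major R convention, y
down); all physical quantities derive from `pixel_size_um`/`z_step_um`
metadata, which travel in a YAML sidecar next to the float TIFF pages.

## Expansion microscopy

The per-cell scaling factor is the mean of the long- and short-axis
post/pre ratios of the soma, measured on binarized maximum-intensity
projections via PCA extents. Lengths divide by the factor and areas by
its square. The generator renders the *same* drawn scene twice — once
at 0.27 µm/px, once with all physical coordinates multiplied by the
expansion factor at 0.155 µm/px — keeping the optical PSF fixed in
physical units, which is exactly why expansion reveals substructure.
The ExM default field is 70 × 70 µm with two microglia: expanded
full-size ROIs would be impractically large, and expanded cells are
imaged a cell or two at a time anyway.

Lysosome detection applies the published rule set: candidate CD68
voxels ≥ 2× the local background (median CD68 within the cell
footprint), grouped in 3-D with 26-connectivity so that a component
spanning adjacent planes satisfies the two-consecutive-z-planes
requirement; at the brightest plane (argmax of mean ROI intensity — the
deterministic stand-in for the original slope-based plane call) the
region must cover ≥ 9 px (0.216 µm² expanded; configurable 7–9). PSD-95
positivity requires (a) ROI mean ≥ annulus mean + 2 annulus SD, (b) a
≥ 4 px (0.0961 µm²) PSD region at ≥ 2× background inside the ROI, and
(c) PSD and CD68 z-profiles peaking within one plane. The annulus is a
band of width twice the ROI-equivalent radius around the ROI, excluding
every detected lysosome — the published description names a
"surrounding region" without geometry, so the band width is our
design choice, exposed as code.

## Spines and TIB

TIB is the mean gray value of the spine ROI at its brightest focal
plane (argmax over z of ROI mean intensity) divided by the adjacent
shaft mean at the same plane — invariant to illumination scale and
monotone in spine-head volume, since GFP brightness is
volume-proportional. Classification cuts the control-condition
reference TIB distribution at its 25th/75th percentiles (linear
interpolation between order statistics; stable for reference sizes of
a few dozen), with boundaries assigned to the medium class. Whether
the reference is pooled or per-analysis is configurable; per-analysis
is the default. The inclusion rule re-checks that any candidate ROI
protrudes ≥ 3 px beyond the shaft (Euclidean distance to the shaft
mask); manual spine identification is out of scope, so ROIs come from
annotation tables or generator truth.

The spine generator draws head volumes from a tri-modal mixture
(thin/medium/mushroom at 25/50/25 weight, component means
0.06/0.20/0.55 µm³, ~25% CV) and renders protrusions with amplitude
proportional to volume on 50–80 µm shafts at 0.12 µm/px. Its truth
classes are the volume quantiles of the drawn sample under the same
25/75 convention, so classifier agreement is measured against a
like-for-like definition.

## Electrophysiology

Detection is Clements–Bekkers: a unit-peak difference-of-exponentials
template (defaults 0.5/5 ms; IPSC-like 1/10 ms is a config choice, not
a claim about the original settings) is slid across the trace, at each
offset optimally scaled and offset in closed form, and the criterion is
scale divided by the residual standard error √(SSE/(N−1)); the default
threshold is 3.5. Above-threshold runs reduce to local criterion
maxima, maxima within one rise-to-peak merge to the larger, and
residual duplicates (criterion re-firing on the decay) deduplicate at
the peak level. Amplitude is measured against the median of the 10 ms
before onset, with the peak read from a 0.25-ms boxcar-smoothed copy —
the raw argmax rides the noise maximum and overestimates amplitudes by
roughly half the noise SD times the selection factor. Decay τ comes
from a Levenberg–Marquardt single-exponential fit; non-convergent or
edge-truncated events are flagged and excluded from τ statistics.

Passive properties invert the seal-test circuit: Rs = dV/I_peak,
R_total = dV/I_ss, Rm = R_total − Rs, Cm = τ/(Rs∥Rm). The transient
peak is *extrapolated to the step onset* from the exponential fit;
reading the first sample instead clips the transient by up to several
percent at 10 kHz when τ ≈ 1 ms. Rheobase is the smallest step of a
300-ms family (from −200 pA, 10–15 pA increments) eliciting an AP,
where an AP is an upward 0 mV crossing with ≥ 2 mV/ms preceding slope —
the AP definition is ours, chosen for robustness on simulated traces.
The published Rs-drift exclusion (>20%) is acquisition metadata, not a
pipeline step. Trace I/O uses a CSV interchange with fs/mode header
lines.

## Behavior

Zone geometry defaults (cup discs of 10 cm radius, 15 × 15 cm corner
squares in the examples) are configuration values — the original zone
extents are not published — and comparisons are only meaningful with
identical configs across groups. A frame is in a zone if the centroid
is inside, boundaries inclusive (the in-package point-in-polygon exists
precisely to pin that boundary convention). DI is
(t_target − t_other)/(t_target + t_other); latency is first-entry
time; velocities come from centered differences on a 5-frame boxcar
path (raw tracking jitter otherwise inflates maxima). The trajectory
generator is a Metropolis random walk with reflecting walls whose
stationary density is proportional to the zone preference weights, so
uniform weights give uniform occupancy — the property the symmetric
chain tests exploit; `lock_zone` emulates an absorbing preference for
the DI = 1 bound. Group hypothesis tests (Welch, Fisher, KS) are
delegated to base R.

Bregma interpolation completes every-other-section counts linearly
against coordinate and refuses to extrapolate outside the counted
range.

## Morphometry and expression

Sholl crossings are computed analytically per internode segment, with
segments split at their closest approach to the soma so re-entrant
branches count each crossing separately — the convention of the
ImageJ-style dense-sampling definition, against which a 0.1-µm
sampling oracle validates the implementation on random trees. Branch
order starts at 1 at the soma and increments after each branch point.
Soma diameter is the mask extent along the perpendicular to a supplied
apical axis through the centroid. ΔΔCt normalization combines the
three reference genes by the arithmetic mean of their Ct values
(equivalently the geometric mean of their expression); an
expression-mean alternative sits behind a flag because the original
combination rule is unstated.

## Problem sizes and what the tests show

The validation cohorts are desk-scale by design: 26 ROIs per arm for
the engulfment ratio and pixel-shift bound (2 shift rounds per ROI in
the tests, 10 in the acceptance script), 4 ExM pairs (8 cells) for the
2.8× factor, 400 protrusions for TIB classification, 60–120 s traces
for detection metrics, 50 random trees for Sholl, and 40 trajectories
for first-choice balance. Passing them shows the estimators recover
known parameters under the generators' assumptions — isotropic
Gaussian PSF, additive Gaussian noise, simplified soma-plus-straight-
process morphology, stationary Poisson event trains, memoryless random
walks. They do not certify performance under real-tissue conditions:
anisotropic PSFs, autofluorescence and shot noise, ramified microglia,
correlated event trains, or systematic tracking artifacts. The
measurement definitions, unit conversions and rule sets, however, are
exactly those applied to real data, which is what the package is for.
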