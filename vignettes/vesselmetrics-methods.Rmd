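---
title: "Zone-wise vessel morphometry on en-face OCTA label maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zone-wise vessel morphometry on en-face OCTA label maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmetrics)
```

## The problem

Optical coherence tomography angiography (OCTA) produces en-face maps of
retinal blood flow. After a segmentation model labels each pixel of a
3×3 mm macular scan as artery, vein, arteriovenous junction, or
background, the clinical questions are quantitative: how dense are the
vessels in each macular zone, how thick are they, how long, how
geometrically complex, how tortuous — and do those numbers differ
between patient groups (e.g. healthy controls, diabetics without
retinopathy, and eyes with non-proliferative retinopathy)?

`vesselmetrics` implements that measurement pipeline end to end:

1. a **zone partition** of the field into the fovea (0.5 mm radius disk)
   and the parafoveal annulus (0.5–1.5 mm) split into four 90° quadrants
   (superior, inferior, nasal, temporal);
2. **skeletonization** of vessel masks and decomposition of the skeleton
   into ordered centerline **tracks**;
3. the **metric family** per zone × vessel class: vessel density (VD),
   vessel diameter index (VDI), vessel length fraction (VLF),
   box-counting fractal dimension (FD), and the tortuosity family —
   mean direction angle change (MDAC), curve length (LC), and total
   squared curvature (TSC) normalized by chord (TSC-LX) or arc length
   (TSC-LC);
4. the **group-comparison protocol**: a Kolmogorov–Smirnov normality
   gate routing to one-way ANOVA (with a Levene gate choosing LSD or
   Tamhane T2 post hoc pairs) or to Kruskal–Wallis, plus chi-square
   tests for count data, all two-tailed at α = 0.05;
5. a **vessel-phantom generator** that replaces patient images with
   parametric curves of analytically known geometry, so every estimator
   can be validated against exact ground truth and the full pipeline can
   be exercised on cohorts with known injected effects.

Patient images from the motivating study design are not redistributable,
so the phantom generator is a first-class component, not a test fixture:
it defines the conditions under which every quantitative claim about the
pipeline is demonstrated.

## Metric definitions

With `V` the vessel pixels, `S` the skeleton pixels and `N` the pixels
of a zone:

* `VD = ΣV / N` — the fraction of the zone covered by vessels;
* `VDI = ΣV / ΣS` — mean vessel caliber in pixels (also reported in µm,
  `VDI_px × pitch × 1000`);
* `VLF = ΣS / N` — normalized total vessel length. (In some published
  formula listings this ratio appears under the label "VDI"; the formula
  ΣS/N is the length fraction and is implemented here as VLF.)

For an ordered centerline track `P_1 … P_n`:

* `LC = Σ |P_i − P_{i+1}|` (arc length), `LX = |P_n − P_1|` (chord);
* the curvature `C(t) = (x′y″ − y′x″) / (x′² + y′²)^{3/2}`;
* `TSC = ∫ C(t)² ds`, with `TSC-LC = TSC/LC` and `TSC-LX = TSC/LX`
  (undefined for closed tracks, where LX → 0);
* `MDAC` averages the turning angle between the unit vectors
  `UV(P_{n−step}, P_n)` and `UV(P_n, P_{n+step})` over the track, with
  the arccos argument clamped to [−1, 1]; tracks shorter than
  `2·step + 1` points are excluded.

FD is the box-counting dimension of the skeleton: occupied-box counts
over the dyadic ladder ε = 2, 4, 8, … up to a quarter of the image side,
grid anchored at the zone bounding box (or the occupied bounding box for
whole-image calls — a misaligned anchor inflates the large-box counts
and biases the slope down), with the slope fit by ordinary least squares
over scales with `N(ε) ≥ 2`.

## Estimating tortuosity on pixel tracks

The definitional formulas assume a differentiable curve; an 8-connected
pixel chain is anything but. Three distinct numerical problems arise,
and the package treats them separately.

**Arc length.** The raw pixel-chain polyline overestimates the length of
a smooth curve by up to ~10% (staircase steps of 1 and √2 px). Zone
records therefore report LC measured on the Gaussian-smoothed centerline
(σ = 2 points), which recovers semicircle arc lengths within ~6% at the
tightest radius tested (0.25 mm at ~10 µm/px) and within 2% above it.
`curve_length()` itself stays definitional (it is also the oracle-tested
primitive).

**Pointwise curvature.** `curvature_profile()` smooths the coordinates
with a Gaussian (σ = 2 points) and applies central differences — on
cleanly sampled curves this recovers circle curvature to well under 5%
away from the endpoints. But **squared** curvature integrated along a
quantized track inherits the *variance* of the digitization noise as a
positive bias: at 10 µm/px the naive Σ C²Δs overestimates TSC of a
gently curved vessel severalfold.

**Total squared curvature.** The zone records therefore use a denoised
estimator (`total_squared_curvature(..., method = "denoised")`): two
curvature estimates computed at different central-difference steps
(5 and 9 points), each corrected for the closed-form finite-step circle
bias (`κ̂ = κ·sinc(z/2)²/sinc(z)²`, `z = h·Δs·κ`), locally averaged over
a 31-point window and then *multiplied*. Because the two estimates carry
largely independent digitization noise, the noise term cancels in
expectation instead of accumulating in the square. On rasterized
semicircle phantoms with radii 0.25–1.0 mm this recovers TSC-LC = 1/r²
within 5% in every tested orientation; straight vessels return exactly
zero. The parameters (steps 5/9, window 31) were calibrated once against
the analytic circle truth across that radius range and are exposed in
`metric_config()`.

**MDAC** is computed on Gaussian-smoothed coordinates with a slightly
wider kernel (σ = 3 points, `mdac_sigma`): the mean *absolute* turning
angle is noise-dominated on nearly straight tracks, and the wider kernel
brings the recovery error on semicircles under ~5% at every radius
(versus ~10% at σ = 2). The MDAC index step default is 5 points — at
~10 µm/px this probes direction changes over ~50 µm of vessel, a
reasonable compromise between angular noise and locality.

These choices favor estimator accuracy over literal application of the
continuous formulas to raw pixel chains; the raw-formula variants remain
available (`sigma = 0`, `method = "profile"`) and are the ones checked
against brute-force oracles.

## The zone partition

Distances are measured from pixel centers; the fovea is the half-open
disk `d < 0.5 mm` and the annulus `0.5 ≤ d < 1.5 mm`, so the zones are
disjoint and cover the field exactly. Quadrants are split on the 45°
diagonals (sectors centered on the up/down/left/right axes, the standard
parafoveal display convention); a pixel whose angle falls exactly on a
boundary joins the clockwise sector, deterministically. Row 1 is the
superior edge; the nasal quadrant is image-right for a left eye (OS) and
image-left for a right eye (OD). The fovea center defaults to the image
center (where the phantoms place it) and is configurable. Whether a
device splits quadrants on the diagonals or on the axes is not always
documented; `quadrant_split = "axis"` provides the alternative.

## Skeletons and tracks

Masks are thinned with the Zhang–Suen topology-preserving algorithm
(8-connectivity); the skeleton is a subset of the mask and thinning is
idempotent. Thinned skeletons contain staircase patterns in which a
diagonal neighbor is also reachable through an orthogonal pixel; raw
8-neighbor degrees would read these as spurious junctions, so the graph
uses *reduced adjacency* — a diagonal link is ignored whenever an
orthogonal skeleton pixel bridges the pair. Nodes are pixels of reduced
degree ≠ 2; edges are the simple paths between them, and every skeleton
pixel belongs to exactly one edge interior or is a node. Pure cycles are
cut at their lexicographically smallest pixel and flagged; their
chord-normalized tortuosity is undefined. Tracks inherit a vessel class
by majority vote of their pixels' labels (junction pixels vote for
neither; ties fall to the first non-junction pixel) and a zone by
majority pixel membership (ties to the first point). Tortuosity is
computed per edge; thinning erodes roughly half a vessel width at each
open end, which is visible as a small negative bias in track lengths.

Junction pixels (green in the label maps) are excluded from single-class
artery/vein masks — they cannot be attributed without double counting —
and included in the "all vessels" class; `include_junction_in_class`
flips that choice.

## The phantom generator

`cohort_spec()` + `generate_cohort()` emulate a three-group study on
304×304 px, 3×3 mm scans (the en-face grid of a common commercial
device; both are configurable). Each eye is built from:

* five concentric *lanes* per parafoveal quadrant — gently wavy
  arc-chord chains (sinusoid segments with phase chained across
  segments), alternating artery/vein, at radii 0.65–1.35 mm;
* two parallel chords through the fovea (one artery, one vein);
* one artery and one vein radial *crosser*, which intersect
  opposite-class lanes and generate arteriovenous junctions.

Per-zone, per-class target densities are converted to curve length
through the ribbon geometry (`painted ≈ length × width + π(w/2)²` end
caps), inflated to survive pixel dropout; realized zone densities land
within a few percent of target. Defaults: all-vessel density 0.12 in
each quadrant and 0.04 in the fovea (large/medium vessels only — the
capillary bed is deliberately absent), caliber 50 µm, sinusoid amplitude
20 µm at 2 cycles/mm, dropout 0.02, and a between-eye coefficient of
variation of 0.10 on each density target, so the within-group SD of a
zone density is ≈ 10% of its mean — the scale of between-eye variability
reported for OCTA densities. Group effects are injected as absolute
density offsets (optionally class- and zone-specific) and amplitude
offsets for tortuosity. All randomness flows from the single integer
seed; identical specs yield byte-identical cohorts.

What the phantoms deliberately do **not** model: capillary-plexus
texture, OCTA decorrelation/speckle noise, vascular branching topology,
projection artifacts. Passing tests on phantoms therefore demonstrate
the *estimators and the protocol*, not robustness to real-device
artifacts: the generator validates that the pipeline measures what it
claims to measure on geometry whose truth is known.

## The statistical protocol

Per metric × zone × class cell, with missing values dropped cell-wise:

1. normality per group by the one-sample Kolmogorov–Smirnov test against
   a normal with estimated parameters. Estimated parameters require the
   Lilliefors correction, which is the default; the uncorrected K-S
   (`normality = "ks"`) is offered because statistics packages commonly
   default to it and fidelity comparisons may need it;
2. if all groups pass (p > α): one-way ANOVA. With ≥ 3 groups, Levene's
   test on mean-centered absolute deviations gates the post hoc: LSD
   (pairwise t with the pooled within-group mean square, df = N − k,
   unadjusted) when variances are homogeneous, Tamhane T2 (pairwise
   Welch t with a Šidák-style `1−(1−p)^m` adjustment) otherwise;
3. if any group fails normality: Kruskal–Wallis with tie correction.

No multiple-testing correction is applied across cells by default (the
zone-wise reporting convention in this literature uses raw p-values); a
Benjamini–Hochberg option (`mtc = "BH"`) is provided. Eyes are treated
as independent observations, as is conventional in these studies even
when both eyes of a subject are included; that is a fidelity choice, not
an endorsement — inter-eye correlation is a known limitation.

On null phantom cohorts (3 × 10 eyes, no injected effect) the protocol's
empirical false-positive rate for a fixed cell over 500 simulated
cohorts lies within [0.03, 0.08] at nominal α = 0.05, and an injected
arterial density deficit of 3 between-eye SDs in one zone is recovered
with power > 0.9 — both recomputed by the test suite and by
`scripts/acceptance.R`.

Count data (sex, laterality) use Pearson chi-square without continuity
correction. Published demographic tables in this field typically report
eye counts in headers while sex percentages resolve to person counts;
`baseline_statistics()` follows that convention — person counts for the
continuous variables and sex, eye counts for laterality — which is
exactly how the bundled worked-example tables reconstruct to their
printed p-values (0.12, 0.424, 0.955, 0.002, 0.105, 0.534, 0.954).

## Problem sizes and numerical choices

The Monte-Carlo suites use 500 null cohorts and 60 effect cohorts of
3 × 10 eyes at the full 304×304 default resolution, with the
density-only metric configuration (`metrics = "density"`) — the quantity
under test is the VD protocol, and skipping skeletons keeps the
simulation inside a desk-scale run. Oracle-equivalence sweeps use 50
random phantoms at 160×160 px. Degenerate inputs are never silent:
empty zones, empty skeletons, constant samples, closed tracks and
all-tied ranks each return flagged `NA`s or errors, and undefined
metrics propagate as missing values into the statistics (pairwise
deletion), never as zeros.

## Known limitations

* Tortuosity is only as good as the segmentation: a model that captures
  only large and medium vessels excludes the capillaries that dominate
  microvascular tortuosity changes.
* The TSC estimator's cross-product construction can return slightly
  negative integrals on nearly straight tracks before clamping at zero;
  its calibration target was constant-curvature geometry, and strongly
  varying curvature at scales below the 31-point averaging window is
  smeared (ordering across conditions is preserved in the regimes
  tested; see the amplitude-monotonicity test).
* MDAC saturates geometrically: beyond amplitude × frequency products
  where vessels turn faster than the step window resolves, the true
  pixel-scale MDAC itself is non-monotone in amplitude.
* Eyes are treated as independent; no covariate adjustment is offered.
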