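---
title: "Quantifying mesoglea biogenesis and aboral-valve function: models and methods"
author: "mesoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mesoglea biogenesis and aboral-valve function: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoquant)
```

## The measurement problem

During the larva-to-polyp transition of the sea anemone *Nematostella
vectensis*, the body column elongates under muscular hydraulics while the
mesoglea — the thin extracellular-matrix layer sandwiched between ectoderm
and endoderm — is assembled and remodelled. Four quantitative readouts
characterise this process in fluorescence microscopy data:

1. **Body-column morphometrics**: length $l$ (parallel to the oral–aboral
   axis), width $w$ (perpendicular), aspect ratio $AR = l/w$ as a proxy for
   developmental progress, and a body volume estimate; tracked over time
   these form a *morphospace trajectory* (volume vs. shape), on which
   abrupt aboral *leakage* events appear as sudden volume drops.
2. **Mesoglea thickness and amount**: the collagen-IV (or laminin) band is
   traced with a polyline, the image is *straightened* into
   (axial position $s$, signed transverse offset $d$) coordinates, and the
   full width at half maximum (FWHM) of the transverse intensity peak
   defines the local thickness; the signal inside the FWHM window defines
   the local matrix amount.
3. **Photoconverted-patch elongation**: a patch of area $A$ with skeleton
   length $l$ has empirical width $w = A/l$ and elongation index
   $AR_{patch} = l/w = l^2/A$, reporting tissue rearrangement.
4. **Aboral-pole profiles**: intensity along a line across the aboral pore,
   pore-centred (position 0 at the pore), from which the width and depth of
   the collagen-IV depletion zone (the prospective valve) are estimated;
   pErk wound-response profiles run 0–50 µm outside-in.

The package implements all four, plus a synthetic-scene generator that
renders each structure with known ground truth so that every estimator has
a parameter-recovery test, and a Wilcoxon rank-sum comparison for treated
vs. control groups.

## Coordinate and calibration conventions

All analysis operates in physical units (µm). Pixel centres sit at integer
indices; the physical coordinate of pixel $[r, c]$ is
$((c-1)\,p, (r-1)\,p)$ with $p$ the isotropic pixel size. Anisotropic
calibrations are rejected rather than silently averaged. Intensities are
arbitrary units; no background subtraction is applied except where an
operation defines one explicitly. Resampling a scene at a different pixel
size leaves every µm-denominated output invariant within interpolation
tolerance (≲ 2 %; covered by a test).

In a straightened map, positive $d$ is to the left of the polyline's
direction of travel; the caller orients the polyline so the endoderm lies
on the positive side (scenes generated by the package do this
automatically). Missing samples at image borders are `NA`, never
zero-filled — zero-filling would bias the FWHM baseline.

## The FWHM thickness estimator

For a transverse profile $I(d)$:

* the **baseline** is the mean of the outer 10 % of samples on each side —
  robust to tissue autofluorescence shoulders;
* the **peak** is the maximum of $I - \text{baseline}$, required to be
  interior and to exceed 5× the standard deviation of the edge samples
  (profiles indistinguishable from baseline noise are rejected rather than
  yielding a spurious width);
* the half-maximum crossings nearest the peak on each flank are located by
  linear interpolation; the **width** is their distance.

The construction makes the estimate exactly invariant to affine intensity
transforms (gain and offset). On a noise-free Gaussian of σ = 1 µm it
returns $2\sqrt{2\ln 2} \approx 2.355$ µm within 1 %; on a symmetric
triangle it is exact.

One bias is worth knowing about. When the band sits on *unequal* flanking
backgrounds (ectoderm intensity $t$, endoderm $t\,e$), the intensity step
$\Delta = t(e-1)$ under the peak shifts the two half crossings
asymmetrically (to Gaussian fractions $0.5 - \Delta/4A$ and
$0.5 + 3\Delta/4A$ of the peak amplitude $A$), giving roughly a −7 % width
bias at $\Delta/A = 0.2$ and −2 % at $\Delta/A = 0.05$. In practice the
basement-membrane band is much brighter than the residual tissue signal,
so the effect is small; the generator's default intensities (peak 200,
tissue 10, endoderm excess 2) reflect that regime, and the closed-form
analysis above quantifies what happens outside it.

Per-column thickness uses a default bin of 5 axial samples to stabilise
noisy flank crossings; undefined positions are excluded and counted. The
local matrix *amount* is reported both as the sum and as the mean of
baseline-subtracted intensity inside the FWHM window, since either reading
of "intensity" is defensible; users pick one and stay consistent.

## Straightening

The polyline is arc-length parameterised; the image is resampled by
bilinear interpolation at $p(s) + d\,n(s)$ with $n$ the unit normal of the
containing segment. Axial position is rescaled to $[0,1]$. For a straight,
grid-aligned polyline sampled at the pixel pitch this reduces exactly to
the axis-aligned crop (tested to machine precision), and on a concentric
ring image traced with a semicircular polyline the per-position transverse
profiles agree along the arc within 3 %, while total band intensity is
conserved within 5 % for curvature radii ≳ 5× the half-width. Sharper
curvature compresses/stretches the outer/inner band and is outside the
estimator's validity; body-column mesoglea curvature is far milder.

## Body shape, volume, and leakage events

**Bounding box.** The oral–aboral direction is taken as the principal axis
of the mask's second-order moments, and $l, w$ are the extents of the
axis-aligned minimal rectangle (pixel footprints included). This reading —
rather than the image-axis-aligned pixel box — follows from $l$ being
defined *parallel to the body axis*. The moment axis agrees with an
exhaustive rotating-calipers search within 2 % on test shapes. Tentacle
exclusion is the caller's responsibility: masks must be body-column-only.

**Volume.** No volume procedure is uniquely implied by 2-D cross sections;
the package uses a solid of revolution about the principal axis, justified
by the radial symmetry of the body plan: per axial slice of thickness
$\Delta s$ (one pixel), the transverse half-extent $r(s)$ gives
$V = \sum \pi r(s)^2 \Delta s$. Cylinders and spheres are recovered within
3 %, and uniform rescaling by $s$ scales the estimate exactly as $s^3$.

**Leakage onset.** The volume trace is smoothed with a rolling median
(default window 5; raw values are always retained) and an event is
declared at the first frame whose smoothed volume is at least 10 % (the
default `dropThreshold`) below the maximum of the preceding 3 frames
(`window`). Detection re-arms after a new running maximum, so one
sustained drop yields one event. Both knobs are exposed; the defaults
detect 15 % drops at 1 % multiplicative noise with ≥ 95 % power and no
false positives on monotone traces (50 + 50 simulated trajectories in the
test suite). The aspect ratio at the onset frame is reported with each
event, supporting onset-vs-AR comparisons across treatments.

## Patch elongation

$A$ is the foreground pixel count times pixel area. The skeleton comes
from Zhang–Suen morphological thinning (implemented in the package; no
installed dependency provides 2-D thinning), and $l$ is the longest
geodesic path through the skeleton's 8-connected graph — which inherently
discards short side spurs. Two numerical refinements matter:

* Raw $\{1, \sqrt 2\}$ chain weights overestimate oblique digital curves
  by the classical staircase factor (up to ≈ 8 %); path length is
  therefore measured with the Vossepoel–Smeulders chain-code estimator
  $0.980\,N_e + 1.406\,N_o - 0.091\,N_c$, accurate to ≈ 1 % for straight
  digital lines at any orientation.
* Thinning retracts skeleton endpoints away from the true medial-axis
  tips (by roughly a sixth of the local width per end). Each path end is
  extended along its local direction to the mask boundary minus the local
  half-width from the Euclidean distance map, which reconstructs the
  retracted portion exactly for elongated patches.

With both corrections, stadium-shaped patches with $L/W \in \{2, 5, 10\}$
recover the analytic medial-axis elongation $(L-W)^2/A$ within 5 % across
orientations. Near-circular patches collapse the skeleton towards a point;
they are reported with $AR_{patch} < 1$ and a degenerate-skeleton warning
rather than an error. Whether a patch "inverted" during elongation has no
automatic criterion; inversion is caller-declared and implemented as the
reciprocal $AR_{patch} \mapsto 1/AR_{patch}$, an exact involution.
Multi-component masks are rejected rather than merged, since patches are
photoconverted individually.

## Aboral profiles and the depletion zone

"Rescaled, with 0 denoting the pore" is read as a *translation* of the
position axis (pore-centring): the profiled window has a fixed physical
length (default 100 µm), which makes translation the only consistent
reading; `normalize = TRUE` offers division by the ROI length as the
alternative. The depletion estimator mirrors the FWHM convention: flank
level = mean of the outer 20 % of samples per side, depth
$= 1 - \min/\text{flank}$, width = distance between the two crossings of
the half-depth level (full width at half depth). Width is invariant to
intensity gain *and* offset; depth to gain. Flat profiles (depth below a
configurable noise floor, default 0.05) raise a no-dip error. Pore
localisation is caller-supplied; automatic pore detection is out of scope.

Multi-animal ensembles are aligned by linear interpolation onto the
overlap of their position grids; the per-position mean and standard
deviation (denominator $n-1$; 0 when $n = 1$) support mean ± SD band
plots. The pErk profile is the same machinery specialised to a 0–50 µm
outside-in span with a 5 µm averaging width.

## Group comparison

Treated-vs-control comparisons use the two-sided Wilcoxon rank-sum
(Mann–Whitney) test. For pooled sizes ≤ 12 the null distribution of $U$ is
enumerated over all $\binom{n}{n_a}$ assignments of the pooled observed
values — exact under ties — with the two-sided p the doubled smaller tail
(including the observed value), capped at 1. Larger samples use the
tie-corrected normal approximation with continuity correction; it tracks a
$10^5$-permutation estimate within a few per cent for moderate p-values
(the regime where one relies on it), but like any normal approximation it
is relatively poor in the far tails — for p ≲ 0.01 at these sample sizes
expect relative errors of tens of per cent, and prefer the exact path or a
permutation test when the decision hinges on a tail p-value.

## The synthetic-scene generator

The generator renders what the estimators measure, with analytic truth:

* **Body scenes** — an elliptical body column (defaults: length 100 µm,
  width 50 µm — larva-like AR 2 — at 0.1 µm/px) with a Gaussian mesoglea
  ridge along the major axis whose transverse σ is
  $T/(2\sqrt{2 \ln 2})$, so the band FWHM equals the nominal thickness
  $T$ (default 2 µm) *by construction*; ectoderm and endoderm tissue bands
  (endoderm brighter by the `endodermExcess` factor, default 2) flank the
  ridge, and a uniform cytoskeletal counterstain channel (`fActin`)
  provides the segmentation target. Truth records AR, the spheroid volume
  $\tfrac{4}{3}\pi\,\tfrac{l}{2}(\tfrac{w}{2})^2$, and the midline
  polyline.
* **Aboral scenes** — a horizontal band on zero background with a
  Gaussian-shaped multiplicative dip at the pore (depth 0.6, full width at
  half depth 5 µm by default) in the ColIV channel and a co-located 50 %
  band thickening in the Laminin channel. The band is background-free
  because the profile runs along the basement membrane itself, where its
  signal dominates; this also makes depth recovery exact (a depth-1 dip
  sends the profile to zero).
* **Patch scenes** — stadium-shaped masks (default 50 × 10 µm at 30°; the
  oblique default is the generic orientation — grid-aligned boundaries are
  the degenerate special case). The boundary is 4×4 supersampled and the
  stadium centred half a pixel off the grid so the discretised area is
  unbiased. Truth records the stadium area $LW - (4-\pi)(W/2)^2$, the
  medial-axis length $L - W$, and the implied $AR_{patch}$.
* **Trajectories** — AR interpolating linearly (defaults 1.5 → 8,
  spanning the larva-to-polyp range), volume growing geometrically
  (0.5 %/frame over 100 frames at 5 min/frame) until the optional leakage
  frame, where it drops by `leakageFraction` and stays reduced — growth is
  arrested by the event, matching the developmental arrest and regression
  that follow aboral leakage, and making the frame-to-frame ratio at the
  event exactly $1 - \text{fraction}$ in the noise-free case.

Noise models: additive Gaussian truncated at zero for images (as in a
photon detector; the truncation is negligible where signal is present),
mean-one multiplicative log-normal for volume traces. Identical
(config, seed) pairs give bit-identical output.

**What the generator does not emulate**: real optical blur (structures are
rendered analytically sharp), intracellular puncta, tissue
autofluorescence texture, mesenteric segment structure, tentacles,
photobleaching, or drift. Passing parameter-recovery tests therefore
demonstrates correctness of the estimators under the stated geometric and
noise models — not robustness to every artefact of real microscopy, where
ROI tracing quality and segmentation curation still matter.

## Ambiguities resolved as user-facing options

* The axial origin convention is contradictory between figure legend
  (0 = oral) and methods (0 = aboral) in the source protocol; the package
  does not guess: `axialIntensityProfile(..., origin = "aboral")` is the
  default, `"oral"` flips the axis.
* The mesoglea "intensity" summary (sum vs. mean within the FWHM window)
  is emitted in both forms.
* Patch inversion is a caller-declared flag; no automatic trigger exists.

## Problem sizes and test design

The test suite builds every fixture in code: body scenes of 60 × 30 µm at
0.1 µm/px for thickness recovery (T ∈ {1, 2, 4} µm; 20 noisy seeds at 5 %
of peak), 50 + 50 simulated trajectories of 100 frames for leakage power
and specificity, stadium patches at 0.2 µm/px, aboral scenes of
120 × 40 µm at 0.1 µm/px (20 noisy seeds), rotated-ellipse and disk masks
for the bounding-box and volume oracles, and full enumeration vs. an
independent implementation for the Wilcoxon exact path. These sizes were
chosen so that each property is resolved well inside its tolerance while
the whole suite stays fast enough to run on every change. The
`scripts/acceptance.R` script recomputes the same headline quantities from
scratch against the installed package.

## Known limitations

* Straightening assumes mild curvature (radius ≳ 5× half-width) and a
  simple, non-self-intersecting polyline.
* The volume model assumes radial symmetry about a single straight
  principal axis; strongly bent columns violate it.
* The leakage detector is a threshold rule on a smoothed trace, not a
  changepoint model; drops slower than the detection window or smaller
  than the threshold are missed by design.
* Skeleton length for patches narrower than ~5 px is unreliable
  (thinning artefacts dominate); work at sufficient magnification.
* 3-D stacks are only supported plane-by-plane; maximum-intensity
  projections are the caller's input.
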