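---
title: "Crypt morphometrics from en-face SHG imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crypt morphometrics from en-face SHG imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptscape)
```

# The measurement problem

Second-harmonic generation (SHG) microscopy images fibrillar collagen
label-free: in an en-face view of colon mucosa the collagen appears as a
bright honeycomb and the crypt lumens as dark holes. Inflammation-driven
fibrosis remodels this pattern — walls thicken, crypts become fewer,
larger and more widely spaced — so the geometry of the lumen mosaic is
itself a quantitative readout of fibrosis. `cryptscape` turns a projected
SHG field into that readout: a labeled crypt map, per-crypt morphometrics,
and per-image summaries suitable for per-animal aggregation, plus the
companion analyses used alongside such imaging (collagen-covered area,
matrisome set overlap, simple cohort statistics).

All thresholds with physical meaning are expressed in micrometers, which
is why every image carries an explicit pixel size and why a missing pixel
size is an error, never a silent default: a wrong pixel size would corrupt
every downstream number at once.

# Segmentation

The pipeline is: maximum-intensity projection of the stack → per-pixel
crypt-class probability → hysteresis thresholding → hole filling and a
physical size filter.

**Pixel classification.** The probability step is a two-stage logistic
linear model over a fixed feature bank: raw intensity and, per Gaussian
scale $\sigma \in \{1, 2, 4\}$ px, smoothed intensity, gradient magnitude
of the smoothed image, and local variance. The second stage is an
*autocontext* refit: Gaussian-smoothed stage-1 probabilities are appended
as extra features, letting spatial context overrule local texture. This
is a deterministic, dependency-light stand-in for an interactively
trained classifier; users with their own classifier can inject any
probability TIFF through `read_probability_map()` instead. Filters use
reflective boundary handling. One consequence worth knowing: within
roughly one feature scale of the image frame, reflection mirrors nearby
lumens, so a one-pixel wall strip between a lumen and the frame can be
absorbed into the crypt. This only affects objects essentially touching
the frame, which the border rule excludes from statistics anyway.

**Hysteresis.** A pixel is kept iff its probability strictly exceeds the
low threshold and it is 8-connected, through pixels above low, to a pixel
strictly above the high threshold. Strict inequalities make the operation
exactly testable; defaults are low 0.5 / high 0.8 and are explicit
configuration (the protocol this re-implements does not publish its
values). The implementation is verified against an independent
flood-fill oracle on random probability maps and obeys the sandwich
property (above-high mask ⊆ output ⊆ above-low mask, every component
seeded).

**Post-processing.** Objects are 8-connected components; background holes
are detected with 4-connectivity (the standard complementary pair) and
filled when enclosed by a single object, *before* the size filter, so
filled area counts toward it. Objects below 300 µm² are then discarded —
at 1 µm pixels a 17×17 square (289 µm²) falls, an 18×18 square (324 µm²)
survives. Labels are renumbered by descending area and objects touching
any image edge are flagged as border crypts. The whole step is
idempotent.

# Spatial morphometrics

Distances are measured between boundary-pixel centers (object pixels with
a background 8-neighbor; the frame counts as background), in µm. This
matches a pixel-based protocol and is exactly testable; sub-pixel contour
interpolation is deliberately not used. Two implementations coexist:

* `gt_metrics()` — the brute-force oracle: exhaustive minimum over all
  boundary-pixel pairs, simple loops, no shortcuts;
* `crypt_metrics()` — the fast path: bounding-box pre-screening (a lower
  bound on the boundary distance, so no qualifying pair is ever skipped)
  with vectorized pair distances.

The two must agree exactly, and the test suite asserts identity on
hundreds of random label maps. Two consequences of the pixel grid are
asserted as invariants: symmetry, and a minimum distance of 2 pixels
between distinct 8-connected objects.

**Radii.** The nearest-crypt distance uses a 40 µm search radius: a
minimum above 40 µm is *undefined* (excluded from image means), not
truncated to 40. The neighbor count uses an inclusive 20 µm radius.
Inclusive bounds at round physical radii are fixed conventions; whether
the original protocol capped, excluded, or searched within 40 µm is not
published, and exclusion is this package's documented choice.

**Border rule.** Border crypts contribute as distance and neighbor
partners but are excluded from every per-image mean; their rows remain in
the crypt table flagged `is_border` for transparency. Per-image summaries
therefore report interior counts, interior mean area, the nearest-crypt
mean over interior crypts with a defined value, and the interior mean
neighbor count.

**Update mode.** Segmentations are persisted as self-contained JSON
contour files and can be hand-corrected (labels merged, split, deleted,
vertices moved); `update_from_contours()` rasterizes the edited file,
re-validates every invariant, drops objects that fell below the size
filter (with a warning) and recomputes all measurements from scratch. On
an unedited file this reproduces the original outputs exactly.

Contours are stored as crack-boundary polygons through pixel *corners*
(0-based; pixel $(i, j)$ spans $[i, i+1] \times [j, j+1]$), outer rings
with positive signed area and holes negative, with possibly several rings
per label. Corner polygons were chosen over pixel-center polygons because
they admit an exact even-odd rasterization inverse for every 8-connected
object, including one-pixel-wide structures where center polygons
degenerate; round-trip identity is asserted property-style in the tests.

**Heatmaps.** Crypts are colored by any per-crypt value on a perceptually
uniform monotone colormap (viridis), with reserved neutral grays for
border crypts and undefined values and black background; the exact
label → value → color mapping is emitted as a table because the original
figures' colormap is not published.

# The synthetic mosaic generator

Because the study's raw images are not reproducible at desk scale, every
stage is validated against synthetic fields with exact ground truth. The
generator emulates what matters to the measurements — dark elliptical
lumens (axis ratio ≤ 1.3) in a bright collagen band with striated
texture over a dimmer background — and nothing more: no point-spread
function, no depth attenuation, no 3D.

Defaults are fixed once as the package's study conditions: a
426 × 426 µm field (512 px at 0.8325 µm/px — twice the 0.41625 µm/px of
the colon acquisitions, halving compute at no cost to the ~10 µm-scale
geometry), ~60 lumens of mean radius 12 µm (sd 2 µm, mean area
≈ 450 µm²), 6 µm minimum border-to-border gap, 5 µm walls, 8-bit
intensities wall 190 / background 60 / lumen 25, oriented texture of sd
15 and Gaussian noise of sd 8. Intensities are configuration, not
contract. Two generator rules exist to keep the ground truth
well-defined rather than to ease any test:

* a lower radius truncation at 10 µm (≈ 314 µm²): lumens below the
  pipeline's 300 µm² physical filter are not biologically expected, and
  generating them would make exact count recovery impossible by
  construction;
* a placement margin of 3 px at the frame: a lumen whose boundary stops
  within a pixel of the frame without crossing it has no stable
  interior/border class under the ±1 px uncertainty inherent to any
  pixel segmentation, so such configurations are rejected (lumens either
  cross the frame decisively or keep clear of it).

Placement is dart throwing with rejection when the conservative gap
(center distance minus both major semi-axes) falls below the minimum, up
to 10,000 attempts per crypt; failure to place the full count warns with
the achieved count and proceeds, since a partially filled field is still
a valid field. Wall texture is white noise passed through anisotropic
Gaussian band-pass filters at four orientations, each pixel taking the
channel aligned with the local wall tangent (perpendicular to the
gradient of the lumen distance transform). Everything is deterministic
given the spec's seed.

The `fibrosis_transform(spec, severity)` maps these conditions toward the
fibrotic phenotype monotonically — crypt count × (1 − 0.5 s), mean radius
× (1 + 0.5 s), minimum gap × (1 + 2 s), wall thickness × (1 + 0.5 s) —
with severity 0 the identity. The factors were chosen once to span,
at s = 0.8, roughly the halving of crypt count and doubling of crypt
area that distinguishes a fibrotic from a healthy field.

**What passing tests do and do not show.** Ground-truth recovery on
these mosaics demonstrates that the geometry pipeline measures what it
claims on images with the right large-scale structure. It does not
demonstrate robustness to the things the generator omits: uneven
illumination, out-of-focus collagen, touching lumens, mucus autofluor-
escence, or genuinely ambiguous crypt boundaries — which is exactly why
the manual-correction update mode exists.

One known interaction: the ground-truth table includes *every* rasterized
lumen, while the pipeline's physical filter drops border slivers below
300 µm². An interior crypt whose nearest within-40 µm partner is such a
sliver gets a different (farther) partner after segmentation, so
segmented nearest-distance means can drift by up to about a pixel
relative to the raw ground-truth mean even when every interior crypt is
recovered exactly. The per-image summaries report the number of crypts
contributing to each mean so this is visible in the output.

# Collagen-covered area

The in-vitro ECM deposition readout uses a fixed recipe, in fixed order:
(1) enhance white detail — implemented as image + white top-hat with a
disk of radius `size` (default 2 px), a standard small-bright-structure
enhancer standing in for a proprietary microscope filter of that name and
parameter; (2) linear histogram stretch (observed min → 0, max → dtype
max; constant images pass unchanged); (3) median filter of radius
`size` (default 1, i.e. a 3×3 window); then a strict fixed threshold.
No automatic threshold selection is offered on purpose — the reference
protocol set it manually, so it is explicit configuration here. Stacks
are processed slice-wise with the per-slice table exposed and means
reported, since covered area is a per-field 2D quantity. Covered fraction
is non-increasing in the threshold and increases with wall thickness on
synthetic mosaics; both are asserted.

# Matrisome overlap and differential expression

Protein lists are normalized (trim, uppercase, deduplicate) and compared
by exact string equality; no ortholog mapping is attempted for
cross-species comparisons, because the reference analysis publishes none
and uppercased symbols coincide for most matrisome genes — mismatches
stay visible in the membership listings for audit. Differential
expression keeps proteins with fold change strictly above 1.5 in either
direction (ratio > 1.5 or < 1/1.5) and FDR ≤ 0.1; the printed convention
"FC > 1.5; FDR < 0.1" is ambiguous at the FDR bound and the inclusive
reading is fixed here. "Step-up" correction is Benjamini–Hochberg.

The screening test is a per-protein two-way ANOVA (factors such as
genotype and timepoint; interaction included when replication allows)
with step-up adjustment per factor across proteins; single-factor
designs — e.g. an endpoint-only genotype comparison — are routed to an
unpaired two-sided Student's t-test. Sequential (Type I) sums of squares
are used; the designs in scope are (near-)balanced, where Type I and
Type II main effects coincide. Proteins with zero variance in every
design cell are flagged with undefined p-values rather than dropped
silently. Matched normal-vs-tumor abundance comparisons use the
classical paired two-sided t, with all-zero differences defined as
t = 0, p = 1 and constant nonzero differences flagged degenerate.

# Cohort statistics

Per-mouse values are unweighted means over that animal's images, with
images lacking a defined value excluded from that metric's mean and the
contributing count reported. Group comparisons use Welch's
unequal-variance two-sided t (reported as mean ± SEM per group);
correlations with tumor burden use two-sided Pearson via the t
transform. Both are verified against closed-form recomputation to
1e-10 and the Welch test's type-I error is checked by simulation
(2000 null replicates, 8 animals per group, unequal variances) to lie
in [0.03, 0.07] at nominal 0.05.

Outliers — the motivating case being one animal whose mean crypt size of
~11,000 µm² sat twenty-fold above its group — are flagged by an
iterative two-sided Grubbs test at α = 0.05, a documented stand-in for
the unstated "statistically significantly different from group average"
criterion. Values are only flagged, never removed: exclusion is an
explicit user action.

# Problem sizes and verification summary

The test suite regenerates all fixtures in code: 200 random label maps
(≤ 64×64, ≤ 6 objects) for exact oracle equivalence of the distance
machinery; 200 random 32×32 probability maps for hysteresis against the
flood-fill oracle; 256 px mosaics at gaps 5/12/25 µm for spacing
recovery after classifier training (within one pixel of ground truth;
interior IoU ≥ 0.95 and exact interior counts on noise-free fields);
512 px fields for the fibrosis-direction check; and the null simulations
above. `scripts/acceptance.R` re-runs the full pipeline — training,
segmentation, morphometrics, collagen area, calibration — from a single
seed and writes every headline quantity as JSON.

The matrisome worked example against the source study's deposited
supplementary tables and the published mouse/human colon matrisome lists
cannot ship with the package (the data are external deposits); the
corresponding acceptance test documents the expected file layout under
`inst/extdata/matrisome/` and fails informatively until those files are
supplied.
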