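---
title: "Quantifying the nuclear-to-cytoplasmic ratio in fiber-bundle microendoscopy"
author: "hrme package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the nuclear-to-cytoplasmic ratio in fiber-bundle microendoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrme)
```

## The measurement

A high-resolution microendoscope images proflavine-stained epithelium
through a coherent fiber bundle placed in contact with tissue. Proflavine
labels DNA, so nuclei appear bright against a dimmer cytoplasmic
background, within a circular field of view 720 µm across at roughly 4 µm
lateral resolution. In neoplastic epithelium nuclei are larger and more
crowded, so the fraction of the image occupied by nuclei rises. The
package quantifies this as the nuclear-to-cytoplasmic area ratio within a
region of interest (ROI):

$$\mathrm{N/C} \;=\; \frac{A_\mathrm{nuc}}{A_\mathrm{ROI} - A_\mathrm{nuc}},$$

a ratio of total areas, not a mean of per-nucleus ratios. A site is
called neoplastic when its N/C ratio strictly exceeds a fixed cutoff
(default 0.163); neoplastic here means high-grade dysplasia, CIN 2 or
CIN 3, with all other histopathologic diagnoses (normal, inflammation,
HPV effect, CIN 1) pooled as non-neoplastic.

The processing sequence per imaged site is fixed:

1. **Frame selection** — one representative frame is chosen from the
   site's short movie, maximizing sharpness while penalizing motion and
   obstruction (`select_frame()`).
2. **Quality control** — the frame is discarded if more than 50% of the
   field of view is out of focus, if it shows motion artifact, or if
   debris covers a significant fraction of the FOV (`qc_evaluate()`).
3. **Preprocessing** — ROI restriction, contrast-limited adaptive
   histogram equalization (CLAHE), then median filtering to suppress the
   honeycomb pattern of the fiber bundle (`preprocess_frame()`). The
   order is fixed; a `reorder` flag exists for sensitivity analyses and
   defaults off.
4. **Segmentation** — binarization at an adjustable threshold
   (initialized by Otsu's method within the ROI), 8-connected labeling,
   and removal of objects smaller than 50 px (noise) or larger than
   1500 px (debris), with *strict* inequalities at both bounds: objects
   of exactly 50 or exactly 1500 px are retained (`segment_frame()`).
5. **Quantification and evaluation** — per-site N/C
   (`nc_ratio()`), per-category means, standard errors and pairwise
   pooled-variance Student's t-tests (`group_stats()`), confusion counts
   and sensitivity/specificity at the fixed cutoff (`confusion()`,
   `sens_spec()`), and an ROC curve with Q-point selection
   (`roc_curve()`, `q_point()`).

## The synthetic-frame generator

No public image archive accompanies this kind of clinical study, so the
package ships a first-class generator that renders frames with known
ground truth; every downstream stage is tested against it.

A rendered frame is

$$I \;=\; \mathrm{clip}_{[0,1]}\big[(B + N)\cdot P + \varepsilon\big],$$

where $B$ is the cytoplasmic background (default 0.25 of dynamic range),
$N$ adds non-overlapping elliptical nuclei at per-nucleus peak
intensities (default 0.75 ± 0.05), $P$ is the multiplicative honeycomb
pattern of the bundle (Gaussian-profiled cores on a triangular lattice
with 4 µm spacing, unity mean in the FOV, peak modulation 0.2), and
$\varepsilon$ is Poisson shot noise (500 photons at full scale) plus
Gaussian read noise (sd 0.01). Nuclei have *hard* edges: a pixel is
nuclear iff its centre falls inside the ellipse. This keeps the
ground-truth mask and the true N/C exactly countable, at the cost of not
modeling partial-volume softness at nuclear boundaries.

Nucleus equivalent radii are drawn from a truncated normal, 7 ± 1.2 µm
on [4.5, 12] µm, giving areas of roughly 80–450 px at 1 µm/px — nuclei of
squamous epithelium at this magnification, comfortably inside the
50–1500 px object filter. Nuclei are placed by rejection sampling with a
clearance margin so they never touch; placement stops when the realised
N/C is within 0.005 of the request (the last nucleus is sized to close
the gap). Requests beyond the packing limit of non-overlapping nuclei
are refused.

Cohorts mirror the study design: 44 analyzable sites with the diagnosis
mix 5 normal, 7 inflammation, 11 HPV effect, 7 CIN 1, 2 CIN 2 and
12 CIN 3, at two sites per patient. True N/C ratios are drawn per
category from Beta distributions parameterised by a mean and a shared
concentration. The published record anchors only two exemplar values —
about 0.08 for a low-grade site and 0.22 for a CIN 3 site — so the
defaults are configuration, not claims: means 0.06 (normal/benign), 0.08
(low grade) and 0.22 (high grade), concentration 60 (high-grade
site-to-site sd ≈ 0.05, comparable to the visible scatter of a
per-category dot plot of such cohorts). An `artifact_rate` fraction of
the imaged cohort is rendered out of focus (probe not in contact); with
the default diagnosis counts and a rate of 8/52 the generator produces
the study's 52-imaged / 44-analyzed split. Artifact sites carry no histopathology
record, as excluded sites are not diagnosed.

**What the generator does not emulate.** Touching or overlapping nuclei
(watershed splitting is out of scope), intensity gradients from uneven
probe contact, nuclear pleomorphism beyond mild elliptical elongation,
biological overlap between diagnostic categories beyond Beta dispersion,
and soft nuclear edges. Passing tests therefore demonstrate correctness
of the measurement chain — not that the classifier would achieve the
same operating point on clinical images. Simulated cohorts separate
more cleanly (AUC ≈ 0.99) than the clinical cohort did.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `fov_diameter_um` | 720 | µm | instrument field of view |
| `pixel_size_um` | 1 | µm/px | sensor sampling is unreported; 1 µm/px anchors pixel thresholds to physical units |
| `core_spacing_um` | 4 | µm | matches the ~4 µm lateral resolution |
| `pattern_amplitude` | 0.2 | fraction | typical visible core contrast |
| CLAHE `tiles` | 8 × 8 | tiles | common practice for this method |
| CLAHE `clip_limit` | 0.01 | fraction of tile histogram | bounds noise amplification |
| `kernel_radius_px` | 2 | px | smallest window spanning one core period; see below |
| `min_px`, `max_px` | 50, 1500 | px | published object-size window, strict bounds |
| `nc_cutoff` | 0.163 | — | published operating point |
| QC `focus_min` | 0.02 | — | calibrated on synthetic sharp/blurred fixtures |
| QC `oof_max` | 0.5 | fraction | published 50% out-of-focus rule |

## Numerical and design choices

**Median kernel radius.** The filter must span a fiber core to suppress
the honeycomb, yet every extra pixel of window width erodes nuclear
boundaries: for a two-valued image the median is exactly the
neighbourhood majority vote, which shaves a sub-pixel band off any
convex object. Measured on default frames, a 7 × 7 window removes about
10% of nuclear area and biases N/C by −0.026 at N/C 0.22; the 5 × 5
window (radius 2, the smallest spanning the 4 µm core period at 1 µm/px)
leaves a residual honeycomb of ~17% of its input amplitude — low enough
for stable Otsu segmentation — while keeping the N/C bias below 0.015
across the clinical range. Radius 2 is therefore the default, with the
radius exposed for configuration.

**Threshold initializer.** Otsu's maximization of between-class variance
is computed on a 256-bin histogram spanning the observed ROI range, so
the suggested threshold is exactly equivariant under affine intensity
rescaling. The published protocol had a blinded reviewer adjust the
threshold visually; that human-in-the-loop step is reproduced
deterministically as an optional per-site `threshold_override` column in
the ledger, defaulting to the Otsu value.

**Connectivity and label order.** Components use 8-connectivity (the
conservative choice for blob integrity; configurable at the labeling
level) and are labeled in scan order of each component's first pixel, so
labeling is deterministic.

**Strict size bounds.** "Fewer than 50" and "more than 1500" pixels are
implemented as strict inequalities — objects of exactly 50 or 1500 px
survive. This matters at the margin and is asserted by test.

**Q-point.** The ROC operating point is the point closest (Euclidean
distance in (FPR, sensitivity) space) to the perfect classifier at
(0, 1), with ties broken by higher sensitivity, then lower cutoff.
Youden's J selection is available via `q_point(curve, "youden")`.
Operating points are evaluated at all midpoints between distinct sorted
scores plus sentinels outside the score range, which makes the
trapezoidal AUC equal the Mann–Whitney U statistic divided by
$n_1 n_2$ (ties counted ½) — a property the tests verify by brute force.

**Rounding.** Headline percentages are rounded half away from zero
(85.71→86, 86.67→87); full precision is retained in all CSV output.

**Statistics.** "Student's t-test" is the classical pooled-variance
two-sample test, two-sided (`welch = TRUE` switches to the
unequal-variance form). The three pairwise category comparisons are
reported without multiple-testing correction, matching the original
presentation; a `bonferroni` flag exists and defaults off.

**QC metrics.** The focus score is the variance of a 4-neighbour
Laplacian per 32 × 32 px tile, normalized by the squared mean FOV
intensity so verdicts are invariant to positive intensity rescaling; a
frame fails when more than half of the scored tiles fall below the
calibrated threshold. Motion is one minus the peak normalized
cross-correlation with temporally adjacent frames (zero for single
frames); debris is the FOV fraction covered by saturated or occluding
connected components larger than the 1500 px debris bound. The study
applied these three rules visually; the thresholds here are documented
configuration, not claims of equivalence to the human reviewer.

**Degenerate inputs.** Constant-intensity ROIs refuse a threshold;
empty ROIs, empty cohorts, one-class cohorts (no ROC), singleton
categories (no t-test) and nuclear-area-equals-ROI (undefined ratio) all
raise informative errors rather than propagating NaN.

**Frame indexing** is 1-based throughout, following R convention; ROI
polygon files use 0-based pixel coordinates (origin top-left, x
rightward, y downward), the convention of the image-file world, and are
converted on read.

## Problem sizes

Unit and property tests run on a reduced 240 µm field of view at the
native 1 µm/px sampling, so every pixel-denominated threshold (object
sizes, median kernel, focus tiles) keeps its meaning while frames stay
small; end-to-end checks that depend on tile resolution or the full
cohort (the 52→44 QC ledger, N/C recovery across 0.05–0.30) run at
240 µm or the full 720 µm geometry as appropriate. The acceptance script
always uses the native 720 µm geometry and the full 52-site cohort.

## Known limitations

- The exact clinical N/C values, group means and t-test p-values of the
  original 44-site cohort require the original images and are not
  reproducible; the package reproduces the *procedure* and validates it
  on synthetic ground truth.
- CLAHE parameters and the median kernel used in the original study are
  unreported; exact numeric reproduction of the published exemplar
  values (0.08, 0.22) from raw clinical frames is not claimed.
- The 50/1500 px object bounds are applied verbatim in pixel units;
  whether they were magnification-dependent is unknowable from the
  record, so analyses at other pixel sizes should rescale them
  explicitly.
- Touching nuclei are segmented as single objects; heavily crowded
  high-grade epithelium may merge objects, which the size filter then
  removes if they exceed 1500 px. The non-overlap constraint of the
  generator avoids this regime by construction.
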