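---
title: "Methods: automated SEM-EDS counting of elongated mineral particles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated SEM-EDS counting of elongated mineral particles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(empscan)
```

## The problem

Fibrous minerals such as erionite — a zeolite classified as a Group I
carcinogen — occur in near-surface rock and can become airborne during
construction, quarrying, or roading. Exposure assessment samples a known
volume of air onto a polycarbonate membrane filter and counts the elongated
mineral particles (EMPs) deposited on it. Manual counting under phase
contrast or electron microscopy is slow (50–400 fields of view per filter)
and cannot identify mineral species. An automated scanning electron
microscope with an energy-dispersive X-ray detector can image many fields
unattended, measure every particle, and acquire a short elemental spectrum
per particle; this package implements the data-analysis side of that
workflow, from micrograph to fibers-per-cm³ with Poisson uncertainty, plus a
synthetic generator so every stage is testable without an instrument.

## Segmentation and morphology

A field of view is a grayscale raster with a physical calibration in µm per
pixel (mandatory external metadata; SEM export headers are too inconsistent
to guess from). A fixed linear brightness/contrast transform
(`gain * I + offset`, identical across all fields of a run) is applied, then
pixels at or above a manual intensity threshold become candidate particle
material. An automatic bimodality (Otsu) threshold is available for
exploration, but the analysis-faithful mode is a fixed, operator-chosen
threshold.

Foreground pixels are grouped into **8-connected** components so that thin
diagonal fibers stay whole. Components below a minimum pixel count (default
4) are discarded: a fiber narrower than a pixel cannot be measured, and this
floor makes the sub-resolution limitation explicit and testable. Components
touching the image border are flagged and excluded from counting by default
(no edge-correction rule is applied; the flag is configurable).

Length and width are the **maximum and minimum Feret (caliper) diameters**
of the component footprint. Calipers are computed over the convex hull of
the pixel centres, plus one pixel of extent, so a single pixel measures
1 × 1 px and an axis-aligned 96 × 8 px block measures its diagonal by 8 px.
This convention was chosen because (a) it matches fiber-counting practice,
(b) it admits an exact independent oracle (brute force over all
boundary-pixel pairs: the maximum pairwise distance, and the minimum over
pair-defined directions of the projection width), and (c) it makes a square
particle measure an aspect ratio of √2, correctly non-fibrous. The hull
implementation and the oracle agree exactly; both agree with analytic shape
dimensions within 2 px across orientations.

A particle is counted as a fiber when **aspect ratio ≥ 3 and width < 3 µm**.
There is deliberately **no minimum-length rule**: erionite fibers shorter
than 5 µm occur in air samples, so the conventional >5 µm length criterion
of asbestos counting would miss them. Both thresholds are configurable;
crossed or touching fibers remain a single component (no watershed
splitting), matching the known limitation of the automated instrument
approach.

## Elemental classification

The EDS export gives mass percentages per particle. Carbon and oxygen are
contaminated by the polycarbonate substrate, so the analysis restricts to
the eight elements commonly found in zeolites — Si, Al, Mg, Na, K, Ca, Fe,
Cl — renormalized to 100%. The screening statistic is the tetrahedral ratio

$$T_{Si} = \frac{Si}{Si + Al}$$

computed here on the renormalized **mass** basis (the quantity the
automated export provides); the same function applied to atomic proportions
reproduces the bulk-formula value (0.744 for the reference erionite's
microprobe formula; 0.752 on the mass basis).

Classification is a deterministic first-match decision tree: non-fibers are
set aside; Cl ≥ 15% → halide salt; Si ≥ 30% with Al ≤ 2% → silica; Si > 0,
Al > 2%, and extra-framework cations Na+K+Ca+Mg ≥ 2% → zeolite branch,
labelled `erionite_like_zeolite` when T~Si~ lies in the open window
(0.68, 0.79) and `other_zeolite` otherwise; Fe ≥ 30% → Fe-rich mineral;
anything else is `unclassified_mineral`. The numeric gates are
**screening defaults, not mineralogical identifications**: composition
alone cannot separate erionite from offretite (their T~Si~ overlap), so the
erionite-like label marks candidates for TEM/SAED confirmation, and every
gate is configurable through `classification_rules()` or a YAML file. The
window (0.68, 0.79) brackets the reference erionite's mass-basis T~Si~
(~0.75) while excluding high-silica zeolites such as mordenite (~0.84);
whether the instrument software used mass or atomic percentages is not
documented, which is another reason the gates are exposed as configuration.

## From counts to concentrations

With effective filter area $A_{effect}$ (mm²), $n$ analyzed fields of area
$A_{FOV}$ (mm²), flow $v$ (cm³/min) and duration $t$ (min),

$$\mathrm{AS} = \frac{A_{effect}}{n \, A_{FOV} \, v \, t}, \qquad
  C = N \cdot \mathrm{AS},$$

where AS (f/cc per fiber) is the analytical sensitivity and $N$ the counted
fibers. Counts over randomly/transect-sampled fields are Poisson, so the
95% interval on $C$ multiplies exact (Garwood) chi-square count limits by
AS: lower $\tfrac12\chi^2_{\alpha/2}(2N)$, upper
$\tfrac12\chi^2_{1-\alpha/2}(2N+2)$. The **limit of detection** is the
one-sided 95% upper bound when zero fibers are observed,
$-\ln(0.05) = 2.996$ fibers, times AS, computed through the same code path
as the confidence limits. For the performance-evaluation configuration
(385 mm² filter, 25 fields of 0.0031 mm², 2 L/min for 1 min) this gives
2.484 f/cc per fiber and an LOD of 7.44 ≈ 7.4 f/cc. The field area
0.0031 mm² is a documented reconstruction of a 64 × 48 µm field at 2000X
(consistent with the ~0.003 mm² field of the magnification comparison);
plausible alternatives within rounding move the LOD between about 7.4 and
7.7 f/cc.

Sequential scanning stops on a cap rule — `fiber_cap` fibers counted
(default 100) or `n_max` fields analyzed (default 25 for spiked filters,
100 for environmental ones) — the standard stopping idiom of SEM filter
methods; the ISO tabulation it stands in for is not reproduced in
accessible form, so the caps are fully configurable. Fields are placed
edge-to-edge along a radial transect from the filter centre
(`fov_transect()`), averaging over uneven deposition.

Calibration against spiked standards is ordinary least squares of measured
f/cc on bulk erionite mass%, with R², a two-sided slope t-test
($n-2$ df), and a 95% slope interval. Note a real property of this design:
Poisson counting noise is heteroscedastic (variance grows with loading),
and the highest standards carry both the most leverage and the most
variance, so the naive OLS slope interval is anti-conservative (~78%
observed coverage in simulation). The slope estimate itself is unbiased and
tight — within 10% of truth in >90% of simulated series — which is the
property the tests assert. Weighted or GLM fits would fix the interval but
would depart from the simple regression this method reports.

## The synthetic generator

`simulate_scene()` emulates a backscatter image: bright rotated rectangles
(fibers) and ellipses/wide ribbons (distractors) on a dark background with
optional dark filter pores and additive Gaussian noise, all geometry drawn
in physical units so one scene can be rasterized at several magnifications.
Defaults encode the study conditions: fiber lengths log-normal with median
1.5 µm capped at 5 µm (mechanical aerosolization fragments fibers short),
widths log-normal with median 0.3 µm, a 10 µm hard cap standing in for the
PM10 pre-separator, a 64 × 48 µm field at 0.03125 µm/px (2048 × 1536,
2000X), background/particle intensities 20/200, and an 0.8 µm pore size.
Deposition is uniform; placement is rejection sampling with a ~0.6 µm
separation (a `cluster_fraction` option deliberately places touching
fibers).

Rasterization marks pixels whose centres fall inside a shape, with two
resolution effects built in: shapes thinner than **half a pixel do not
render** (sub-pixel fibers are undetectable), and visible thin shapes
render at a minimum thickness of ~1.45 px so a resolvable fiber appears as
a continuous bright line in any orientation, as it does in a real
backscatter image (naive centre-sampling would instead shatter near-pixel
fibers into fragments and double-count them). Together these make the
detected count of a fixed scene non-decreasing as pixel size shrinks — the
qualitative magnification behaviour of the instrument. The ground-truth
mask equals the rendered shape union, so in the noiseless limit
binarization at the intensity midpoint reproduces it exactly.

`simulate_eds()` models counting statistics only: total counts =
rate × time (default 2500 cps, a typical benchtop throughput at 15 kV),
split multinomially by the template mass fractions. No detector background,
escape peaks, coating peak, or matrix corrections — input to the real
workflow is the instrument's composition table, not spectra. Templates:
erionite from the reference microprobe formula (Ba, outside the
eight-element set, dropped), a mordenite-like other-zeolite, near-pure
silica, and halite. At the 10 s acquisition default (~25,000 counts) the
composition noise is small enough that classification accuracy stays above
95% and the mean simulated T~Si~ sits within 0.01 of the template —
mirroring the finding that 10 s spectra preserve the ratio.

`simulate_pe_experiment()` ties loading to counts: expected count
λ = k · mass% / AS with aerosolization efficiency k defaulting to
716/1.74 ≈ 411.5 f/cc per mass%, scaling the 1.74% standard to the
observed 0–716 f/cc range; observed counts are Poisson, split uniformly
over fields. k is a free parameter of the apparatus, unknown in truth, and
possible nonlinearity at high loading is not modelled.

## What passing tests do and do not show

Synthetic scenes are clean: noiseless shapes, no charging, focus drift,
beam drift, overlapping deposition layers, or substrate texture. Perfect
recall/precision on them validates the geometry and bookkeeping of the
pipeline — not detection performance on heavily loaded or poorly imaged
real filters, where touching particles merge (counted once), fibers
attached to grains are missed, and brightness settings decide everything.
The EDS model validates the screening logic, not spectral quantification.
Classification output is a screening verdict; confirmation of erionite
requires electron diffraction.

## Numerical and design choices

- Pixel convention: 0-based (row, col) centroids; physical position of
  pixel (r, c) is ((c+0.5)·px, (r+0.5)·px) µm in reported coordinates.
- Problem sizes in the shipped tests: 2048 × 1536 px scenes for detection
  checks, 100 random shapes for the Feret oracle, 10,000 replicates per λ
  for interval coverage, 200 seeded series for calibration recovery, 1000
  noisy draws for classification accuracy — large enough for stable
  percentages while keeping the suite quick on one CPU.
- Degenerate inputs: all-zero compositions, empty masks, zero-count
  filters, constant calibration responses, and transects longer than the
  filter radius all have defined behaviour (error or explicit zero), tested.
- Reports omit wall-clock timestamps so a run is byte-reproducible from
  its echoed config and seed; timing belongs to the log stream.
- `run_pipeline()` restricts the EDS table to analyzed fields before the
  strict two-sided id check, so early termination does not trip the
  orphan-id error.
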