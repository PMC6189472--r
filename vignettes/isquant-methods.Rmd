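---
title: "Methods: quantitative imaging of receptor dynamics at the immunological synapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative imaging of receptor dynamics at the immunological synapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(isquant)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the design decisions taken where a
workflow is conventionally under-specified, and what the synthetic-data tests
do and do not demonstrate about real microscopy data.

## The scientific setting

When a T cell engages a stimulatory surface — micropatterned antibody spots,
an antibody-coated bead, or a supported lipid bilayer (SLB) presenting
laterally mobile anti-CD3 — its receptors reorganize. Submicron receptor
microclusters form at the cell periphery and are transported centripetally by
retrograde actin flow until they coalesce into the central supramolecular
activation cluster (cSMAC) of the immunological synapse. A receptor that
physically associates with the TCR/CD3 complex is expected to (i) be
co-recruited to CD3-ligating regions, (ii) be partially immobilized when CD3
is immobilized, and (iii) co-migrate with CD3 microclusters. The package
quantifies each of these readouts from image stacks: FRAP curve fitting,
enrichment ratios, co-localization time series, kymograph speeds, and synapse
scoring.

## Data model and conventions

All image data live in an `image_stack`: a `(frame, channel, row, col)`
array plus `pixel_size_um` and `frame_interval_s`. Readers permute to this
layout at the boundary; there is exactly one internal axis order.

Coordinates are continuous, 0-based and pixel-centred: pixel `(i, j)` is
centred at `x = j`, `y = i` and a pixel belongs to a rasterized ROI iff its
centre is inside. This makes rasterization unambiguous and ROI JSON sidecars
portable. Time is 0 at the first frame of a stack; FRAP-specific re-zeroing
(t = 0 at the first post-bleach sample) happens in the normalization step,
not in the I/O layer.

TIFF reading goes through the `tiff` package. Writing uses a minimal
baseline-TIFF emitter built into the package, because the installed writer
clamps intensities to [0, 1] and cannot store an ImageDescription tag; the
emitter stores uint16 for integer data in range and 32-bit float otherwise,
with axes, channel names and physical metadata in a JSON ImageDescription.
Round trips are lossless for integer data and float32-representable values;
doubles beyond float32 precision are rounded — a documented limit, matching
what microscopy acquisition software itself records.

Background estimation defaults to a per-frame histogram-mode (darkest-peak)
heuristic, appropriate when most of the field is background; an explicit
background ROI always overrides it. Whether a background is per-frame or a
single value is a free choice in most published workflows; both are
supported here, per-frame being the default.

## FRAP: normalization

Two normalizations are implemented. *Double normalization* divides the
background-corrected bleach-ROI trace by a background-corrected reference
(whole-cell) trace and rescales by the prebleach means,

$$I_{dn}(t) = \frac{B(t)-bg}{R(t)-bg}\cdot
  \frac{\langle R-bg\rangle_{pre}}{\langle B-bg\rangle_{pre}},$$

which cancels acquisition photobleaching exactly when bleaching affects both
ROIs equally — the property the test suite verifies by generating traces
with and without an imposed acquisition-bleach factor. *Single
normalization* omits the reference.

Both curves are then rescaled to *full scale*: the first post-bleach sample
maps to 0 and the prebleach plateau to 1. This step is rarely stated
explicitly in papers, but it is what makes the fitted plateau *literally*
the mobile fraction; the package applies it after either normalization, and
keeps the prebleach-unit curve as a column for plotting conventions that
prefer it. Full scale drives all fitting.

## FRAP: the two recovery models

**Single exponential.** The package fits
$F(t) = A\,(1-e^{-t/\tau})$, with mobile fraction $A$, immobile fraction
$1-A$, and halftime $t_{1/2} = \ln 2\,\tau$. FRAP methods sections often
print the decaying form $A e^{-t/\tau}$; that form describes the
unrecovered deficit and cannot be fitted to a rising curve, so the recovery
form is used here — an interpretation, flagged in the documentation of
`fit_frap_exponential()`.

**One-dimensional strip-bleach (Ellenberg) model.** For a rectangular ROI of
width $w$ on a membrane where recovery is effectively one-dimensional,

$$F(t) = I_{final}\left(1-\sqrt{\frac{w^2}{w^2+4\pi D t}}\right),$$

fitted for $(I_{final}, D)$. Two halftimes are reported side by side:

* the conventional value from $D = 0.88\,w^2/(4\,t_{1/2})$, i.e.
  $t_{1/2} = 0.22\,w^2/D$;
* the model's exact half-recovery time, obtained by solving
  $F(t)=I_{final}/2$, which is $3w^2/(4\pi D)\approx 0.2387\,w^2/D$.

These differ by about 7.9% relative. The discrepancy is a property of the
convention, not of any particular data set; the package reports both and
never substitutes one for the other. $I_{final}$ is reported as the mobile
fraction for this model — a stated convention, since the strip model does
not define one.

`w` is by convention the *short* side of the strip (default 1 µm for a
2 × 1 µm ROI), the dimension along which recovery is treated as 1-D
diffusion; it is configurable where an analysis treats the long side as the
recovery axis.

**Fit numerics.** Initialization: plateau from the mean of the last 10% of
samples; the rate parameter from the first crossing of half the plateau.
Optimization uses bounded Levenberg–Marquardt (`minpack.lm`), plateau in
[0, 1.5], rate > 0, parameter tolerance 1e-10. Reported mobile fractions
are clamped to [0, 1.05] with an `out_of_range` flag; non-convergence is
returned as `converged = FALSE` with the optimizer's message, never
silently.

```{r frap-example}
spec <- scene_spec("frap", seed = 1, f_imm = 0.3, tau = 2,
                   bleach_depth = 0.5, noise = noise_gaussian(0.02))
curve <- simulate_frap_curve(spec, n_pre = 10, n_post = 100, dt = 0.2)
fit <- fit_frap_exponential(double_normalize(curve))
glance(fit)[, c("mobile_fraction", "tau", "t_half", "converged")]
```

## The synthetic-data generators

Every analysis stage is validated by parameter recovery on synthetic scenes
whose ground truth is known by construction. The generators take a
`scene_spec` with a mandatory seed; identical specs give byte-identical
output.

**FRAP curves** are closed-form model curves with a prebleach plateau at 1,
an instantaneous drop to $1-d$ (bleach depth $d$, default 0.5 to match the
~50% fluorescence loss typical of short high-power bleaches), and Gaussian
noise (default sd 2% of the plateau — a spec choice, since acquisitions
rarely state their SNR; the acceptance checks sweep the relevant levels).
The default sampling (10 prebleach + 100 postbleach samples at 200 ms) and
the bleach-ROI geometry (2.1 µm circle; 2 × 1 µm strip) mirror standard
confocal FRAP protocols on these cells.

**FRAP image stacks** are generated mechanistically: a mobile concentration
field (fraction $1-f_{imm}$) diffusing by explicit finite differences
(reflecting boundaries, sub-stepped to $D\,\Delta t/px^2 \le 0.2$) plus a
static immobile field; the bleach multiplies both by $1-d$ inside the ROI.
Bleaching is instantaneous because real bleach times (0.1–1 s) are short
compared to recovery; acquisition photobleaching is off by default but can
be switched on specifically to test double normalization. For tests of the
strip model the bleach strip spans the full field height, so recovery is
genuinely one-dimensional — matching the model's own assumption. An
independent lattice random-walk simulation (kept in the test helpers, not
in the package, so it cannot share code with the implementation) reproduces
the finite-difference traces within Monte-Carlo error.

**Spot scenes** emulate cells over a 5 µm-spot grid (10 µm pitch): a spot
channel, a receptor channel with an exact on/off intensity ratio, and a
DIC-like channel rendering cell edges as intensity ridges — sufficient for
edge-based segmentation, deliberately not optics-accurate. Cells are
disjoint disks centred on spots (the analysis excludes watershed splitting
of touching cells by design).

**Bead scenes** render a membrane annulus whose bead-contact arc is
brighter by the prescribed ratio; the returned contact/opposite ROIs are
exact mirror images, so their pixel counts are equal and the noiseless
measured ratio equals the prescribed one exactly.

**Synapse time-lapses** nucleate microclusters on a peripheral ring and
transport them inward at a set speed until they merge centrally; speed 0 is
the actin-inhibited regime in which clusters stay peripheral. A set
fraction of channel-A clusters has a channel-B twin at the same position;
the rest are interleaved at disjoint angles. Ground-truth tracks are
returned for every cluster.

What passing these tests shows: the algorithms recover known parameters
under realistic geometry, sampling and noise. What they do not show:
robustness to optical artefacts the generators deliberately omit — PSF
blur, TIRF field decay, uneven illumination, membrane topography, cell
motion and segmentation of touching cells. Results on real data inherit
those caveats.

## Segmentation and enrichment

Spots: intensity threshold (Otsu by default — published workflows typically
say only "an intensity threshold"; a manual threshold reproduces specific
analyses), hole filling, and removal of objects below 25% of the nominal
spot area when a diameter is configured.

Cells: Sobel gradient magnitude → hysteresis threshold (low-mask components
kept iff they contain a high pixel; high = Otsu of the gradient, low =
0.4 × high) → morphological closing (disc radius 2 px) → hole fill →
erosion by the same radius → connected components → size filter. The final
erosion biases the outline slightly *inward*: the measured region is then a
subset of the true cell, which keeps enrichment ratios pure (a boundary
pixel of background dilutes a ratio far more than a missing interior pixel
biases it). All structuring-element sizes are arguments.

Enrichment is the ratio of background-subtracted mean intensities over the
on-spot and off-spot parts of each cell (1 = no recruitment); with
background 0 it reduces to a plain intensity ratio, and whether published
values were background-subtracted is typically unstated — the subtraction
is a switch, default on. Cells whose on- or off-spot region is smaller
than `min_pixels` (default 20) are excluded rather than contributing
sliver-based ratios. The bead-contact ratio is the same quantity over two
equal-sized membrane ROIs, warning when their pixel counts differ by more
than 10%.

## Co-localization, relative intensity, kymographs

Mander's coefficients are computed in the intensity-weighted (JACoP)
convention: $M_1$ is the fraction of above-threshold channel-A intensity
lying where channel B is above its threshold, $M_2$ the converse — so
channel swap exchanges them exactly. Thresholds are recomputed per frame by
default (Otsu, percentile or fixed; per-frame versus global is unstated in
typical workflows, per-frame is the default here) and always recorded.
Pearson's coefficient is the plain product-moment correlation over the ROI.
The ROI applied to a time series is fixed across frames; its size is a
parameter, since "the central part of the interface" is qualitative.

Relative intensity time courses divide the per-frame integrated density of
an ROI by its value at the frame nearest the reference time (snapped,
because a stated reference like t = 2 min need not coincide with a frame).

Kymographs sample a line ROI by bilinear interpolation at 1-pixel steps per
frame; rows are frames (time increases downward), columns positions from
the first endpoint. Display conventions differ — some tools show static
objects as horizontal lines in a transposed layout — so a `transpose` flag
exists; analysis functions accept both. Speed estimation takes the
intensity-weighted centre of the above-threshold signal per row and fits a
robust line (`MASS::rlm`) of position against time; it assumes one dominant
streak and warns when rows repeatedly contain several separated runs.

## Synapse scoring

The visual synapse call ("a cell on the bilayer overlaying a TCR/CD3
cluster") is automated with two explicit criteria on the largest
above-threshold CD3 cluster within each cell: area ≥ `min_area_um2`
(default 3 µm²) and centroid within `centrality_max_frac` (default 0.4) of
the cell's equivalent radius from the cell centroid. The defaults are
package choices — the manual definition is qualitative — and both are
logged per cell in the output (`area_pass`, `centrality_pass`), so a
re-analysis can tighten or relax them transparently. Eligibility requires
80% of the cell footprint on the thresholded bilayer-tracer (DiI) area when
that channel is provided; otherwise all segmented cells are eligible. The
condition-level fraction carries a Wilson 95% interval. Known limitation:
when transport inhibition also reduces bilayer engagement, washed-off cells
are invisible to scoring, so inhibited-condition fractions can be
overestimates of engagement-conditional synapse formation; no correction is
applied.

## Problem sizes used in the checks

The packaged checks run at deliberately modest sizes chosen to exercise the
estimators well inside their asymptotic regime: 50–100 noisy curves per
FRAP recovery level; a 48 × 240 px (4.8 × 24 µm at 0.1 µm/px) strip-bleach
field with 40–60 post-bleach frames; 10⁵ walkers for the particle oracle;
three-cell spot scenes; eight-cell scoring scenes; 25–40-frame synapse
time-lapses. These sizes reproduce the pinned values (30% / 10% immobile
fractions, threefold bead enrichment, unit no-recruitment baseline) with
margin relative to their tolerances.

## Reproducing the headline numbers

`scripts/acceptance.R` regenerates the three pinned quantities from scratch
(immobile-fraction recovery at the 30% and 10% ground-truth levels through
simulation, double normalization and exponential fitting; the uniform-cell
enrichment baseline through the full segmentation pipeline) and writes them
as JSON. See the README for the exact invocation.
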