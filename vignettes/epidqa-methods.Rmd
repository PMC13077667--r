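---
title: "Models and methods behind epidqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epidqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epidqa)
```

# Scope and coordinate conventions

`epidqa` analyzes integrated portal images from an EPID mounted below a
C-arm linac, and simulates such images with known injected errors so the
analyses can be validated without hardware. All pixel values are
calibrated units (CU), the panel's dimensionless dose-response unit; the
package never converts CU to dose — every metric it reports is a ratio,
a difference of ratios, or a geometric position, which is also why the
analyses are invariant to a global rescaling of the image.

One coordinate convention is declared in `epid_image()` and consumed
everywhere: continuous panel coordinates in mm with the origin at the
projection of the beam central axis; x is crossplane (transverse),
increasing with column index; y is inplane (radial), increasing toward the
gantry (decreasing row index). ROI dimensions and off-axis distances are
declared in the isocenter plane and projected to the panel by the
magnification $m = \mathrm{SID}/\mathrm{SAD}$ (1.5 for the default 150 cm
imager position at 100 cm SAD). This matches how ROI sizes are quoted in
practice ("a 5 mm radius circle") alongside panel pixel counts consistent
with a ×1.5 projection. Published per-panel pixel counts for such ROIs are
treated as informative rather than contractual, since they depend on each
panel's exact pixel-inclusion rule.

# The ROI engine

`roi_mean()` computes the true area average of the piecewise-constant
pixel raster over the projected ROI: interior pixels weigh 1, boundary
pixels weigh the fraction of their area inside the ROI. For rectangles
that fraction is the analytic overlap; for circles it is estimated by
16×16 subpixel supersampling (configurable). The supersampling order sets
the worst-case fraction error per boundary pixel at ~1/256 of a pixel
area; with boundary pixels a small minority of any realistic ROI the
engine agrees with a 10^6-point stratified Monte-Carlo area integration to
well under 10^-3 on step images (the hardest case), which the test suite
and acceptance script verify. Degenerate requests (ROI off the image, ROI
covering only zero-valued pixels) raise errors instead of returning NaN.

# Field-edge detection

The field edge is the conventional 50%-of-plateau crossing.
`detect_edges()` first finds the above-half-maximum region, estimates the
plateau as the mean of that region's central 50% (robust to horns and
noise near the penumbra), then linearly interpolates the crossings of
0.5 × plateau. Profiles with no plateau, a truncated edge, or multiple
plateaus are rejected. Linear interpolation at the 50% point of a
sigmoid penumbra is third-order accurate because the crossing sits at the
curve's inflection; at a 1 mm panel pitch the residual edge bias is a few
microns and partially cancels between opposing edges when a field center
is formed.

# The synthetic image generator

`make_open_field()` renders
$CU(x, y) = k \cdot P(r)\,\bigl(1 + t_x x/100 + t_y y/100\bigr)
S_x(x)\,S_y(y) + \varepsilon$:

* **Cross-profile** $P(r) = 1 \pm c\,(r/r_f)^2$ with $c = 0.03$ for
  flattened beams (few-percent horns) and $c = 0.10$ falloff for FFF;
  minimal shapes that reproduce the features the analyses see.
* **Penumbra** $S$ is a logistic edge whose 25–75% width defaults to 3 mm
  at the panel; the 50% crossing coincides exactly with the projected
  collimator edge, making edge-detection ground truth exact by
  construction.
* **Projection geometry**: a collimator edge at isocenter position $e$
  collimated at height $h$ by a source displaced laterally by $s$ projects
  to $s + (e\,h/\mathrm{SAD} - s)\,\mathrm{SID}/h$. This single line of
  ray tracing is what gives focal-spot errors their device-height
  dependence. The cross-profile stays centered on the collimator axis
  when the source shifts, emulating the clinical procedure of re-steering
  the beam symmetric after a focal-spot displacement.
* **Errors** (`error_spec()`): multiplicative output scale (55 MU on a
  50 MU baseline is 1.1), linear asymmetry tilt in fraction per 100 mm,
  focal-spot shift in mm, wedge angle, and per-segment MU fractions.
* **Noise**: additive Gaussian per pixel with a seeded generator
  (`noise_sd = 0` by default, and bit-reproducible for a fixed seed).
  Real acquisitions carry structured noise too (see Limitations).

The wedge fluence is exponential,
$G(y) = \exp[-\gamma \tan\theta\,(y - y_{heel})]$ with $\gamma =
0.002\,\mathrm{mm}^{-1}$ and $y_{heel} = -90$ mm, giving a ground-truth
wedge factor $WF(\theta) = G(0)$ that decreases monotonically over
10°–60° (0.98 at 10°, 0.73 at 60°). Enhanced dynamic wedges are generated
by jaw motion and have no single published fluence form; only the
monotone angle dependence is treated as contractual, and the constants are
arguments.

VMAT band images (`make_vmat_pair()`) multiply the open field by a
per-band modulation, so the open-field envelope (penumbra, horns) divides
out of $R_{corr}$ exactly. Default band centers are the published
detector positions — leaf speed at x = −4.5, −1.5, 1.5, 4.5 cm; the
dose-rate/gantry-speed ladder read as x = −5.1, −3.1, …, 6.9 cm (the
first position is printed with a positive sign in the source material but
is taken as −5.1 cm, the value consistent with the ascending 2 cm
ladder; it is configurable). Two scaling conventions are offered:
`"baseline"` (bands scaled by the segment count so an equal-fraction plan
reproduces the open field, $R_{corr} = 100$) and `"none"`
($R_{corr} = 100 f_i$, under which the 16/21/29/34% leaf-speed fractions
give Diff = (−9, −4, +4, +9)).

# Analysis design choices

* **Wedge band**: "5 mm wide central region" is implemented as 5 mm along
  the wedge-gradient axis × the central 80% of the field along the
  unwedged axis, so the band samples the gradient at the central axis.
  The 5 mm average of the exponential gradient differs from its central
  value by $a^2/6 \approx 10^{-6}$ relative ($a = \gamma\tan\theta \cdot
  2.5$ mm), which bounds the method error of the convention. Orientation
  and dimensions are configurable since the field's band conventions vary.
* **ROI sizes read literally**: the symmetry circles are 5 mm *diameter*
  ("5 mm circular regions"), the central-dose circle 5 mm *radius*; both
  configurable, the latter explicitly meant to be matched to the
  comparison chamber's size.
* **Symmetry offset** fixed at 75 mm (83.33% of the central-axis-to-edge
  distance of the 18 × 18 cm field); an option scales it with field size
  but is off by default because the published layout ties it to that
  field.
* **Device heights** default to typical C-arm values (MLC 509 mm, X jaws
  367 mm, Y jaws 279 mm from the target). They are not measured values
  for any particular machine and must be configured per linac; the
  focal-spot solver refuses geometries where jaw and MLC heights coincide
  (`height_floor`). Exposing the heights lets users study how the small
  jaw–MLC height difference limits sensitivity, and why radial and
  transverse sensitivity differ (the Y and X jaws sit at different
  heights).
* **Sensitivity fits** use ordinary least squares with Pearson r after
  baseline subtraction — matching how relative EPID metrics are compared
  to a reference detector — rather than an errors-in-variables regression;
  the reproducibility and propagation tools quantify the measurement
  uncertainty separately.
* **Concordance** (`trend()`) normalizes every device to its first
  (baseline) measurement and compares baseline-relative deltas, so two
  systems that drift together remain concordant even when their absolute
  responses differ; missing time points are dropped pairwise with a
  warning.
* **Plan editing**: `redistribute()` rescales each segment's
  cumulative-weight span to the requested fraction and maps interior
  control points affinely within their segment, preserving the delivery
  shape inside segments — the published procedure states only that
  cumulative meterset weights were modified. Segment boundaries default
  to an equal partition (the baseline tests use equally spaced segments).
  The beam's total MU is left untouched; plans are stored as plain-text
  JSON carrying the weights plus any per-control-point payload unchanged.

# Validation problem sizes

The test suite and `scripts/acceptance.R` run the full simulate → analyze
→ evaluate loop on a 384 × 384 px panel at 1 mm pitch (a 38.4 cm panel,
half the sampling density of an AS1200-class imager) — sufficient for the
recovery accuracies quoted below while keeping a complete run in seconds.
At these sizes, noise-free recoveries are: injected output changes to
< 10^-13 percentage points (the analysis is exactly linear in a global
scale), tilt-induced asymmetry with measured-vs-injected OLS slope
1 ± 0.0001, focal-spot shifts over 0–0.6 mm to < 0.007 mm
(< 0.001 mm at 0.5 mm pitch), and band Diff values to < 10^-6. The
Monte-Carlo ROI oracle uses 10^6 stratified points per image; the
propagation oracle 10^5 samples.

# Limitations

The generator reproduces the geometry and first-order physics the
analyses rest on, not the detector: no energy response, ghosting, arm
backscatter (a known confound for focal-spot measurements on older
panel mounts), panel sag, or structured flood-field residuals — and no
Monte-Carlo transport. Noise is i.i.d. Gaussian. Consequently, passing
recovery tests demonstrates the *analysis chain* is correct and sensitive
at the stated magnitudes; it does not predict absolute agreement between
a physical EPID and an ion chamber, which published commissioning studies
find at the 0.3–1.5% level depending on test and panel generation.
Dark/flood-field and CU calibration are hardware procedures and out of
scope, as are absolute dosimetry, statistical process-control action
limits, and real DICOM transfer syntax (images and plans use the
package's plain-text formats).
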