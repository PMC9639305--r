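---
title: "Evaluating 'n-SD from remote' infarct quantification on synthetic LGE phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating 'n-SD from remote' infarct quantification on synthetic LGE phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsdremote)
```

## The method under evaluation

Late gadolinium enhancement (LGE) CMR shows infarcted myocardium as
hyper-enhanced against nulled remote myocardium. The "n-SD from remote"
rule estimates the mean $\mu$ and standard deviation $\sigma$ of pixel
intensity in a remote region of interest (ROI), assumes those intensities
are normally distributed, and classifies as infarct every myocardial pixel
strictly brighter than $\mu + n\sigma$. Everything this package does is in
service of one question: how does the measured infarct size respond to the
free choices the rule leaves open — where the ROI sits, how big it is,
which $n$ is used, whether small supra-threshold islands are removed — and
to the signal properties of the image itself?

The rule's assumptions are fragile in exactly the ways the package's
phantom can control:

* remote intensities in magnitude MR images are not Gaussian near zero
  signal — single-coil noise is Rician, multi-coil sum-of-squares
  reconstruction gives a non-central chi distribution;
* the remote mean and variability depend on ROI position because of
  receiver-coil sensitivity inhomogeneity;
* $\sigma$ differs systematically between scanners, sequences and sites
  (how well the myocardium is nulled), so no single $n$ can be right
  everywhere;
* dark microvascular obstruction (MVO) inside the infarct lies *below*
  the threshold by construction and is always missed.

## The phantom: a stated world

`generate_slice()` rasterizes an annular myocardium (pixel centers against
exact circles; 0-based coordinates, centers at integer positions), paints
an infarct sector of configurable circumferential extent and transmurality
(measured from the endocardium), optionally carves an MVO core, applies a
multiplicative coil-bias bump, then adds tissue-class noise and clips to
[0, 1]. Defaults, fixed once and used throughout the tests:

| parameter | default | rationale |
|---|---|---|
| grid, spacing | 128 px, 1.5 mm | typical short-axis in-plane resolution |
| endo/epi radius | 20 / 30 mm | typical LV cavity and 10 mm wall |
| remote mean | 0.15 | imperfect nulling: dark but nonzero |
| remote SD | 0.02 | mid-range of the ~0.013–0.026 spread observed across vendors on a 0–1 scale |
| infarct mean ± SD | 0.45 ± 0.08 | hyper-enhanced but heterogeneous, so infarct and remote distributions overlap as they do clinically |
| MVO intensity | = remote mean | MVO appears nulled-dark |
| bias field | off (amplitude 0) | enabled per-study when coil inhomogeneity is the factor under test |

Noise is added only inside the myocardium; the background (air, blood
pool) stays at zero. The analysis never reads non-myocardial pixels, and a
noisy zero-mean background would be dominated by clipping artifacts under
the Gaussian model. The MVO core occupies the innermost (subendocardial)
infarct pixels until the requested area fraction is met, matching the
physiology of contrast failing to reach the infarct core. The bias field
is a single truncated-Gaussian bump (width `bias_scale`, placed at
mid-wall radius at `bias_angle`) — the simplest model of a smooth coil
sensitivity gradient.

**What the phantom does not model**: gray zone / partial-volume intensity
transitions (the infarct border is hard), 3-D slice stacks, k-space-level
MR simulation, motion or ghosting artifacts, and physiological intensity
texture in remote myocardium beyond stationary noise. A green test on this
phantom therefore establishes the *intrinsic* behavior of the
classification rule under controlled signal statistics, not its full
clinical error budget; in particular, position- and size-dependence on
real images is driven by artifacts and gradients that are only partially
represented by the bias field, so phantom CoV values are lower bounds in
spirit, never estimates of clinical CoV.

## Geometry conventions

All circumferential logic lives on a polar map: angle $\theta$ in degrees,
counter-clockwise from the +x axis about the epicardial-contour area
centroid (the convention is arbitrary; it is fixed so tests are portable),
and transmural depth 0 (endo) to 1 (epi), computed along the ray through
each pixel with contour radii linearly interpolated at the ray angle.
Sector ROIs exclude a 15% transmural rim at each surface — a depth-based
rule rather than a fixed millimeter band, so it scales with wall
thickness. Sector *angles* are measured at the centroid (not as arc length
along the mid-wall), the natural reading when contours are near-circular.

The circumference is discretized into 1° bins; a bin is "infarcted" when
at least one reference-infarct pixel falls in it. At coarse grids some
bins contain no myocardial pixel at all; such holes inherit the status of
the circularly nearest populated bin so that they cannot masquerade as
remote arcs inside an infarct sector. The slice-inclusion filter requires
≥ 36° of infarcted circumference and a largest contiguous infarction-free
arc of ≥ 180°, both inclusive.

Candidate ROI positions must fit entirely inside the largest remote arc.
When seven or more centers fit at ≥ 10° spacing, seven are spread *evenly*
over the admissible span (maximizing positional diversity, consistent with
"steps of at least 10 degrees"); otherwise as many as fit at exactly 10°
spacing are centered in the span. The ROI size grid is 15°–105° in 15°
steps — seven sizes bracketing the 45° baseline; published work fixes the
count at seven but not the values, so results should always be read as a
function of this grid.

## Numerical choices in the classifier

* $\sigma$ is the sample SD (denominator $N-1$); with ROIs of tens to
  hundreds of pixels the estimator choice is numerically minor but must be
  fixed for bit-reproducibility.
* Strictly greater than the threshold counts as infarct; ties resolve to
  non-infarct. This is measure-zero under continuous noise but decisive on
  noiseless fixtures (a noiseless remote pixel sits exactly at the
  threshold and must not be labeled).
* Island removal defaults to 8-connectivity (4 available); components of
  fewer than 10 pixels are deleted in the "no-spurious" variant. Removal
  only deletes, so the naive size always bounds the no-spurious size from
  above, for every slice — a property the tests assert rather than assume.
* A remote ROI must contain at least 10 pixels; a $\sigma$ estimated from
  fewer is statistically meaningless.
* No MVO rescue and no cross-slice processing: those belong to validated
  reference algorithms, not to the rule under evaluation.

## The studies and their statistics

Accuracy is the mean error (measured − reference, in scar percentage
units) pooled over all ROIs, with its SD; the absolute difference of
medians is reported alongside, since both definitions are in circulation.
Precision is the coefficient of variation computed per slice — the SD of
that slice's errors across the varied factor, divided by the slice's
reference size — then summarized as mean ± SD across slices. The
"mean ± SD of per-slice CoV" reading is adopted because published CoV
figures of the form "47% ± 46%" imply a distribution of per-slice values.
Slices offering fewer than two ROI variants stay in the error statistics
but cannot contribute a CoV; they are counted separately, never silently
dropped.

The per-slice optimal $n$ is a grid search over 0.1–15 in steps of 0.1
(continuous rather than integer: per-slice optima reported in the
literature average to non-integers, and integer grids cannot express
that), with ties resolved to the smallest $n$ and end-of-grid optima
flagged degenerate. The search uses the naive variant: the published
description of the per-slice optimum adjusts $n$ against the reference
with a fixed 45° ROI and says nothing about island removal.

Signal variability is reported per site as the SD of remote-ROI intensity
after min-max normalizing each image to [0, 1] — arbitrary units by
design. Note the divisor is the image's own intensity range, so the
reported value is proportional to, not equal to, the generating
`remote_sd`; cross-site *ratios* and orderings are preserved, which is
what the statistic is for.

Image-quality stratification (an observer-scored construct) is replaced by
objective stratification over phantom parameters — sites differing in
`remote_sd` and bias amplitude — and is labeled as such wherever used.

## The signal-variability direction, and why the fixture has a bias field

A fixed $n$ interacts with signal variability directionally: at high
$\sigma$ the threshold $\mu + 5\sigma$ climbs into the (heterogeneous)
infarct intensity distribution and the measurement underestimates; at low
$\sigma$ the threshold hugs the remote mean and the measurement
overestimates. The *under*estimation channel needs nothing but
overlapping distributions. The *over*estimation channel is subtler: with a
hard-edged phantom and Gaussian remote noise, the probability of a remote
pixel exceeding $\mu + 5\sigma$ is $\approx 3\times10^{-7}$ regardless of
$\sigma$, so low variability alone can never push the measurement above
truth. On real images the excess comes from partial-volume transition
pixels and from remote regions brighter than the ROI used. The phantom
reproduces the second mechanism — the one its feature set contains: the
directionality fixture enables a coil-sensitivity bump (amplitude 0.4,
scale 10 mm) over remote myocardium away from the ROI, with imperfect
nulling (remote mean 0.15). Bright-but-healthy pixels under the bump then
exceed the low-$\sigma$ threshold but not the high-$\sigma$ one. These
fixture parameters were fixed by tail arithmetic before the test was first
run, and are not tuned.

## Determinism

Every slice is a pure function of its spec (including its seed); cohort
generation draws per-slice seeds without replacement under the master seed
before resolving any template ranges, so cohorts are pure functions of
(config, master seed). Studies contain no randomness at all. End-to-end
reruns are bit-identical at the level of masks, counts and outcome tables;
file round trips are lossless for masks and contours and
double-precision-faithful for images.

## File formats

Slices travel as plain-text bundles: a TSV intensity grid, a TSV label
grid (0 background, 1 myocardium, 2 infarct, 3 MVO) and a JSON sidecar
with contours and the generating spec. Plain text keeps the package free
of binary-format dependencies (no NIfTI reader is required anywhere in the
stack), keeps fixtures diffable, and loses nothing at these grid sizes;
externally supplied images in the same grid format load without a
reference mask and support segmentation-only use.

## Known limitations

* Endo/epicardial contour variability — a major error source in its own
  right — is out of scope; contours are taken as given.
* Comparator methods (FWHM, Otsu, EWA, level sets, mixture models) are not
  implemented; the package evaluates one rule, not the field.
* The phantom's lack of gray zone means threshold-position effects at the
  infarct *border* are absent; conclusions about partial-volume behavior
  cannot be drawn from it.
* Per-slice analysis only: no 3-D consistency constraints across a stack.
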