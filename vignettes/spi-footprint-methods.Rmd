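---
title: "Locating aquaculture sulfide footprints from sediment profile imagery"
author: "spiFootprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating aquaculture sulfide footprints from sediment profile imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(spiFootprint)
```

## The problem

Suspended long-line mussel farms deposit faeces and pseudofaeces on the
seafloor. Anaerobic degradation of that organic matter raises the
sediment's acid volatile sulfide (AVS) pool, and sulfidic sediment is
visibly darker. Sediment profile imagery (SPI) photographs a vertical
cross-section of the upper sediment column in situ, so the mean colour
intensity (grey value, 0--255) of the imaged sediment is a rapid proxy
for its AVS content: the darker the sediment, the more sulfide.
Monitoring programmes need two numbers from such a survey: how strongly
the seafloor under the farm differs from background, and how far beyond
the farm boundary the alteration extends — the *footprint*. This
package implements the full analysis chain from raw profile images to a
footprint extent with a confidence interval, and a synthetic-data
generator that makes every stage testable against known ground truth.

## From pixels to grey values

**Colour calibration.** Every profile image carries a reference strip
(six grey swatches spanning 0--255 plus red, green and blue primaries,
rendered on the right edge in the synthetic images). Lighting and
camera response differ between images, so the package models the
distortion per channel as affine (`value = gain * true + offset`),
estimates it by least squares from the measured swatch means against
the reference values, and inverts it on every pixel. Two numerical
details matter. First, 8-bit clipping censors swatches driven past 0
or 255; a censored swatch would bias the regression, so only swatches
whose reference value is strictly inside (0, 255) enter the fit and
measured means within half a grey of the limits are dropped, with at
least three usable swatches required per channel. Second, the affine
model is the package's choice: the reference software behind the
original workflow is proprietary and its correction model
undocumented, so the model is deliberately simple, logged with each
image, and idempotent (calibrating a calibrated image estimates gains
near 1 and offsets near 0).

**Intensity.** Images are converted from RGB to the intensity channel
of the classical HSI space, `I = (R + G + B) / 3`, kept real-valued on
the 0--255 scale. Other intensity definitions can be supplied as
channel weights; the equal-weight form is the default because the
exact HSI variant used by the original imaging software is not
documented.

**Region of interest.** Profile images rarely show a horizontal
sediment surface. The surface contour is detected per pixel column as
the position of the maximum downward intensity drop after median
smoothing (width 9 px, minimum contrast 20 grey values), and a manual
contour always overrides detection. The analysis band then runs from
10 mm below the surface down a further 40 mm, either as a polygon
following the contour (the default — selection is less ambiguous) or
as a rectangle anchored at the deepest surface point. Pixel
coordinates are 1-based with pixel centers at integer positions; ROI
membership is a pixel-center, even-odd polygon test, with band edges
placed at half-integer coordinates so no pixel center ever lies on an
edge. The physical scale defaults to 0.08 mm per pixel, the printed
scale of 300 dpi-class SPI imagery. When a band would run past the
image bottom the default is an error naming the shortfall; an explicit
`clip = TRUE` truncates it instead, which is how a deepest-anchored
rectangle ends up with fewer pixels than the contour-following polygon
on steeply sloped surfaces.

## Grey to AVS

Mean grey converts to an AVS concentration through a site-specific
quadratic calibration, by default
`AVS = 0.0024 * grey^2 - 0.5249 * grey + 28.392` (umol per g), the
published coefficients for the Awakiriapa Bay long-line farm. Two
flags accompany every estimate. `in_range` marks conversions whose
grey value lies inside the calibrated interval; the original
calibration's numeric grey limits were published only graphically, so
the default interval (55, 105) is a package choice, configurable and
clearly not a literature value. `negative` marks negative predicted
concentrations, which are reported rather than clamped: the
calibration's mean 95% individual CI is 0.5 umol/g, so negative
estimates are consistent with true concentrations at or near zero. The
quadratic is monotone decreasing up to its vertex near grey 109, so
darker sediment maps to higher AVS across the working range.

## The footprint boundary: plateau-constrained segmented regression

The central statistic models grey value against signed distance `x`
from the farm boundary (negative inside the farm) as a linear rise
meeting a flat plateau at the breakpoint `psi`:

$$\mathrm{grey}(x) = \beta_{plateau} + \beta_1 \min(x - \psi,\, 0) + \varepsilon$$

The far-field slope is constrained to zero because unaffected
background sediment is assumed to have no long-distance colour trend;
`psi` is then the footprint boundary. For any fixed `psi` the
remaining parameters have a closed-form least squares solution, so the
package profiles `psi`: a coarse grid (default 201 candidates spanning
the identifiable interior of the x range, seeded with the starting
value, default 100 m), then a dense 41-point scan of the winning
bracket followed by golden-section refinement (tolerance 1e-4 m). This
is a deliberate design choice over iterative linearisation: the
profile optimum is global, reproducible, and immune to
local-optimum convergence; ties are broken toward the smallest `psi`.
The profiled search matches an exhaustive 0.01 m grid to within 0.05 m
in the test suite, and recovers noise-free series with SSE below 1e-9.

A fit is declared non-converged — never a silent estimate — when the
breakpoint is unidentifiable: fewer than two points strictly on either
side of the optimum, an optimum at the boundary of the candidate
range, a flat SSE profile, or segmented terms that fail a 95% F screen
against the flat-mean model. The F screen is a pragmatic
identifiability filter, not a formal test (the null distribution of a
profiled breakpoint is non-standard); it reliably flags pure-noise
series while passing any realistic signal. The starting-value scan
(`psiSensitivity()`, default 50--150 m in steps of 10) is retained for
protocol compatibility; since the search is global, all valid starts
agree by construction, and the scan instead reports genuine ambiguity:
a secondary local minimum of the SSE profile within 10% of the global
minimum and separated by more than 5% of the range marks the fit
multimodal rather than averaging competing breakpoints.

**Confidence intervals.** Two methods are offered. The default is a
seeded case-resampling percentile bootstrap (1999 refits by default),
each replicate refitted by the same profiled search and screened for
identifiability; the interval is flagged unreliable when more than 20%
of refits fail. The alternative is the delta method on the linearised
gap-variable parameterisation: refit `y ~ U + V` with
`U = min(x - psi, 0)` and `V = 1(x < psi)` at the estimated
breakpoint, and `SE(psi) = SE(gamma_V)/|beta_1|`. At study scale the
bootstrap interval covers the true breakpoint at its nominal rate
(92--98% across 500 simulated surveys in the acceptance suite), but
its percentile distribution is lumpy — the breakpoint estimator is not
smooth in the resampled data — so bootstrap half-widths are typically
wider than delta half-widths; the two agree to within a factor of two
rather than a few percent, and the delta half-width tracks the true
sampling SD more closely. Both are reported so either convention can
be compared.

## Transect statistics

Grey values are compared across transects with sequential (Type I)
ANCOVA under treatment coding — `grey ~ distance + transect` for the
three strata (overall, inside the farm, outside the farm), and the
full factorial `grey ~ distance * transect * depth` inside the farm —
with each term's sum of squares equal to the RSS reduction over the
model before it (verified against an independent nested-regression
oracle to 1e-8 relative). Distance and depth are continuous
covariates, transect a factor. No multiplicity correction is applied
across the three strata, matching the analysis convention the package
reproduces. Where a transect effect is significant (p < 0.05),
Tukey–Kramer contrasts on covariate-adjusted means use the studentized
range distribution with the model's residual degrees of freedom; for a
two-level factor the adjusted p equals the ordinary t-test p exactly.
The rectangle-vs-polygon ROI comparison uses the classical paired
t-test; identical vectors return t = 0, p = 1, while constant non-zero
differences are an error (t undefined).

## Footprint mapping

Image positions are reduced to signed distances from the farm's
northern boundary: Euclidean point-to-segment distance in a local
equirectangular projection centered on the survey (adequate below
about a kilometre of extent; a warning fires beyond 10 km), negative
inside the farm polygon by an even-odd containment test. Distance is
measured to the boundary line rather than to individual mooring
buoys — the difference is below the survey's positional noise.
Grey values are interpolated onto a metric raster (default 5 m cells)
by either a first-order local polynomial with Gaussian distance
weights (default bandwidth 25 m, at least 6 neighbours, falling back
to a weighted mean at degenerate cells and to inverse-distance
weighting when all points are collinear) or inverse-distance weighting
(default power 2), with cells farther than 100 m from the nearest
observation masked as no-data and values clamped to the grey scale.
The reference interpolation parameters of the original GIS workflow
were not published, so these defaults are package choices exposed in
the configuration. The footprint edge is the iso-contour of the raster
at a threshold midway between the fitted plateau and the inside-farm
mean grey.

## What the synthetic data emulate — and what they do not

The generator is the package's ground truth and its defaults *are* the
study conditions: a rise-to-plateau transect with background
(plateau) 93 grey values, inside-farm mean 61, breakpoint 56 m,
n = 182 points spanning −50 m to 200 m from the boundary, and additive
Gaussian noise clipped to \[0, 255\]. The rise slope is derived from
the background level, the inside-farm mean and the breakpoint
(0.394 grey/m under the default design), and the noise SD (8.8 grey
values) was computed analytically, once, so that the fitted model
explains about 69% of the variance at this design — the calibration
the study conditions prescribe. The three-transect survey uses
per-transect breakpoints of 35, 71 and 19 m, inside-farm means of 58,
59 and 70 grey values, sample sizes 57, 97 and 28, and mean depths
13.6, 15.3 and 15.7 m across a 600 m rectangular farm with its
northern edge at y = 0. Synthetic images place bright, low-texture
water above a configurable surface contour, achromatic sediment with
Gaussian texture around a target grey (the realised post-quantisation
mean is recorded in the sidecar), and the calibration strip, then push
the whole frame through a known affine colour distortion.

Passing tests on these data demonstrate the correctness of the
algorithms, not the realism of the model. Real profile images contain
chromatic sediment, burrows, shell debris, layering and the geometric
signature of a rotating scanner, none of which are emulated; real
transect noise may be autocorrelated along the transect, whereas the
generator draws independent errors; and real surveys have positional
error in the GPS fixes. The noise model (independent, additive,
homoscedastic Gaussian on grey) is the simplest model consistent with
the scatter the workflow is designed for.

## Simulation sizes and numerical choices

The test suite uses problem sizes chosen to exercise every code path
at full study scale while keeping a complete run of the suite around
two minutes: 200 replicate surveys for the bias check of the
breakpoint estimator, 500 surveys with 999 bootstrap refits each for
the interval-coverage check (the package default of 1999 refits is
used for single analyses), 25 random small instances against the
exhaustive-grid oracle, 175 paired synthetic images for the
ROI-method comparison, and 1000 null ANCOVA replicates for the
p-value uniformity check. Synthetic test images are 150 x 120 px —
smaller than field imagery, which only scales pixel counts, not
logic. Other numerical details: the breakpoint grid excludes the two
outermost observations on each side so every candidate is
identifiable; golden-section refinement stops at 1e-4 m; bootstrap
refits use a 121-point grid with 1e-3 m refinement; interpolation
distances below 1e-9 m short-circuit to the data value (the
interpolating property of IDW); and all randomness flows through
explicit seeds recorded in outputs, with generator functions
preserving the caller's RNG state.

## Known limitations

The AVS conversion extrapolates far above its calibrated range for
heavily enriched sediment inside a farm; conclusions there should rest
on grey values, which is exactly why the footprint boundary is
estimated from colour intensity rather than converted AVS. The
plateau constraint assumes the survey reaches unaffected background —
a transect that ends inside the enrichment gradient yields a
non-converged or boundary-flagged fit rather than a usable estimate.
The bootstrap interval's lumpiness at moderate n is inherent to
resampling a non-smooth estimator; the delta interval is provided as
the smoother alternative. Finally, the colour calibration corrects
only per-channel affine distortion; spatially varying illumination
within a frame is not modelled.
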