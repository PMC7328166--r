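---
title: "Calibrating bead density to hydrogel stiffness: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating bead density to hydrogel stiffness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradgel)
```

`gradgel` turns two instrument outputs — confocal stacks of fluorescent
beads embedded in a polyacrylamide (PA) gradient gel, and AFM
force-indentation maps of the same region — into a calibration curve that
afterwards reads local substrate stiffness straight from bead density. This
vignette is the package's own account of the science: the models, what their
parameters mean, the numerical decisions behind the fits, and what the
synthetic generators do and do not tell you about real data.

## Units

All lengths are in µm (pixel sizes, indentation depths, adhesion lengths),
map coordinates in mm (tile centers, AFM locations), Young's moduli in kPa,
forces in nN, and bead densities in beads per 10⁴ µm² — the count in a
100 µm × 100 µm area. The unit identity 1 kPa = 1 nN/µm² makes the Hertz
formula dimensionally closed in these units with no conversion factors.

## From bead stacks to a density map

Each stack is reduced by maximum-intensity projection over z: beads are
bright, sparse, sub-resolution objects, and the projection preserves each
one as a local maximum regardless of its depth. Projections are split into a
2 × 2 grid of sub-images (configurable) before counting; smaller tiles both
localise the density estimate and reduce the chance that a single bad region
contaminates a whole field.

Counting segments the projection at a threshold and labels connected
components. The default threshold is Otsu's method — parameter-free and
invariant under rescaling all intensities — but Otsu alone misbehaves on
very unbalanced histograms (a handful of bright blobs over a large noisy
background can make it split the background mode). The counting threshold is
therefore floored at `median + 5 × MAD` of the image, which also scales
linearly with intensity, so the rescaling invariance survives. A fixed
numeric threshold can replace both. Components larger than 1.5× the median
single-bead area are assumed to be merged beads and are resolved by counting
their internal local maxima, merging maxima closer than `min_separation_px`
(default 3 px, about two PSF sigmas at our default sampling). Counts divided
by the physical sub-image area give beads per 10⁴ µm², positioned at the
tile center in mm.

Counting degrades gracefully but inevitably at high density: once blobs
overlap heavily, local maxima merge and the estimate saturates below the
true density. The Monte-Carlo tests put the reliable regime, at the default
phantom geometry (0.5 µm pixels, 0.3 µm PSF sigma), up to several hundred
beads per 10⁴ µm²; real acquisitions at higher magnification push that
boundary up.

## Hertz fits of AFM force curves

For a spherical indenter of radius `R` on an elastic half-space of Young's
modulus `E` and Poisson ratio `ν`,

\[ F = \tfrac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2}. \]

Three numerical choices matter:

- **Indentation kinematics.** The recorded axis is piezo position; the tip
  indents less than the piezo travels because the cantilever bends. The
  indentation is `δ = (z − z_contact) − (F − baseline)/k`, with `k` the
  spring constant (default 1 N/m, a typical stiff-gel cantilever). With the
  default `k` and nN-scale forces the correction is small but systematic.
- **Contact point.** An exhaustive candidate search over sample indices
  models the curve as a flat baseline followed by a Hertz rise, solving for
  `E` in closed form at each candidate (the model is linear in `E`), and
  keeps the candidate with the lowest total residual sum of squares; a
  bounded one-dimensional refinement between the neighbouring samples then
  removes the sampling-grid quantisation. The procedure is deterministic —
  no derivative heuristics, no smoothing parameters. A curve whose best
  Hertz amplitude is not significantly positive (t < 3) is rejected as
  having no post-contact rise rather than returning a junk modulus.
- **Fit range.** `δ ∈ [0.1 µm, min(2 µm, 0.3 R)]` by default: below 0.1 µm
  the signal is noise-dominated; above 0.3 R the Hertz small-indentation
  assumption fails. At least 8 samples must fall in the window.

`ν` defaults to 0.5 (an incompressible gel) and is overridable. Per-location
replicates (nine indentations in a 3 × 3 grid, 30 µm × 30 µm, in the
default acquisition layout, locations 0.5 mm apart) are consolidated by
their arithmetic mean with the SEM and replicate count retained; a location
where every fit failed stays in the map flagged as missing.

On noise-free forward-model curves the fit is exact to floating-point
precision for any valid `(E, R, ν)` — the estimator is the literal algebraic
inverse of the generator. With 1% force noise the mean recovered modulus
over 100 curves is within a fraction of a percent of truth.

## The calibration families

With `x` bead density and `y` Young's modulus:

- **Linear** `y = a·x + b`, ordinary least squares. Appropriate for narrow
  stiffness ranges (roughly 0.5–22 kPa gradients), where diffusion places
  beads in proportion to the stiff-mix fraction.
- **Logit** `y = y_half + rate · ln((x − x_lo)/(x_hi − x))` on
  `x ∈ (x_lo, x_hi)`, an inverse sigmoid: near-linear around its midpoint
  (where `y = y_half` exactly) and steep near both abscissa limits, so small
  density changes at the extremes accompany large stiffness changes.
  Appropriate for wide ranges (roughly 2–60 kPa). `rate` (kPa) scales the
  steepness; `x_lo` and `x_hi` are the density values at which the modelled
  stiffness diverges, and stiffness is undefined outside them — predictions
  there raise a domain error rather than clipping.

The orientation of the limits is chosen so that stiffness increases with
bead density; with published constants `(y_half = 29.221, rate = 18.884,
x_lo = −179.59, x_hi = 4720)` the curve rises from soft to stiff across
densities of a few hundred to a few thousand beads per 10⁴ µm². Other
sigmoid parameterisations can be fitted externally and wrapped via
`calibration_model()`.

### Fitting the logit without stepping outside its domain

The logarithm is undefined whenever an iterate puts a data point outside
`(x_lo, x_hi)`, so the fit runs in a transformed space where that cannot
happen: `x_lo = min(x) − exp(l_lo)`, `x_hi = max(x) + exp(l_hi)`, and
`rate = exp(l_rate)`. Levenberg–Marquardt (via `minpack.lm`) optimises
`(y_half, l_rate, l_lo, l_hi)` from a starting point that places the limits
10% of the density range outside the data and seeds `(y_half, rate)` by a
linear regression on the induced log term. No silent clipping occurs at any
point. Natural-scale covariance is recovered by the delta method.

### Confidence intervals and bands

Parameter intervals for the logit are Wald intervals computed on the
transformed scale and mapped monotonically back. This matters: the raw-scale
sampling distributions of `rate` and especially of the limits are heavily
skewed at calibration-sized samples, and symmetric raw-scale intervals
undercover badly (≈80% instead of 95% in our simulations), while the
transformed-scale intervals are close to nominal. Profile-likelihood
intervals were evaluated and rejected — the profile machinery fails to
converge on most replicates of this model.

Prediction bands for both families use first-order (delta-method)
propagation of the parameter covariance: the band half-width at density `x`
is `t_{df, 0.975} · sqrt(gᵀ Σ g [+ σ²])`, with `g` the gradient of the
prediction in the parameters and the residual variance `σ²` added for a
prediction (rather than mean-curve) interval. The plotted dashed band is the
mean-curve interval; `validate_calibration()` defaults to the prediction
interval, since a new AFM measurement carries its own noise — in
simulations it contains ≈95% of points drawn from the fitted model's noise
distribution. For the linear family the band is the exact OLS band:
narrowest at the density centroid, growing outward.

A note on identifiability: at small n and realistic noise the logit's
abscissa limits are weakly identified — their estimators are heavy-tailed,
and a minority of replicates place the limits far from the data. Median
recovery is excellent (within a few percent of the abscissa span) but
mean-based bias summaries do not converge at a few hundred replicates. This
is a property of the model family at calibration-scale data, not of the
optimiser; the package's tests therefore assess the limits by median error
and by interval coverage.

### Model selection and validation

`select_calibration()` fits both families and keeps the lower small-sample
AICc, reporting the margin; margins below 2 set a near-tie flag. Validation
of fresh AFM measurements (`validate_calibration()`) flags each
density–stiffness point as inside or outside the band and reports the
fraction inside — the practical check that a stored calibration still
applies to a new gel batch.

## Spatial pairing

Bead-density sub-tiles are aggregated per parent stack (mean ± SEM, n = 4
for the default 2 × 2 split), and each AFM location is matched to the
nearest aggregate within 0.3 mm — just over half the standard 0.5 mm AFM
spacing, so each location matches at most one stack but modest registration
offsets survive. Unmatched locations are reported with a warning and kept in
an attribute, never silently dropped; no match at all is an error.

## Downstream quantifications

**Ratiometric adhesion images.** Each channel is independently
background-subtracted (grayscale opening with a disc — the rolling-ball
idea — default radius 50 px) and masked at a threshold (Otsu per channel by
default; fixed override), keeping supra-threshold values and zeroing the
rest. The per-pixel ratio A/B then follows four cases: both zero → 0;
ratio ≤ 0.1 → 0.1; ratio ≥ 10 (or A > 0 with B = 0) → 10; otherwise the
plain ratio. The output domain is exactly {0} ∪ [0.1, 10]: zero means "no
signal in either channel", and the two clamps bound the display range to two
orders of magnitude. `log_display()` maps positive pixels by log₁₀ onto a
jet-like colour table (0.1 and 10 at the ends, 1.0 at the midpoint) and
renders zeros a fixed grey. Pearson colocalization is offered over all
pixels (the common plugin default) and over the union of the channel masks;
the two can differ a lot for sparse signals — shared empty background
inflates the unmasked coefficient — so both are worth reporting.

**Nuclear-to-cytoplasmic ratio.** Mean signal inside the nucleus mask over
mean signal in a ring obtained by dilating the mask 1 µm and subtracting it;
computed on maximum projections; scale-invariant by construction. Nuclei
whose ring would leave the image are flagged rather than dropped.

**Cell shape.** Area is pixel count × pixel area. Roundness is
`4A/(π·major²)` with the major axis length from second central moments
(4·√eigenvalue, exact for ellipses): 1 for a disc, `b/a` for an ellipse.
This is the common particle-analysis definition; other definitions exist,
and results are comparable only within one definition.

**Adhesion lengths.** Components above a minimum area (default 4 px) are
measured by their geodesic diameter — the longest 8-connected shortest path
through the component, with Borgefors-optimal chamfer weights
(0.9619/1.3604) that bound the orientation-dependent error to about ±4%,
plus one pixel to convert centre-to-centre into end-to-end distance. For
thin, possibly curved adhesions this equals the skeletal length without the
end-erosion bias of morphological thinning; synthetic 3.5 µm bars are
recovered within ~3% at any orientation. This replaces manual freehand
tracing, so absolute comparisons against manually measured lengths should be
validated per dataset.

**Length–stiffness model.** `L = α + β·ln(E)` by least squares, with a
linear-in-E alternative fitted alongside and compared by AICc; `β > 0` is
the signature of mechanoresponsive lengthening that rises steeply at low
stiffness and plateaus at high stiffness. Per-record local stiffness (and
its CI) comes from the density map and calibration via
`attach_stiffness()`, including the soft/stiff stratification thresholds
(< 1 kPa vs > 8 kPa) exposed as plain dplyr filters on the returned tibble.

## The synthetic generators: what they emulate, and what they do not

All generators are deterministic under a fixed seed.

- `sim_bead_stack()` renders a spatial Poisson process of beads (expected
  count = density × area) as isotropic Gaussian blobs (σ = 0.3 µm by
  default) with additive Gaussian noise (default background 10, noise SD 2,
  amplitude 100 — chosen as a realistic bright-bead SNR of ~45; instrument
  noise characteristics are acquisition-specific). Overlapping blobs occur
  at their natural Poisson frequency, so merged-blob handling is exercised.
  It does **not** simulate confocal sectioning, PSF anisotropy, bleaching or
  camera artefacts — passing tests show the counting logic is correct, not
  that any particular microscope meets these noise assumptions.
- `sim_force_curve()` generates Hertz forward-model approach curves with the
  deflection-consistent position axis and additive force noise. No cantilever
  dynamics, adhesion forces, viscoelasticity or drift.
- `sim_gradient()` draws calibration points exactly from a generating model
  plus independent Gaussian noise on each axis — the idealisation underlying
  every recovery and coverage simulation.
- `sim_adhesion_pair()` / `sim_cell_phantom()` rasterise analytic ellipses
  and discs at stated intensities; they provide exact ground truth for
  morphometric code, not realistic cell images.

Default study designs in the tests: the narrow-range (linear) design spans
densities 0–4000 (stiffness ≈ 0.9–18.5 kPa under the published constants);
the wide-range (logit) design spans 500–4200, inside the published abscissa
limits; recovery simulations use 20 points and noise of 10% of the stiffness
range over 200 replicates. Simulation sizes throughout (100-seed Poisson
checks, 100-curve Hertz recovery, 200-replicate coverage, 10⁶-pixel ratio
oracle) were chosen so the full suite runs in about a minute while keeping
Monte-Carlo error well below the asserted tolerances.

## Degenerate inputs and edge behaviour

Empty masks warn and return empty/zero results (a blank image has zero
beads; it is not an error). Curves with no post-contact rise, calibrations
with fewer points than parameters or with degenerate density spread, logit
predictions outside the abscissa limits, and pairings with no match inside
the tolerance are classed errors (`gradgel_fit_error`,
`gradgel_domain_error`, `gradgel_pairing_error`, ...), so callers can react
programmatically. Records that cannot be quantified (nucleus touching the
border, positions outside the density map) are returned flagged, never
silently removed.

## Known limitations

- Bead counting saturates at densities where blobs overlap pervasively;
  calibrations built near that regime inherit a density-dependent bias.
- The logit's abscissa limits are weakly identified from narrow-span data;
  prefer designs that cover the steep ends when the wide-range family is
  expected.
- The delta-method band is first-order; for strongly curved logit fits at
  small n a bootstrap band would be wider in the tails.
- TIFF metadata travels in a JSON sidecar (`<file>.meta.json`), because
  baseline TIFF tags cannot carry z-spacing; files moved without their
  sidecar need an explicit pixel size.
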