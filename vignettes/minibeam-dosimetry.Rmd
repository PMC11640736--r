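---
title: "Methods: primary-standard dosimetry analysis in proton minibeam fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: primary-standard dosimetry analysis in proton minibeam fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minibeamdose)
```

## The measurement problem

Proton minibeam radiation therapy (pMBRT) splits a proton field into
sub-millimetre planar beamlets — here 15 slits, 400 µm wide, at 4 mm
center-to-center pitch — to spare shallow healthy tissue. Realizing
absorbed dose-to-water with a primary-standard graphite calorimeter in such
a field is hard for one dominant reason: the field varies by a factor of
several over fractions of a millimetre, so small detector-positioning
errors translate into large changes in the dose a finite sensitive region
reports.

The quantity this package is built around is the **dose-area product (DAP)
per unit area**: the integral of dose over a detector's circular sensitive
area divided by that area, i.e. the mean dose the detector reports. The
dose-to-water realized by the calorimeter is assembled as a pure product:

$$
D_w \;=\; D_{\mathrm{core}} \cdot \frac{D_w^{MC}}{D_g^{MC}} \cdot
k_{\mathrm{imp}} \cdot k_{\mathrm{gap}} \cdot k_{\mathrm{vert}},
$$

where $D_{\mathrm{core}}$ is the measured dose-to-core,
$D_w^{MC}/D_g^{MC}$ converts graphite dose to water dose,
$k_{\mathrm{imp}}$ and $k_{\mathrm{gap}}$ correct for non-graphite
constituents and for the vacuum gaps of the calorimeter stack, and
$k_{\mathrm{vert}}$ corrects for a vertically displaced mounting position
in a field that is non-uniform along the beamlets. A profile factor
$k_{\mathrm{prof}}$ harmonizes detectors of differing footprint radius
(8.0 mm calorimeter core vs 7.8 mm plane-parallel chamber). Because the
model is a pure product, relative (fractional) uncertainty propagation is
exact and all uncertainty bookkeeping is done in percent at $k=1$, with
quadrature combination.

## The synthetic field generator

No measured film or transport calculation ships with the package; every
analysis stage is exercised on synthetic data whose statistical structure
matches what the analysis assumes.

A minibeam dose map is

$$
D(x, y) = D_{\mathrm{peak}}
\left[ v + (1 - v) \sum_i r_i\, G_i(x) \right]
(1 + g\,y)\; E_y(y)\, E_x(x),
$$

with $G_i$ the 400 µm slit top-hat convolved with a Gaussian of width
`blur_sigma` and normalized to unit peak, $v$ the uniform scatter
background (`valley_fraction`, a fraction of the beamlet peak), $g$ the
linear dose gradient along the beamlets, $r_i$ a linear per-slit amplitude
ramp mimicking a collimator tilt, and $E_y, E_x$ cosine-smoothed (2 mm)
envelopes at the slit ends and the scanned-field edge. Coordinates are
field-centered, $x$ across the slits, $y$ up; the calorimeter's mounted
position is $(0, -11)$ mm.

Parameter defaults and what they emulate:

* `blur_sigma = 0.9` mm for the shallow (2 cm water-equivalent depth,
  mono-energetic) condition and `1.3` mm for the mid-SOBP (10 cm
  water-equivalent) condition. These are calibrations of the surrogate
  chosen so that beamlets are sharply distinct in the first case and still
  distinct but markedly less so in the second; they are not measured
  values.
* `valley_fraction = 0.05` (shallow) and `0.10` (SOBP depth): deeper
  measurement means more scatter filling the valleys. The resulting
  peak-to-valley dose ratios (≈ 4.6 and ≈ 1.5 on the central profile) are
  surrogate properties; the measurements behind the published analysis do
  not state PVDRs at these depths.
* `vertical_gradient = +0.0033`/mm, so the dose 11 mm below center is
  3.6% lower than at center and the vertical correction factor there is
  ≈ 0.964, matching the magnitude seen on measured films. The sign is
  fixed by the $y$-up convention: the correction is below unity only if
  dose falls toward negative $y$.
* `peak_dose = 5` Gy and Gaussian per-pixel noise `noise_sd` (clipped at
  zero dose); a seed is mandatory for any stochastic output and the
  caller's RNG state is never touched.

Depth-dose curves use an analytic Bragg-like shape (a gently rising
entrance channel smoothly cut off past the peak, plus a Gaussian peak
whose width scales with range as ~1.2%, emulating straggling), rescaled so
the distal 80% falloff depth r80 lands exactly on the requested range.
Spread-out Bragg peaks are non-negative-least-squares superpositions of
range-shifted pristine curves, with component ranges overshooting the
plateau's distal end by 2.5 peak widths so flatness (≤ 1%) holds over the
full modulation width. These are implementation inventions that exist to
exercise the r80-matching dose-conversion procedure, not transport
results.

Calorimeter traces emulate both operating modes. Quasi-adiabatic: linear
baseline drift plus a temperature ramp of total height $\Delta T = D/c$
(in mK), shaped by optional energy-layer intensity steps. Active
isothermal: a constant electrical heating baseline minus a power
depression whose trapezoidal integral on the sampled grid equals
$D \cdot m$ exactly — matching the integral at the sample level is what
makes noiseless analysis round-trips exact to machine precision at finite
sampling rates. Defaults ($c = 706$ J kg⁻¹ K⁻¹, $m = 0.74$ g for a 16 mm
diameter, 2 mm thick graphite core, 60 s beam-on) are synthetic fixture
parameters, not measured values.

## Aperture statistics and their numerics

`dap_per_area()` classifies pixels exactly as interior/exterior wherever
the circle cannot cross them (center distance more than half a pixel
diagonal from the radius) and weights the boundary ring by per-pixel
coverage fractions from 4 × 4 subpixel sampling. At film-scan resolution
(600 dpi, 42 µm pixels) the residual integration error is far below the
0.1% tolerance at which the implementation is verified against a dumb
16 × 16 supersampled integrator in the test suite. The disc mean divides
by the coverage-weighted area rather than $\pi r^2$, so a uniform map
returns its value exactly.

Offset scans displace the aperture along one axis (horizontal
−3…+3 mm in 0.5 mm steps at $y = -11$ mm; vertical −13…−9 mm at $x = 0$)
and normalize to the reference position ((0, −11) mm). Between grid
points the scans are interpolated with a shape-preserving monotone cubic
(Fritsch–Carlson), which cannot overshoot between measured offsets.

## Positioning uncertainty

Detector positioning is modelled per axis as Gaussian around the nominal
position with $\sigma = 0.5$ mm (the stated ±1 mm at 95% confidence;
the constructor enforces $2\sigma$ = the stated half-width).
`sample_type_b()` draws positions (default $10^6$ per axis), evaluates
the interpolated normalized scan, and takes the standard deviation of the
sampled relative doses as that axis' Type B; axes combine in quadrature.
Draws beyond the measured scan range are clipped to the range ends and
counted in the output — with the default scans the range spans at least
±4σ, so clipping is a ~$10^{-4}$ tail effect.

For the film-derived factors, `positional_type_b_on_factor()` samples the
**unnormalized** DAP responses of both apertures entering a factor and
recomputes the ratio per draw. The two readings come from separately
positioned set-ups, so the two apertures receive independent positioning
errors. This choice matters: with a common error the vertical-correction
ratio is nearly invariant (the gradient cancels) and the propagated
uncertainty collapses to ~0.006%, while independent errors give the
$\sqrt{2}$-enlarged single-position spread that published uncertainty
budgets for this correction exhibit.

## Correction factors

* `compute_kvert()`: mean over repeated film maps of
  DAP(0, −11)/DAP(0, 0) for the detector's radius; the standard deviation
  of the per-film ratios is Type A. On the noiseless generator this ratio
  is exactly $(1 + g \cdot (-11))$ because the beamlet profile is even in
  $x$, which the tests exploit as a closed form. The factor applies to
  detectors measuring at center for comparison against the displaced
  position; a calorimeter already mounted at (0, −11) in the
  mono-energetic set-up needs no vertical correction, while the SOBP
  set-up (measured at center) carries the calorimeter's own factor.
* `compute_kprof()`: mean ratio of the 8.0 mm to the 7.8 mm footprint DAP
  at the same center.
* `compute_kimp()` / `compute_kgap()`: ratios of externally scored core
  doses between the pure-graphite/full and compensated/pure-graphite
  model geometries; their statistical uncertainties combine in quadrature
  into Type A. The product telescopes exactly to compensated/full.
* `compute_dose_conversion()`: both depth-dose curves are first
  normalized to their own maximum (percentage depth dose), the graphite
  depth axis is scaled by the ratio of distal r80 values, and the curves
  are compared at the reference depth (20 mm mono-energetic, 100 mm
  mid-SOBP). r80 is always taken on the **distal** side of the peak
  (range-like behaviour); proximal crossings are ignored. Linear
  interpolation brackets the r80 crossing; monotone cubics interpolate
  the PDDs at the reference depth. Normalization and range scaling make
  the factor exactly 1 for affinely related curves, which the tests
  assert.

Maximum-deviation sensitivity studies enter the budget as expanded
($k=2$) uncertainties and are halved by `expanded_to_standard()` before
quadrature.

## Calorimeter signal analysis

Quasi-adiabatic: straight lines are fitted to the pre- and
post-irradiation windows (default: the 60 s adjacent to the beam-on
window, boundary samples excluded — they belong to the irradiation) and
both are extrapolated to the irradiation **midpoint**; the radiation-induced
temperature rise is the difference of the two lines there. Extrapolating
to the midpoint cancels any common linear drift exactly, which the tests
verify to $10^{-9}$ relative. Dose is $c \cdot \Delta T$. A negative rise
beyond the noise level is rejected rather than silently returned.

Isothermal: one straight baseline is fitted across pre and post windows
jointly; the dose is the trapezoidal integral of (baseline − power) over
the irradiation window divided by the core mass. Energy-layer steps in the
depression are handled by the same integral without special-casing.

`combine_modes()` averages the two modes, reports the half-difference as
a consistency metric, and flags relative disagreement above 1%.

## Assembly and reporting

`dose_to_water()` validates that exactly the required factor set for the
configuration is present (duplicates, gaps and strays are named in the
error), multiplies, and carries a component table from which the combined
uncertainty is recomputable; serialization writes numbers at full
precision so budgets round-trip bit-exactly. `ratio_report()` forms the
calorimeter-to-chamber dose ratio with the profile factor applied to the
chamber reading and quadrature uncertainty. Reports round values to 4
decimals and uncertainties to one decimal in percent, matching standard
practice in calorimetry factor tables.

## What the surrogate does and does not show

Passing tests on synthetic fields demonstrate that the analysis chain is
numerically correct under the stated field model. They do not certify the
model against measured film. Two known departures:

* Real beamlets have non-Gaussian scatter tails, film has its own noise
  and calibration structure, and measured fields show per-slit asymmetries
  that the linear tilt ramp only caricatures.
* In the idealized periodic field, a 2.5 mm-radius aperture centered on a
  valley (a 2 mm horizontal offset) always reports slightly **more** dose
  than centered on a beamlet: the two flanking beamlets, weighted by
  ~3 mm chords, outweigh one central beamlet at the 5 mm full chord, for
  every blur width (dense quadrature gives ratios falling monotonically
  from 1.18 toward 1 as blur grows, never below 1). Film measurements of
  a small plane-parallel chamber in this geometry are reported to show
  the opposite sign (~8% loss). The large-aperture behaviour (gain of a
  few percent for 7.8–8.0 mm radii, sub-percent change for a 40.8 mm
  radius that encapsulates the field) is reproduced. The corresponding
  sign check in the test suite is asserted as stated and fails on the
  small-aperture clause, documenting the surrogate's limit rather than
  hiding it.

## Problem sizes and tolerances

The test suite rasterizes fixture fields at 0.1–0.25 mm pixels — coarse
relative to a 600 dpi scan but fine relative to every structure in the
field (the narrowest feature after blurring has $\sigma \ge 0.9$ mm) —
and uses $2\times10^5$–$10^6$ Monte Carlo draws for sampling checks;
the acceptance script generates full 600 dpi maps. Supersampling-oracle
agreement is asserted at 0.1%, closed forms at $10^{-6}$–$10^{-12}$,
sampling statistics at 3% relative or 3 standard errors, as appropriate
to each check.
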