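---
title: "Segmental tomography and threshold-based rejection prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmental tomography and threshold-based rejection prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(endmtrack)
```

`endmtrack` measures the central thickness of the endothelium/Descemet
membrane complex (En/DMT) of a corneal transplant from radial anterior-segment
OCT scans, and models how serial En/DMT predicts immune graft rejection. This
vignette is the package's account of its models and the choices behind them.

## The imaging model

A visit is a stack of radial B-scans through the corneal vertex, each an
`H x W` intensity image with depth down the columns. Row `r` of a scan sits
at depth `r * axial_um_per_px`; column `c` sits at signed lateral position
`(c - vertex_column) * lateral_um_per_px` along the cut meridian. Three
interfaces matter: the anterior corneal surface, the anterior interface of
the En/DM complex, and the posterior corneal surface — the last two appearing
as the two most posterior hyperreflective bands of the cornea.

The measurement chain is:

1. **Band detection** (`detect_bands()`). Each A-scan column is smoothed with
   a short boxcar (3 px) and its local maxima with topographic prominence of
   at least `min_peak_prominence` (default 0.2 relative units) become band
   candidates: the shallowest peak is the anterior surface; the last two
   peaks are the En/DM anterior interface and the posterior surface. Columns
   with fewer than three peaks, the saturation column at the vertex, and
   columns whose peaks violate the anterior < En/DM < posterior ordering are
   dropped. Peak rows are refined to sub-pixel precision with a three-point
   quadratic fit on the *log* intensity of the raw profile — exact for a
   Gaussian band cross-section, since the log of a Gaussian is a parabola.
2. **Robust boundary fitting** (`ransac_fit()`). Each interface of each scan
   is fit with a polynomial in the lateral coordinate normalised to
   [-1, 1], estimated by classical RANSAC: `ransac_iterations` (500) minimal
   samples of `poly_degree + 1` candidates, inliers within
   `inlier_threshold_px` (2 axial px), consensus-maximal model kept (ties
   broken by lower inlier RMSE, then earlier iteration), final ordinary
   least-squares refit on the consensus set. Fits whose consensus is below
   `min_inlier_fraction` (0.5) are flagged low-confidence rather than
   rejected.
3. **Surface reconstruction** (`fit_surface_bicubic()`). The fitted curves
   are sampled along their meridians, mapped to Cartesian coordinates, and
   interpolated onto a square grid (50 µm spacing over the 6-mm aperture).
4. **Ray-traced thickness** (`raytrace_thickness()`). At every valid node of
   the layer's upper surface a ray is cast along the local inward unit
   normal; the thickness is the ray length to the lower surface. The En/DM
   map runs from the En/DM anterior interface to the posterior surface, the
   full-cornea map from the anterior to the posterior surface.
5. **Central summary** (`central_mean()`). The reported En/DMT and CCT are
   arithmetic means over valid nodes inside the central 2-mm-diameter disk.

### Why polynomial degree 4

Only "a polynomial model" is prescribed by the method this package
implements, so the degree is an engineering choice. A corneal interface over
a 6-mm chord is close to a spherical cap; its sagitta expansion
`r²/2R + r⁴/8R³ + …` has an `r⁴` term worth tens of microns at the scan edge
for physiological radii (6.5–7.8 mm). A quadratic therefore leaves
systematic residuals of several pixels — larger than the 2-px inlier
threshold, which would make RANSAC discard valid peripheral columns — while
degree 4 leaves only the `r⁶` remainder (below 0.3 µm after projection).
Degree 4 is the default; it is even (corneal meridians are nearly symmetric)
and keeps the minimal RANSAC sample small. Degree is configurable for
flatter or more irregular geometry.

### Why a trend-plus-residual bicubic surface

Radial scans sample the cornea on a polar lattice (meridian angle x signed
radius), not a Cartesian grid. The reconstruction is bicubic in two layers:
a global tensor bicubic trend (`x^i y^j`, `i, j ≤ 3`, least squares) that
captures the corneal shape and is exact for planes and paraboloids, plus
interpolation of the lattice residuals — natural cubic splines along each
meridian and periodic Catmull–Rom cubic convolution across the angle. The
scheme interpolates every input sample, reproduces low-order surfaces to
machine precision, and degrades gracefully: for a sphere the residual layer
only carries the sub-micron `r⁶` remainder of the trend. Nodes outside the
sampled aperture are masked invalid rather than extrapolated.

### Why normal rays, and their numerics

Vertical (axial) distance overestimates layer thickness away from the apex —
by `1/cos θ` for a surface tilted by `θ` — so thickness is measured along the
upper surface's local normal, the convention of normal-distance tomography.
Surface normals come from central differences on the reconstruction grid;
the intersection with the lower surface is bracketed by marching at half the
grid spacing and refined by bisection to 10⁻⁶ µm along the ray. For
concentric spherical shells every normal ray passes through the common
centre, so the traced thickness must equal the radius difference exactly;
the test suite holds the chain to 10⁻³ µm on that case. Rays that leave the
sampled aperture are masked and counted, never silently filled. No
refractive bending at interfaces is modelled: distances are geometric
(a documented limitation shared with the thin posterior layers being
measured, where refraction effects are far below the measurement noise).

Manual expert edits are supported as pinned observations: an edited
candidate replaces the detected one and enters the final refit with
dominating weight, so the refit curve passes through the edits. This
reflects the role of expert correction as authoritative, and with at least
`poly_degree + 1` edited columns the edited points fully determine the
curve.

## The phantom generator

`phantom_spec()` / `make_phantom()` / `render_volume()` build synthetic
volumes with known truth. Interfaces are spherical caps: anterior radius
7.8 mm, posterior radius 6.5 mm, apex corneal thickness 600 µm, and an En/DM
anterior interface concentric with the posterior surface at normal distance
`endmt_true` (default 15 µm) — the concentric construction makes the true
En/DM thickness exactly `endmt_true` everywhere and provides the closed-form
oracle above. Optional excrescences — axisymmetric Gaussian ridges on the
En/DM anterior interface — emulate the nodular posterior bumps seen during
rejection; with excrescences the true central thickness is computed by
normal-ray quadrature against the posterior sphere.

Bands are rendered with Gaussian depth cross-sections (FWHM 4 µm) centred on
the exact, generally sub-pixel interface rows; speckle is multiplicative
log-normal with unit mean; a saturated bright column marks the vertex; and a
configurable fraction of A-scan columns is rendered with all bands displaced
by at least 25 axial px to emulate gross acquisition failures. The default
raster is 8 radial cuts of 1024 x 512 px at 2 µm axial sampling over a 6-mm
scan width; the device raster behind the original measurements is not
public, so these are stand-ins chosen to give sub-micron thickness precision
at desk scale. Rendering is a pure function of the spec (including its
seed), and intensities are pre-quantised to 16 bits so TIFF round trips are
lossless.

What the phantom does *not* emulate: refraction, motion artifacts, axial
signal roll-off, the vendor's proprietary container, or the peripheral
signal loss of real high-risk recipient beds. Passing the recovery tests
therefore demonstrates correctness of the geometry and robustness to
speckle and outliers — not performance on degraded clinical scans.

## The cohort generator and the packaged fixture

`simulate_cohort()` draws longitudinal cohorts under `cohort_config()`.
Defaults encode the study conditions: 60 grafts, 21 rejected (35%), imaging
at postoperative months 1/3/6/9/12, rejection diagnoses snapped to the visit
grid with only pre-rejection measurements retained, 81% of rejected and 18%
of clear grafts ever reaching 19 µm, and crossing-to-rejection lead times
centred on 5.3 months within 2–11. Stable grafts sit near 14 ± 1 µm — kept
below 17 µm so that the swept cutpoints (17–21 µm) retain contrast — because
flagged clear grafts are modelled as an early step to a stable plateau at or
above 19 µm, and flagged rejected grafts as a monotone ramp first reaching
19 µm at the drawn crossing visit. CCT starts near 600 ± 30 µm and declines
by about 2 µm/month with noise in both groups, reflecting postoperative
endothelial recovery; the decline magnitudes are stand-ins.

`fixture_default()` is the deterministic calibrated instance shipped as
`inst/extdata/fixture_cohort.csv` and regenerable byte-for-byte. Its 17
flagged rejected grafts carry a *constructed* (not sampled) lead-time list —
`11, 9, 9, 8, 8, 6, 6, 6, 5, 5, 3, 3, 3, 2, 2, 2, 2` months — whose sum is
90, so the mean is 90/17 = 5.294 (5.3 at reporting precision) with minimum 2
and maximum 11. Lead times on a visit grid are necessarily integers, so
hitting the reported one-decimal mean exactly requires this construction.
The rejection months (five at month 3, seven at 6, six at 9, three at 12)
reproduce the published per-month counts of last pre-rejection visits.
Recipient ages are drawn from truncated normals (rejected 53 ± 15, clear
63 ± 15 years) and transplant types follow the published 43/15/2 split of
penetrating and endothelial keratoplasties.

The default generator leaves age uncoupled from the rejection hazard:
published estimates of the age effect in this population are mutually
inconsistent (a reported risk factor incompatible with the accompanying
per-decade change), so no calibration target exists. An optional
`age_loghr` knob couples age to outcome selection for the stepwise-recovery
simulations.

`cohort_to_volumes()` closes the loop: each visit row becomes a phantom with
matching En/DMT and CCT (flagged visits get a central excrescence whose
contribution to the 2-mm mean is ~0.1 µm), so the imaging chain can be
validated against tabulated cohort values end to end.

## The survival stage

`to_counting_process()` builds `(t_start, t_stop]` rows per graft with the
threshold indicator switching at the first visit at or above the cutpoint
and carried forward between visits — the covariate is only observed at
visits, and no interpolation rule is assumed. Absolute En/DMT values are
thresholded (not change from baseline), matching how the cutpoints are
tabulated. `fit_cox_td()` delegates the partial-likelihood maximisation to
`survival::coxph` with **Breslow** tie handling — the default of the
statistics software traditionally used for such analyses; Efron is a
configuration option — and reports Wald 95% intervals `exp(β ± 1.96 SE)`.
The test suite holds the fit to within 10⁻³ of an independent brute-force
Breslow grid search (step 10⁻⁴) on fixed toy datasets, so the backend is
cross-checked, never trusted blind. Degenerate designs (no covariate
contrast, or all events in one stratum of the binary exposure, where the
partial likelihood is monotone) return an explicit non-identifiable result.

`sweep_cutpoints()` repeats this per cutpoint and records per-row failures
without aborting the sweep; exposure person-time is non-increasing in the
cutpoint by construction, which the tests verify. `flag_rates()` and
`crossing_stats()` compute the descriptive counterparts. `fit_trend()` fits
`measure ~ group * month + (1 | patient)` by REML with Satterthwaite
p-values (`lmerTest`); the group-by-time interaction is the reported trend
contrast. `forward_stepwise()` adds candidates by smallest Wald p below
0.05, testing categorical candidates with a block Wald chi-square, and
always retains the threshold covariate.

## Validation problem sizes and study conditions

The test suite exercises the chain at sizes chosen to balance statistical
resolution against desk-scale runtime:

- Imaging unit tests use a reduced raster (4 cuts, 1024 x 256 px); the
  acceptance-level checks (concentric-shell exactness, robustness at 30%
  speckle with 20% outlier columns over 20 seeds) run at the full default
  raster.
- Cox recovery uses 200 replicates of 200 subjects with a true hazard ratio
  of 10 and piecewise-constant hazards switching at the crossing; the null
  size check uses 1000 cohorts of 60 subjects with crossing patterns drawn
  independently of event times. The null cohorts use a baseline hazard of
  0.05/month (about 30 events per cohort) so that Wald asymptotics are
  adequate — at much lower event counts the Wald test is visibly
  conservative, which is a property of the test, not of the implementation.
- Calibration recovery of the cohort generator averages flag rates over 100
  seeds.

## Known limitations

- Geometric (unrefracted) ray tracing; thickness is reported in optical
  path only insofar as the axial pixel scale already encodes it.
- Central 2-mm zone only; the peripheral graft is neither rendered
  realistically nor measured, mirroring the poor peripheral signal-to-noise
  of high-risk recipient beds. Whether the conventional "central 2 mm"
  denotes a diameter or a radius is ambiguous in parts of the literature;
  this package uses a 2-mm-*diameter* disk and makes it configurable.
- The cohort simulator reproduces summary calibration targets, not
  patient-level biology; hazard-ratio magnitudes estimated from it
  characterise the simulator, not the clinical population.
- The fixture's hazard ratios at the swept cutpoints are in the 10–13 range
  — consistent in sign and scale with threshold effects reported for this
  design, but not calibrated to any published coefficient, since the
  clinical data are not public.
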