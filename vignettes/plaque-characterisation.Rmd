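---
title: "Combined characterisation of calcified plaque: models, parameters and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combined characterisation of calcified plaque: models, parameters and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquemorph)
```

## The problem

Calcification is a marked pathological component of carotid artery plaque,
and its amount, geometry and location are believed to shape how a plaque
deforms and where it ruptures during endovascular treatment.  Because no
single bench modality captures all of that, plaque specimens are
characterised three ways and the results joined per specimen:

* **ATR-FTIR spectroscopy** of the intimal surface quantifies the relative
  concentration of lipid, collagen and mineral through absorbance
  peak-area ratios (Lip:Col and Calc:Col).  The probe has a finite
  penetration depth, so it sees surface chemistry, not deep structure.
* **Micro X-ray CT** of excised sections resolves the internal
  calcification in 3D at ~15.5 µm voxels.  Grey-value thresholds separate
  plaque tissue (324–1249 GV on the calibrated 16-bit scale) from
  calcification (≥ 1250 GV); connected components of the calcification
  mask are individual inclusions; the calcification volume fraction
  (CVF) is calcified volume over total plaque volume.
* **Uniaxial tensile testing** to failure provides the mechanical context:
  Cauchy stress–stretch curves, an initial stiffness used to group
  specimens (LS/MS/HS), and the peak strength.

This package implements each stage as composable, tested functions, plus
synthetic data generators that produce inputs with exact ground truth so
every stage can be validated quantitatively.

## CT morphometry

### Model and measurements

A `voxel_volume` is a 3D grey-value grid with isotropic spacing.
Segmentation is by fixed inclusive bands (`threshold_config()`); a grey
value of exactly 1250 is assigned to calcification so the two bands are
contiguous.  Connected components use 26-neighbour connectivity by
default — the inclusive convention, appropriate for agglomerated
calcification where nodules may touch only at corners; 6- and
18-neighbour variants are available.

Per inclusion the pipeline reports:

* volume $V_p$ = voxel count × voxel volume (mm³);
* surface area $A_p$ from a triangulated isosurface (mm², below);
* sphericity $\psi = \pi^{1/3}(6V_p)^{2/3}/A_p$;
* volume-equivalent diameter $d = (6V_p/\pi)^{1/3}$;
* principal extents $l \ge w \ge t$: peak-to-peak spans of voxel centres
  along the eigenvectors of the coordinate covariance, plus one voxel
  size for the finite voxel extent;
* a geometry class, assigned in a fixed order that makes the classes
  mutually exclusive:
  1. **spherical** if $d <$ 300 µm and $\psi \ge$ 0.85,
  2. **sheet** if $l/w \ge 2$ and $w/t \ge 2$ (the boundary counts as a
     sheet),
  3. **irregular** otherwise.

The 300 µm limit is interpreted on the volume-equivalent diameter (the
natural reading when diameters are derived from measured volumes); a
maximum-extent convention is available via
`morphometry_params(diameter_convention = "max_extent")`.  The
sphericity floor of 0.85 operationalises "close to one" with room for
discretisation: digitised true spheres at 10–20 voxel radii measure
$\psi \approx 0.97$–1.02 here.  All of these are parameters, not
constants, because the conventions differ between laboratories.

### Surface-area numerics

Surface area is the one genuinely delicate measurement.  Counting exposed
voxel faces overestimates a sphere's area by roughly 50% (a staircase in
every direction), which would corrupt $\psi$ beyond use.  The package
instead meshes the 0.5 level set of the component indicator with a
marching-tetrahedra pass (each grid cell split into the six Kuhn
tetrahedra sharing its main diagonal; the level set is triangulated by
linear interpolation along tetrahedron edges).  On a raw binary field the
interpolation degenerates to edge midpoints and the mesh inherits a
systematic orientation bias, so the indicator is first smoothed with an
isotropic Gaussian of `smoothing_sigma = 1.0` voxels.  Measured against
closed forms, the smoothed mesh is within 1.3% of $4\pi r^2$ for a
digitised sphere of radius 10 voxels and within 0.4% at radii 20–40,
with $\psi \to 1$ as the radius grows.

The smoothing has a cost at sharp corners: it rounds box edges, so a
faceted shape must be resolved to a few tens of voxels per side before
its area is within a few percent (a 60×48×36 box measures −3.6%).  For
faceted shapes `smoothing_sigma = 0` (midpoint mesh) is better — boxes
come out within 2% — at the price of the curved-surface bias.  The
default favours curved, blob-like calcifications, which is what the
morphometry is for.

Two documented edge behaviours: components too small for the smoothed
field to reach the iso level fall back to voxel-face area and are
flagged (`area_method = "voxel-faces"`); and for marginally resolved
particles (~3 voxel radius, i.e. d ≈ 100 µm at 15.5 µm voxels) the
voxel-count volume overestimates while the mesh slightly underestimates,
so $\psi$ can exceed 1 by up to ~0.2.  The $\psi \le 1 + \varepsilon$
expectation (with $\varepsilon \approx 0.02$–0.03) applies to particles
resolved at 10+ voxel radii; classification is unaffected because small
true spheres still clear the 0.85 floor with a wide margin.

### Calibration

`calibrate_grey_values()` applies the least-squares linear map from
measured grey values of reference materials (air, water, hydroxyapatite
phantom) to their target values; with two references it interpolates
exactly.  Nothing beyond a linear map is attempted — density-accurate
calibration is out of scope.

## FTIR quantification

Peak areas are trapezoidal integrals of absorbance minus baseline over a
component's window.  The default baseline is the chord between the
window's endpoint absorbances — common ATR practice — with a `"none"`
mode for synthetic work.  Negative net areas are floored at zero with a
warning.  Ratios divide lipid and calcification areas by the collagen
area; a specimen's value is the arithmetic mean of per-location ratios
(mean of ratios, not ratio of mean areas, matching how averaged ratios
are reported for multi-location measurements).

The integration windows default to the standard mid-IR assignments —
lipid ester C=O 1710–1770 cm⁻¹, collagen amide I 1600–1690 cm⁻¹,
phosphate ν3 960–1100 cm⁻¹ — and are deliberately configuration:
instrument software differs in its exact limits, and hard-coding
unverifiable constants would lend them false authority.

Two numerical caveats follow from the window/baseline design.  First,
ratios are exactly invariant under global absorbance scaling (the chord
scales with the spectrum).  Second, with wide windows the chord baseline
is anchored on two single samples, so spectral noise of SD $\sigma$
shifts an area by roughly $\sigma \times$ window-width; quantifying weak
bands in noisy spectra therefore calls for windows matched to the band
support, and the package's noisy-recovery tests do exactly that.

## Mechanics

Stretch is $\lambda_i = (L_0 + d_i)/L_0$ and Cauchy stress is
$\sigma_i = F_i \lambda_i / A_0$ (MPa), using the incompressibility
assumption standard for soft tissue; engineering stress $F_i/A_0$ is
available as a convention switch.  Initial stiffness is the
least-squares slope of $\sigma$ against $\lambda - 1$ over
$\lambda \in [1.0, 1.1]$ — a windowed secant chosen to match the
10%-of-gauge preconditioning regime, since whether a laboratory reports
a tangent, secant or windowed fit is generally unstated; the window is
configurable.  Peak strength is the global stress maximum with a
first-occurrence tie-break.  Stiffness groups use half-open intervals
with breakpoints at 1 and 2 MPa, which cleanly separate the three
observed stiffness levels (0.6–0.75, 1.25–1.6, 3.79 MPa) in the packaged
study table.

## Synthetic data: what it emulates and what it does not

The generators define the validation conditions for every stage.

**Voxel phantoms** (`phantom_spec()`, `generate_phantom_volume()`)
emulate reconstructed 16-bit volumes at 15.5 µm voxels: a cylindrical or
box tissue body, embedded inclusions of the three geometry classes,
per-class grey-level means (background 100, tissue 700, calcification
1800) with additive Gaussian noise (default SD 30 GV), rounded and
clipped to 16 bits.  Inclusions are rasterised at voxel centres; the
ground-truth table carries each inclusion's analytic volume and area
(sphere and sheet closed forms; agglomerate unions have no closed form,
so their truth is the voxelised volume).  `study_phantom_spec()` places
a configurable census — by default 16 spheres of 100–250 µm, 2 thin
sheets of 1600×640×96 µm, 2 compact five-sphere macro-nodes — at random
non-overlapping positions with a two-voxel clearance, keeping every
inclusion at least 20% away from the classification decision boundaries
so that exact class-count recovery is the correct expected outcome.
A 200³ phantom generates in a few seconds and runs through the full
morphometry in about one.

The phantoms deliberately do not simulate X-ray physics: no beam
hardening, no reconstruction artefacts, no partial-volume blur beyond
binary rasterisation, no tissue-preservation shrinkage, and no lipid
contrast (lipid is not separable from tissue in CT at these energies).
Passing phantom tests therefore demonstrates that the measurement
pipeline is correct on clean geometry at scanner resolution — not that
segmentation thresholds transfer to any particular scanner without
calibration.

**Spectra** (`spectrum_spec()`, `generate_spectrum()`) are sums of
area-parameterised Gaussian bands (Lorentzian optional) on a linear
baseline with optional noise, on the 4000–700 cm⁻¹ grid at 2 cm⁻¹.
Band centres default to the standard assignments above.  Real ATR
spectra have broader, overlapping, asymmetric bands and water
interference; the generator's isolated-band default is what makes exact
area recovery a meaningful test, and overlap can be configured when
wanted.

**Mechanical curves** (`mech_curve_spec()`,
`generate_mechanical_curve()`) use the standard exponential stiffening
law $\sigma(\lambda) = a(e^{b(\lambda-1)} - 1)$ truncated at a rupture
stretch, inverted through the same Cauchy definition the analysis uses
(F = $\sigma A_0/\lambda$) so the round trip is exact at zero noise.
The exponential form is a stand-in for measured curves — adequate for
testing conversion, stiffness extraction and peak detection, not a
constitutive claim; parameters give an initial tangent stiffness of
$ab$.

## Study-report aggregates

The packaged `table1.csv`/`table2.csv` fixtures transcribe the study's
per-specimen results.  `group_summary()` reports mean ± sample SD
(n − 1) per stiffness group, flagging singleton groups (SD reported as
0); sample SD is used throughout because it reproduces the printed
summary dispersions (0.09 MPa and 0.13) from the table values.  One
reconciliation worth knowing: the mean of the six two-decimal peak
stresses is 0.392, while the printed overall mean is 0.40 — evidently
averaged from unrounded raw data — so the package treats that mean with
±0.01 and anchors its exact checks on the SDs and the stretch mean
(1.44) instead.  Census entries printed as "-" are absences and count
as 0, giving the spherical-particle total of 505 and a sheet total of 7.
The Ca:P validation compares a region's molar calcium-to-phosphorus
ratio against stoichiometric hydroxyapatite (10/6 ≈ 1.67, pass at or
above, with a 0.005 rounding tolerance so an exact 5/3 passes a
two-decimal threshold); tricalcium phosphate (1.5) fails, as it should.

## Worked example

```{r example, eval = FALSE}
# a noisy 200^3 phantom with a known census, through the full pipeline
spec <- study_phantom_spec(seed = 42)
ph <- generate_phantom_volume(spec)
rep <- run_morphometry(ph$volume)
rep$counts        # spherical 16, sheet 2, irregular 2
rep$cvf           # equals ph$cvf_true to ~1e-14 at these noise levels
head(rep$inclusions)

# FTIR: recover a configured composition
s <- generate_spectrum(spectrum_spec(bands = default_bands(lip_col = 0.67,
                                                           calc_col = 0.24)))
composition_ratios(s)

# mechanics: a curve rupturing at 0.40 MPa, stretch 1.44
curve <- to_stress_stretch(generate_mechanical_curve(
  mech_curve_spec(a = 0.40 / (exp(3 * 0.44) - 1), b = 3, lambda_u = 1.44)))
peak_strength(curve)
```

## Known limitations

* Spatial statistics beyond per-inclusion centroids are not computed.
* Surface areas of marginally resolved (< ~5 voxel radius) or thin,
  sharply faceted components carry several-percent method bias; choose
  `smoothing_sigma` for the shape family at hand.
* Scale equivariance: voxel-size rescaling scales volumes by $s^3$ and
  areas by $s^2$ and leaves $\psi$ unchanged, but the spherical class
  has an absolute 300 µm size threshold, so class labels are equivariant
  only when that threshold is rescaled with the data.
* The calibration is a linear grey-value map; no density scoring of
  calcification is attempted.
* Classifier thresholds (300 µm, $\psi \ge 0.85$, aspect ratio 2) are
  conventions fitted to this kind of specimen, not universal constants.
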