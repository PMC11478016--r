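---
title: "Simulation methods: dose-matched XFET and fan-beam CT of gold nanoparticle phantoms"
author: "xfetsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation methods: dose-matched XFET and fan-beam CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`xfetsim` implements a desk-scale comparison of three imaging chains for
detecting dilute gold nanoparticles in soft tissue:

* **XFET** (X-ray fluorescence emission tomography): a 120-kVp pencil beam
  rasters the object; gold atoms along the illuminated line emit K-alpha1
  fluorescence at 68.8 keV, which is imaged directly through 0.5-mm lead
  slit apertures onto six energy-resolving detector planes. No sinogram and
  no tomographic reconstruction are involved.
* **PCCT / EICT**: curved-detector fan-beam CT of the same object with a
  photon-counting (direct Poisson) or energy-integrating (energy-weighted
  compound Poisson) detector model, reconstructed with short-scan fan-beam
  filtered backprojection.

The two CT chains are approximately dose-matched to the XFET raster by the
areal-fluence rule implemented in `computeIproj()`. Image quality is
summarised as the contrast-to-noise ratio CNR = (C_Au - C_bkg) / sigma_bkg
with Rose-criterion detectability (CNR >= 4, boundary inclusive, because the
criterion is quoted as the *lower limit* of detection), and XFET sensitivity
is condensed into depth-dependent gold detection limits with an exponential
depth extrapolation to the surface.

# Forward models and their assumptions

## Physical constants

Elemental mass attenuation coefficients are shipped as a plain-text table
(`inst/extdata/element_mu_rho.csv`) transcribed from the standard published
compilations on a 10-150 keV anchor grid, with explicit K-edge pairs for
gold (80.725 keV) and lead (88.0 keV); log-log interpolation is used between
anchors, so attenuation is strictly decreasing between edges by
construction. Below 10 keV the table is extended with a photoelectric E^-3
term plus the exact Klein-Nishina incoherent term; this region carries
essentially no beam fluence after filtration and only matters for the dose
tally's low-energy tail. L-edge fine structure of gold and lead (below
~15 keV) is smoothed over. The table provenance is recorded in the count
volume metadata.

The mixture rule mu/rho = sum_i w_i (mu/rho)_i is exact and linear in the
mass fractions; gold admixture replaces host mass at the host density
(dilute, <= 4 wt% here) and modifies both attenuation and fluorescence
production.

Fluorescence production uses the K-shell photoelectric component only,
modelled as the tabulated K-edge jump scaled by (E_K / E)^2.55, times the
K fluorescence yield omega_K = 0.96 and the K-alpha1 branching fraction
0.47. Only K vacancies can yield K-alpha1 photons, so using the total
photoelectric coefficient would overcount production by the L/M shell
share. A single emission line at 68.804 keV is modelled (no K-alpha2 /
K-beta, matching a single fluorescence energy bin).

## Tube spectrum

No spectrum model is prescribed for the study, so `generateSpectrum()` uses
a filtered-Kramers tungsten-anode continuum: fluence per 1-keV bin
proportional to (kVp - E)/E, attenuated by an aluminium-equivalent inherent
filtration (default 2.5 mm). Characteristic tungsten lines are not
modelled. Two conventions matter:

* **Histories scale the full beam.** A low-energy cutoff (the XFET runs use
  65.263 keV, kept as a plain configuration value) zeroes bins *without*
  rescaling, so a truncated spectrum still represents an "equivalent"
  full-beam history count. All dose matching and dose tallies refer to
  full-beam histories.
* The fraction of counts above 65.263 keV is spectrum-model dependent; this
  model puts roughly a quarter of the counts there. It is reported by
  `spectrumFractionAbove()`, never asserted.

## XFET expectation model

`xfetExpectedCounts()` is an analytic-expectation model with Poisson count
sampling (`sampleCounts()`), replacing photon-history Monte Carlo so that
the study's full 1.25e8 histories per beam position cost nothing at run
time. Per beam position:

1. **Beam transport**: Beer-Lambert attenuation of the entrance spectrum
   down the axis-parallel voxel column, fluence evaluated at voxel centres.
2. **Fluorescence**: first-order (thin-voxel) production
   fluence x tau_K x voxel length x omega_K x b_Kalpha1. With voxels
   <= 1 mm and gold <= 4 wt% the first-order error is below 1%, and the
   linearity underpins the CNR-concentration linearity the analysis relies
   on.
3. **Single-scatter Compton background**: Klein-Nishina rate times electron
   density at the scattering angle to each detector plane
   (theta = 90 deg +/- atan(2z / (d1+d2)) for an emission at axial offset
   z), with the scattered energy binned at 1 keV. Incident 1-keV bins are
   sub-sampled 8x before binning because the Compton energy mapping is
   compressive; without this the fluorescence bin would alias ~50% excess
   scatter relative to its neighbours and bias the background subtraction.
   Multiple scatter is not modelled; this is the main fidelity limit when
   comparing absolute CNRs to full Monte Carlo.
4. **Slit acceptance**: the solid angle of the open slit from the emission
   point (midpoint quadrature across the 0.5-mm width, closed form along
   the 46-mm length), with the unit-magnification mapping z -> -z onto
   1-mm detector columns; emissions mapping off the detector are lost.
5. **Exit attenuation**: the 68.8-keV photons are ray-marched on the voxel
   grid to each of the six planes (step = half voxel, nearest-neighbour
   sampling). The window bins 66-72 keV differ by < 1% in tissue
   attenuation, so the line energy is used for all of them.
6. **Aperture leakage**: emissions toward closed aperture regions are
   transmitted through 1 mm of lead (~1.6%) into all detector columns,
   reproducing the axial streak mechanism of high-gold lines.

Detector rows and the six planes are summed; detectors are ideal (100%
counting efficiency, perfect 1-keV binning), matching the idealised
comparison. The hexagon's azimuthal orientation only perturbs the scatter
asymmetry and defaults to plane normals at 0, 60, ..., 300 degrees.

Image formation (`formRawImages()`, `subtractBackground()`,
`rebinAxial()`): the 68-69 keV image minus the Gaussian-smoothed average of
the 67-68 and 69-70 keV images (sigma = 1 pixel), rebinned axially 1 mm ->
2 mm. Smoothing is per axial slice ("across the object plane"); reflective
padding preserves constants so spatially constant scatter cancels exactly.
Negative corrected values are kept for unbiased ROI statistics. No
attenuation correction is applied anywhere.

## Fan-beam CT

Geometry (`ctGeometry()`): SID 100 mm, SDD 200 mm, 1024 equiangular
channels over a 19.37-deg fan, 438 views over 219 deg (more than
180 deg + fan). The slab protocol forward-projects 32 sub-slices of
0.0625 mm through a 2-mm slab (`slabOffsets()`, `contrastDepthSlice()`)
with Siddon's exact voxel traversal (compiled), decomposed into host and
gold basis path lengths so the polychromatic exponential is an outer
product over energy bins. Expected counts are summed over sub-slices before
Poisson sampling, which is exactly equivalent to sampling each sub-slice
and summing counts (`slabSum()` is provided for count data).

Detection (`ctDetect()`): PCCT draws K ~ Poisson(sum_E lambda_E); EICT
draws S = sum_E E k_E with independent k_E ~ Poisson(lambda_E). No
scatter, electronic noise, pile-up or charge sharing.

Beam-hardening correction (`waterCalibration()`,
`beamHardeningCorrect()`): -ln(S / S_air) is mapped through a fourth-degree
zero-intercept polynomial fitted on 0-40 mm calibration slabs so that a
slab of the calibration material maps to mu(E_ref) x thickness, with E_ref
the fluence-weighted mean energy (any fixed reference only rescales the
image and cancels in CNR). Water is the default calibration material; the
analysis pipeline calibrates on ICRP soft tissue (the phantom host) because
the 6% density mismatch of a water calibration leaves a radial cupping bias
comparable to the smallest gold contrasts, which would scramble the
CNR-concentration linearity across sphere positions. Gold-induced
hardening streaks between the high-concentration spheres remain, as
expected. Non-positive channels are flagged and interpolated from their
neighbours before the logarithm.

Reconstruction (`ffbpReconstruct()`): cosine pre-weighting (D cos gamma),
the exact equiangular band-limited ramp kernel, a sinc apodization window
with a configurable cutoff fraction, and distance-weighted (1/L^2)
backprojection (compiled). Two numerical choices deserve note:

* **Short-scan redundancy.** The 219-deg arc over-scans the 199.4-deg
  minimum; rays measured twice are weighted by smooth pairwise
  normalisation w = t(beta) / (t(beta) + t(beta_conj)) with a sin^2 taper
  (conjugate view beta + pi + 2 gamma, wrapped into the arc), a generalised
  Parker weighting that is exact for any over-scan by construction. Without
  it the doubly-measured wedge biases the image.
* **The sinc window sets the target resolution.** The detector samples at
  0.033 mm at the isocenter while images are reconstructed at 0.5 mm or
  0.125 mm; the window is what band-limits the ramp to the requested grid.

A noise-free monoenergetic scan of a 32-mm water cylinder reconstructs the
central ROI to within 2% of the true attenuation coefficient, and a small
off-centre disk is localised to well within one voxel (both in the test
suite).

## Dose matching and dose tally

`computeIproj()` evaluates the areal-fluence chain N = Ib / A0,
wiso = gamma_fan SID / N_channels, Iproj = N h wiso / N_proj. With the
study inputs (Ib = 1.25e8, A0 = (0.5 mm)^2, h = 0.0625 mm) the continuous
value is 2355.499; the mouse-phantom inputs (A0 = (1 mm)^2, h = 0.125 mm)
give exactly half, 1177.750. The slice width h for the mouse protocol is an
inference from the published per-channel count, recorded as such. Both the
continuous value and a nearest-integer convenience field are returned.

`estimateDose()` is a primary-beam kerma tally: deposited energy
fluence x E x (mu_en/rho) x rho x dz along each attenuated beam path, with
the soft-tissue mass energy-absorption table used for all tissues, summed
over raster positions and divided by the phantom mass. It omits
scattered-photon transport and therefore underestimates dose; it is
order-of-magnitude honest (the acceptance check requires a factor of two)
and nothing finer. `foldIncrease()` and `localDose()` implement the
partial-FOV reporting conventions (nearest-integer fold; mGy -> cGy).

# The synthetic phantoms

`buildContrastDepthPhantom()` builds the quantitative phantom: a 32-mm
soft-tissue cylinder, 90 mm long (the four stated beam depths need >= 84 mm;
90 gives margin), with 4-mm gold spheres at 4.0, 2.0, 1.5, 1.0, 0.5 and
0.05 wt% centred at beam depths 3.25, 28.75, 54.25 and 79.75 mm. All four
depth planes coexist in one phantom, so a single raster scan yields every
depth; the published description is ambiguous on this point and the
single-phantom choice is ours. The transverse layout places the 24 spheres
on two rings (radius 13 mm with 15 slots, radius 8.5 mm with 9 slots),
which guarantees pairwise-disjoint transverse footprints (minimum
centre-to-centre distance 4.5 mm), keeps every sphere >= 1 mm inside the
wall, and keeps the inner ring clear of the central background ROI. Each
depth plane holds all six concentrations. ROIs follow the published
protocol: circular gold ROIs of the insert diameter, one central background
ROI three times larger ("larger" is all that is stated; 3x keeps it clear
of the inner ring).

`buildMousePhantom()` is a procedural stand-in for a licensed whole-body
mouse phantom: an elliptical body of ICRP soft tissue with ellipsoidal
brain, spine, lungs, heart, liver, spleen, kidneys, hind-leg muscle with an
embedded spherical tumour, and a fat depot, loaded at 4 wt% (kidneys),
0.75 wt% (spleen, lungs, heart, tumour) and 0.12 wt% (liver), with square
ROIs over the kidneys, tumour and background abdomen. It reproduces organ
scale, tissue classes and gold loadings - not anatomy - so absolute CNRs
from it are qualitative only.

Both builders are deterministic: identical arguments give bit-identical
grids. The CT chain samples the same sphere specification analytically at
its own pitch (`contrastDepthSlice()`), so forward projection is not tied
to the XFET voxelisation.

**What passing tests do and do not show.** The generator reproduces the
study geometry, concentrations, dose accounting and noise mechanisms; it
does not emulate multiple scatter, detector response, anatomical texture,
motion, or beam polychromatic fine structure. Passing the acceptance
checks therefore demonstrates correctness of the pipeline and qualitative
fidelity (orderings, linearity, exponential depth structure, dose scale) -
not that a physical scanner would produce these exact CNRs.

# Numerical choices and degenerate inputs

* Voxel pitch 0.5 mm for the contrast-depth phantom (must divide the 4-mm
  spheres and the 1-mm detector columns), 1 mm for the mouse.
* Scatter kinematics sub-sampling 8 per 1-keV bin (aliasing < 2% of the
  background afterwards); slit-acceptance quadrature 8 midpoints across the
  width; exit marching at half-voxel steps.
* Redundancy taper width (arc - 180 deg)/2 - half fan; pairwise
  normalisation makes the pair weights sum to one regardless.
* Sinc-window cutoff defaults to the full detector band for fidelity tests;
  the analysis reconstructions at 0.5 / 0.125 mm are insensitive to it
  within replicate error (checked).
* Degenerate inputs error early: empty spectra (cutoff >= kVp), zero-length
  rays, non-positive dose-matching inputs, empty ROIs, zero background
  standard deviation (undefined CNR), non-increasing CNR lines (no
  detection limit), non-positive limits (no exponential fit).
* Rebinned axial lengths that do not divide pad with zeros and warn.
* Replicates: five noise realisations per modality, matching the study's
  uncertainty convention; seeds are explicit arguments everywhere.

# Problem sizes used in the checks

The acceptance suite runs the full study conditions: 64 x 64 beam positions
x 1.25e8 histories (analytic expectation), five Poisson realisations, a
4x-histories sweep, 32 CT sub-slices forward-projected at 0.125 mm onto
438 x 1024 rays with five EICT and five PCCT realisations reconstructed at
64 x 64 (plus five PCCT replicates at 256 x 256), the noise-model oracles at
10^4 replicates, and 1000-ray traversal checks. Unit tests use small toy
slabs and reduced geometries.

# Known limitations

* Single-scatter background only; no multiple scatter, coherent scatter,
  Doppler broadening, or K-alpha2/K-beta lines.
* Ideal detectors in both chains (no energy response, charge sharing,
  pile-up, electronic noise); the published comparison makes the same
  idealisation.
* Primary-beam-only dose tally with soft-tissue energy-absorption weighting
  for all tissues.
* The tube spectrum is a continuum model; absolute spectrum-dependent
  quantities (e.g. the fraction above the simulation cutoff) differ from
  other spectrum models.
* The attenuation tables are transcriptions at anchor energies, not a live
  cross-section library; interpolation error is largest near the smoothed-
  over L edges of gold and lead.
* The mouse phantom is schematic; joint attenuation/metal reconstruction
  and spectral material decomposition are out of scope.
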