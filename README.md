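# xfetsim

Simulation and contrast analysis for X-ray fluorescence emission tomography
(XFET) compared against dose-matched fan-beam CT.

## The problem

Gold nanoparticles are used preclinically as radiosensitisers, photothermal
agents and drug carriers, and mapping dilute gold (well below 1% by weight)
in soft tissue is beyond routine CT. XFET images metal directly: a 120-kVp
pencil beam rasters the object, gold atoms along the illuminated line emit
K&alpha;1 fluorescence at 68.8 keV, and slit apertures in front of
energy-resolving detector rings map each emission back to its axial position
— no sinogram, no tomographic reconstruction. The open question for anyone
planning preclinical work is *when* XFET beats conventional energy-
integrating CT (EICT) or photon-counting CT (PCCT) at matched dose, since
the pencil beam attenuates with depth while fan-beam CT does not.

`xfetsim` is for imaging physicists who want a desk-scale, fully scripted
version of that comparison: synthetic phantoms, both forward models, the
dose-matching arithmetic, and the detectability analysis, each piece
individually testable.

## What it computes

* **Phantoms** — a 3.2-cm soft-tissue cylinder with 4-mm gold spheres
  (4.0–0.05 wt%) at beam depths 3.25–79.75 mm, transversely non-overlapping
  (`buildContrastDepthPhantom()`), and a procedural mouse-like phantom with
  gold-loaded organs (`buildMousePhantom()`).
* **XFET forward model** — analytic-expectation pencil-beam transport,
  first-order K-shell fluorescence production, single-scatter Compton
  background via Klein–Nishina, slit solid-angle acceptance with 1:1
  inverted axial mapping, lead-aperture leakage, Poisson count sampling;
  image formation with adjacent-bin Compton background subtraction
  (Gaussian-smoothed, &sigma; = 1 pixel) and 1→2 mm axial rebinning.
* **CT forward model** — Siddon raytracing of 32 thin sub-slices per 2-mm
  slab, PCCT (Poisson) and EICT (energy-weighted compound Poisson)
  detection, fourth-degree water-based beam-hardening correction, and
  short-scan fan-beam filtered backprojection with a sinc window
  (219° arc, 1024 channels, 438 views).
* **Dose matching** — the areal-fluence rule
  `N = Ib/A0`, `wiso = γ_fan·SID/N_channels`, `Iproj = N·h·wiso/N_proj`,
  plus a primary-beam dose tally and partial-FOV dose accounting.
* **Metrics** — ROI statistics, `CNR = (C_Au − C_bkg)/σ_bkg`, Rose-criterion
  detectability (CNR ≥ 4), CNR-vs-concentration fits, detection limits and
  their exponential depth extrapolation, and cross-modality comparison
  reports.

## Worked example

Dose-match the CT acquisition to the XFET raster, run an XFET scan of the
contrast-depth phantom, and read off CNRs at the shallow (3.25 mm) depth:

```r
library(xfetsim)

dm <- computeIproj(ib = 1.25e8, a0 = 0.5^2, h = 0.0625)
dm
#> Dose matching (areal-fluence match of CT to the XFET raster):
#>   Ib = 1.25e+08 photons over A0 = 0.25 mm^2  ->  N = 5e+08 /mm^2
#>   wfan = 67.6141 mm, w = 0.0660294 mm, wiso = 0.0330147 mm
#>   Iproj = N h wiso / Nproj = 2355.499101  (nearest integer 2355)

phantom  <- buildContrastDepthPhantom()
spec     <- generateSpectrum(120, filtrationMmAl = 2.5,
                             cutoff = 65.263, histories = 1.25e8)
expected <- xfetExpectedCounts(phantom, spec)          # ~3 s
image    <- formXfetImage(sampleCounts(expected, seed = 1))

rois    <- phantomRois(phantom)
shallow <- rois[rois$plane == 1, ]
bkg     <- shallow[shallow$role == "background", ]
zc      <- colSums(matrix(expected@axialCoords, 2)) / 2
plane   <- imageValues(image)[, , which.min(abs(zc - bkg$z))]
cnrs    <- sapply(which(shallow$role == "gold"), function(i)
  cnrFromImage(plane, expected@beamX, expected@beamY, shallow[i, ], bkg)$cnr)
data.frame(gold_wt_pct = 100 * shallow$goldFraction[shallow$role == "gold"],
           cnr = round(cnrs, 2), detectable = roseDetectable(cnrs))
#>  gold_wt_pct   cnr detectable
#>         0.05  0.03      FALSE
#>         0.50  2.86      FALSE
#>         1.00  6.61       TRUE
#>         1.50 10.01       TRUE
#>         2.00 13.06       TRUE
#>         4.00 24.55       TRUE

detectionLimit(100 * shallow$goldFraction[shallow$role == "gold"], cnrs)$limit
#> [1] 0.62   # wt% gold at the Rose criterion, 3.25 mm beam depth
```

CNR rises linearly with gold concentration; spheres at or above ~1 wt% clear
the Rose criterion at this depth and dose, and the fitted detection limit at
3.25 mm is about 0.6 wt%. Repeating the readout at the deeper planes shows
the CNRs fall monotonically with beam depth (the pencil beam attenuates),
which is where the dose-matched CT chains (`forwardProject()`, `ctDetect()`,
`beamHardeningCorrect()`, `ffbpReconstruct()`) eventually overtake XFET.

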