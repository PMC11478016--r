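#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib xfetsim, .registration = TRUE
NULL

#' Material: an elemental mixture with a density
#'
#' A material is a set of elemental mass fractions plus a bulk density.
#' Mass fractions must sum to one (within 1e-9) and the density must be
#' positive. Materials are usually obtained from the packaged ICRP/ICRU
#' registry via [material()] rather than constructed by hand.
#'
#' @slot name character label.
#' @slot composition named numeric vector of elemental mass fractions.
#' @slot density bulk density in g/cm^3.
#' @export
setClass("Material",
  representation(name = "character", composition = "numeric", density = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@composition) == 0 || is.null(names(object@composition)))
      msg <- c(msg, "composition must be a named numeric vector")
    if (abs(sum(object@composition) - 1) > 1e-9)
      msg <- c(msg, "mass fractions must sum to 1 within 1e-9")
    if (any(object@composition < 0))
      msg <- c(msg, "mass fractions must be non-negative")
    if (length(object@density) != 1 || !is.finite(object@density) || object@density <= 0)
      msg <- c(msg, "density must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Spectrum: tabulated photon fluence per 1-keV energy bin
#'
#' Fluence is stored per uniform 1-keV bin from 0 to the tube potential.
#' Bins above the kVp and below the low-energy cutoff hold zero fluence.
#'
#' @slot energyEdges bin edges in keV (uniform 1-keV spacing).
#' @slot fluence photons per bin (per beam position).
#' @slot kvp tube potential in keV.
#' @slot cutoff low-energy cutoff in keV (bins strictly below hold zero).
#' @export
setClass("Spectrum",
  representation(energyEdges = "numeric", fluence = "numeric",
                 kvp = "numeric", cutoff = "numeric"),
  validity = function(object) {
    msg <- character()
    ne <- length(object@energyEdges)
    if (ne < 2 || any(diff(object@energyEdges) <= 0))
      msg <- c(msg, "energy edges must be strictly increasing")
    if (length(object@fluence) != ne - 1)
      msg <- c(msg, "fluence length must equal number of bins")
    if (any(object@fluence < 0)) msg <- c(msg, "fluence must be non-negative")
    lo <- object@energyEdges[-ne]
    if (any(object@fluence[lo >= object@kvp] > 0))
      msg <- c(msg, "fluence must be zero at and above kVp")
    hi <- object@energyEdges[-1]
    if (any(object@fluence[hi <= object@cutoff] > 0))
      msg <- c(msg, "fluence must be zero below the cutoff")
    if (length(msg)) msg else TRUE
  })

#' VoxelPhantom: voxelised material and gold maps
#'
#' A 3D grid of material identifiers together with a congruent grid of gold
#' weight fractions, a physical voxel pitch and an origin. Axes are
#' (x, y, z) with z the beam / long axis. `materials` maps material id
#' (grid value) to a [Material-class]. Optional metadata: `inserts` (one row
#' per gold sphere) and `rois` (region-of-interest specifications).
#'
#' @slot materialId 3D integer array of material ids.
#' @slot goldFraction 3D numeric array of gold weight fractions.
#' @slot pitch voxel pitch in mm per axis (length 3).
#' @slot origin coordinates of the centre of voxel (1,1,1) in mm.
#' @slot materials list of Material, indexed by material id.
#' @slot inserts data.frame of sphere inserts (may have zero rows).
#' @slot rois data.frame of ROI specifications (may have zero rows).
#' @export
setClass("VoxelPhantom",
  representation(materialId = "array", goldFraction = "array",
                 pitch = "numeric", origin = "numeric",
                 materials = "list", inserts = "data.frame", rois = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@materialId), dim(object@goldFraction)))
      msg <- c(msg, "material and gold grids must be congruent")
    if (length(dim(object@materialId)) != 3)
      msg <- c(msg, "grids must be 3D")
    if (length(object@pitch) != 3 || any(object@pitch <= 0))
      msg <- c(msg, "pitch must be three positive numbers")
    if (any(object@goldFraction < 0) || any(object@goldFraction > 0.04 * (1 + 1e-6)))
      msg <- c(msg, "gold fraction must lie in [0, 0.04]")
    ids <- unique(as.vector(object@materialId))
    if (any(ids < 1) || any(ids > length(object@materials)))
      msg <- c(msg, "material ids must index the materials list")
    if (length(msg)) msg else TRUE
  })

#' XFETGeometry: slit-aperture ring and detector parameterisation
#'
#' Six detector planes arranged hexagonally around the pencil-beam axis,
#' each behind a 1-mm lead aperture with a single slit at axial coordinate 0.
#' Unit magnification (d1 = d2) maps an emission at axial coordinate z to the
#' detector column at -z.
#'
#' @slot d1 isocenter-to-aperture distance in mm.
#' @slot d2 aperture-to-detector distance in mm.
#' @slot slitWidth slit width in mm (axial direction).
#' @slot slitLength slit length in mm (transverse direction).
#' @slot apertureThickness lead aperture thickness in mm.
#' @slot nPlanes number of detector planes.
#' @slot planeAzimuthDeg azimuths of the plane normals in degrees.
#' @slot detColumns number of detector columns (1 mm each, along the beam axis).
#' @slot detRows number of detector rows (2 mm each, transverse).
#' @slot columnPitch detector column pitch in mm.
#' @slot rowPitch detector row pitch in mm.
#' @slot energyBinWidth energy bin width in keV.
#' @export
setClass("XFETGeometry",
  representation(d1 = "numeric", d2 = "numeric", slitWidth = "numeric",
                 slitLength = "numeric", apertureThickness = "numeric",
                 nPlanes = "numeric", planeAzimuthDeg = "numeric",
                 detColumns = "numeric", detRows = "numeric",
                 columnPitch = "numeric", rowPitch = "numeric",
                 energyBinWidth = "numeric"),
  validity = function(object) {
    msg <- character()
    if (abs(object@d1 - object@d2) > 1e-9)
      msg <- c(msg, "unit magnification requires d1 = d2")
    if (object@slitWidth <= 0 || object@apertureThickness <= 0)
      msg <- c(msg, "slit width and aperture thickness must be positive")
    if (length(object@planeAzimuthDeg) != object@nPlanes)
      msg <- c(msg, "one azimuth per detector plane required")
    if (length(msg)) msg else TRUE
  })

#' RasterPlan: pencil-beam raster positions and per-position histories
#'
#' @slot positions two-column matrix of transverse beam positions (x, y) in mm.
#' @slot step raster step in mm.
#' @slot histories photon histories per beam position (full, untruncated beam).
#' @slot seed integer seed for Poisson sampling.
#' @export
setClass("RasterPlan",
  representation(positions = "matrix", step = "numeric",
                 histories = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@positions) != 2) msg <- c(msg, "positions must be an (n x 2) matrix")
    if (object@step <= 0) msg <- c(msg, "step must be positive")
    if (object@histories < 0) msg <- c(msg, "histories must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' CountVolume: energy-binned detector counts per beam position
#'
#' Raw (or expected) detector counts indexed (beam x, beam y, axial position,
#' energy bin), with detector rows and the six planes already summed.
#'
#' @slot counts 4D non-negative array.
#' @slot axialPitch axial pitch in mm (detector column width).
#' @slot axialCoords axial coordinates (mm, slit frame) of the axial bins.
#' @slot energyEdges energy bin edges in keV.
#' @slot beamX,beamY raster coordinates in mm.
#' @slot meta list of provenance metadata (geometry, histories, seed, ...).
#' @export
setClass("CountVolume",
  representation(counts = "array", axialPitch = "numeric", axialCoords = "numeric",
                 energyEdges = "numeric", beamX = "numeric", beamY = "numeric",
                 meta = "list"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@counts)) != 4) msg <- c(msg, "counts must be 4D")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
    d <- dim(object@counts)
    if (d[1] != length(object@beamX) || d[2] != length(object@beamY))
      msg <- c(msg, "beam coordinate lengths must match counts")
    if (d[3] != length(object@axialCoords))
      msg <- c(msg, "axial coordinate length must match counts")
    if (d[4] != length(object@energyEdges) - 1)
      msg <- c(msg, "energy edges must bound the energy bins")
    if (length(msg)) msg else TRUE
  })

#' XFETImage: directly formed 3D metal image
#'
#' Values indexed (beam x, beam y, axial). Negative values are permitted
#' only after Compton-background subtraction.
#'
#' @slot values 3D numeric array.
#' @slot axialPitch axial pitch in mm.
#' @slot provenance list: energy window, correction and rebin flags.
#' @export
setClass("XFETImage",
  representation(values = "array", axialPitch = "numeric", provenance = "list"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3) msg <- c(msg, "values must be 3D")
    if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
    corrected <- isTRUE(object@provenance$backgroundSubtracted)
    if (!corrected && any(object@values < 0))
      msg <- c(msg, "negative values allowed only after background subtraction")
    if (length(msg)) msg else TRUE
  })

#' CTGeometry: curved-detector fan-beam scanner
#'
#' @slot sid source-to-isocenter distance in mm.
#' @slot sdd source-to-detector distance in mm.
#' @slot nChannels number of detector channels.
#' @slot fanAngleDeg full fan angle in degrees.
#' @slot nViews number of projection views.
#' @slot arcDeg gantry arc in degrees (must be >= 180 + fan angle).
#' @slot channelHeight detector channel height in mm (phantom slice width).
#' @export
setClass("CTGeometry",
  representation(sid = "numeric", sdd = "numeric", nChannels = "numeric",
                 fanAngleDeg = "numeric", nViews = "numeric", arcDeg = "numeric",
                 channelHeight = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(object@sdd > object@sid && object@sid > 0))
      msg <- c(msg, "need SDD > SID > 0")
    if (object@arcDeg < 180 + object@fanAngleDeg - 1e-9)
      msg <- c(msg, "arc must be at least 180 deg + fan angle")
    if (length(msg)) msg else TRUE
  })

#' Sinogram: CT projection data
#'
#' `values` is an (nViews x nChannels) matrix. `kind` records the stage:
#' "expected" (noise-free expected signal), "counts" (noisy detected signal)
#' or "lineintegral" (after log-normalisation / beam-hardening correction).
#'
#' @slot values numeric matrix (views x channels).
#' @slot mode detection mode, "eict" or "pcct" ("" for line integrals).
#' @slot kind one of "expected", "counts", "lineintegral".
#' @slot iproj photons per channel per view delivered (per slice stack).
#' @slot s0 reference (air, noise-free) channel signal for normalisation.
#' @slot meta provenance list.
#' @export
setClass("Sinogram",
  representation(values = "matrix", mode = "character", kind = "character",
                 iproj = "numeric", s0 = "numeric", meta = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("expected", "counts", "lineintegral"))
      msg <- c(msg, "kind must be expected/counts/lineintegral")
    if (object@kind != "lineintegral" && any(object@values < 0))
      msg <- c(msg, "count-mode values must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' ReconImage: reconstructed CT slice
#'
#' @slot values 2D numeric matrix on an isotropic pitch.
#' @slot pitch pixel pitch in mm.
#' @export
setClass("ReconImage",
  representation(values = "matrix", pitch = "numeric"),
  validity = function(object) {
    if (any(!is.finite(object@values))) "values must be finite" else TRUE
  })

#' DoseMatchParams: the full dose-matching parameter chain
#'
#' Holds the inputs and intermediate quantities of the areal-fluence
#' dose-matching chain linking the XFET raster scan to the fan-beam CT
#' acquisition, plus the resulting per-channel per-view photon count.
#' `w` is the CT channel width at the detector; it is distinct from the
#' XFET slit width housed in [XFETGeometry-class].
#'
#' @slot ib photons per XFET beam position.
#' @slot a0 beam-position cross-section in mm^2.
#' @slot n target areal fluence, photons per mm^2 (Ib / A0).
#' @slot h channel height = phantom slice width, mm.
#' @slot w channel width at the detector, mm.
#' @slot wfan fan arc length at the SDD, mm.
#' @slot wiso channel width projected to the isocenter, mm.
#' @slot gammaFanRad fan angle in radians.
#' @slot sid,sdd source-isocenter and source-detector distances, mm.
#' @slot nChannels,nProj channel and view counts.
#' @slot iproj photons per channel per view (continuous value).
#' @slot iprojInt nearest-integer convenience value.
#' @export
setClass("DoseMatchParams",
  representation(ib = "numeric", a0 = "numeric", n = "numeric", h = "numeric",
                 w = "numeric", wfan = "numeric", wiso = "numeric",
                 gammaFanRad = "numeric", sid = "numeric", sdd = "numeric",
                 nChannels = "numeric", nProj = "numeric",
                 iproj = "numeric", iprojInt = "numeric"),
  validity = function(object) {
    vals <- c(object@ib, object@a0, object@h, object@gammaFanRad, object@sid,
              object@sdd, object@nChannels, object@nProj)
    msg <- character()
    if (any(vals <= 0)) msg <- c(msg, "all dose-matching inputs must be positive")
    if (abs(object@n - object@ib / object@a0) > 1e-6 * object@n)
      msg <- c(msg, "N must equal Ib / A0")
    if (length(msg)) msg else TRUE
  })
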