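#' @name accessors
#' @title Accessors for xfetsim containers
#' @description Small accessor generics so downstream code never touches
#'   slots directly.
#' @param object an xfetsim container.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("fluence", function(object) standardGeneric("fluence"))
#' @rdname accessors
#' @export
setMethod("fluence", "Spectrum", function(object) object@fluence)

#' @rdname accessors
#' @export
setGeneric("energyEdges", function(object) standardGeneric("energyEdges"))
#' @rdname accessors
#' @export
setMethod("energyEdges", "Spectrum", function(object) object@energyEdges)
#' @rdname accessors
#' @export
setMethod("energyEdges", "CountVolume", function(object) object@energyEdges)

#' @rdname accessors
#' @export
setGeneric("binCenters", function(object) standardGeneric("binCenters"))
#' @rdname accessors
#' @export
setMethod("binCenters", "Spectrum", function(object) {
  e <- object@energyEdges
  (e[-1] + e[-length(e)]) / 2
})

#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @rdname accessors
#' @export
setMethod("counts", "CountVolume", function(object) object@counts)

#' @rdname accessors
#' @export
setGeneric("imageValues", function(object) standardGeneric("imageValues"))
#' @rdname accessors
#' @export
setMethod("imageValues", "XFETImage", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("imageValues", "ReconImage", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("sinogramValues", function(object) standardGeneric("sinogramValues"))
#' @rdname accessors
#' @export
setMethod("sinogramValues", "Sinogram", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("goldFraction", function(object) standardGeneric("goldFraction"))
#' @rdname accessors
#' @export
setMethod("goldFraction", "VoxelPhantom", function(object) object@goldFraction)

#' @rdname accessors
#' @export
setGeneric("materialId", function(object) standardGeneric("materialId"))
#' @rdname accessors
#' @export
setMethod("materialId", "VoxelPhantom", function(object) object@materialId)

#' @rdname accessors
#' @export
setGeneric("voxelPitch", function(object) standardGeneric("voxelPitch"))
#' @rdname accessors
#' @export
setMethod("voxelPitch", "VoxelPhantom", function(object) object@pitch)

#' @rdname accessors
#' @export
setGeneric("phantomRois", function(object) standardGeneric("phantomRois"))
#' @rdname accessors
#' @export
setMethod("phantomRois", "VoxelPhantom", function(object) object@rois)

#' @rdname accessors
#' @export
setGeneric("sphereInserts", function(object) standardGeneric("sphereInserts"))
#' @rdname accessors
#' @export
setMethod("sphereInserts", "VoxelPhantom", function(object) object@inserts)

#' @rdname accessors
#' @export
setGeneric("iproj", function(object) standardGeneric("iproj"))
#' @rdname accessors
#' @export
setMethod("iproj", "DoseMatchParams", function(object) object@iproj)
#' @rdname accessors
#' @export
setGeneric("iprojInt", function(object) standardGeneric("iprojInt"))
#' @rdname accessors
#' @export
setMethod("iprojInt", "DoseMatchParams", function(object) object@iprojInt)

setMethod("show", "Material", function(object) {
  cat("Material '", object@name, "' (", object@density, " g/cm^3): ",
      paste0(names(object@composition), "=",
             signif(object@composition, 4), collapse = ", "), "\n", sep = "")
})

setMethod("show", "Spectrum", function(object) {
  nz <- which(object@fluence > 0)
  cat(sprintf("Spectrum: %g kVp, cutoff %g keV, %d bins, total fluence %.4g\n",
              object@kvp, object@cutoff, length(object@fluence), sum(object@fluence)))
  if (length(nz))
    cat(sprintf("  nonzero range: %g-%g keV\n",
                object@energyEdges[min(nz)], object@energyEdges[max(nz) + 1]))
})

setMethod("show", "VoxelPhantom", function(object) {
  d <- dim(object@materialId)
  cat(sprintf("VoxelPhantom: %d x %d x %d voxels, pitch %s mm\n", d[1], d[2], d[3],
              paste(signif(object@pitch, 4), collapse = " x ")))
  cat(sprintf("  materials: %s\n",
              paste(vapply(object@materials, function(m) m@name, ""), collapse = ", ")))
  cat(sprintf("  gold inserts: %d, ROIs: %d, max gold fraction %.4g\n",
              nrow(object@inserts), nrow(object@rois), max(object@goldFraction)))
})

setMethod("show", "CountVolume", function(object) {
  d <- dim(object@counts)
  cat(sprintf("CountVolume: %d x %d beam positions, %d axial bins (%g mm), %d energy bins (%g-%g keV)\n",
              d[1], d[2], d[3], object@axialPitch, d[4],
              min(object@energyEdges), max(object@energyEdges)))
  cat(sprintf("  total counts: %.4g\n", sum(object@counts)))
})

setMethod("show", "XFETImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("XFETImage: %d x %d x %d (axial pitch %g mm)%s\n", d[1], d[2], d[3],
              object@axialPitch,
              if (isTRUE(object@provenance$backgroundSubtracted)) ", background-subtracted" else ""))
})

setMethod("show", "CTGeometry", function(object) {
  cat(sprintf("CTGeometry: SID %g mm, SDD %g mm, %d channels over %g deg fan, %d views / %g deg arc\n",
              object@sid, object@sdd, object@nChannels, object@fanAngleDeg,
              object@nViews, object@arcDeg))
})

setMethod("show", "XFETGeometry", function(object) {
  cat(sprintf("XFETGeometry: d1=d2=%g mm, %d planes, slit %g x %g mm, detector %d x %d pixels\n",
              object@d1, object@nPlanes, object@slitWidth, object@slitLength,
              object@detColumns, object@detRows))
})

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram [%s%s]: %d views x %d channels\n",
              object@kind, if (nzchar(object@mode)) paste0(", ", object@mode) else "",
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "ReconImage", function(object) {
  cat(sprintf("ReconImage: %d x %d at %g mm pitch, value range [%.4g, %.4g]\n",
              nrow(object@values), ncol(object@values), object@pitch,
              min(object@values), max(object@values)))
})

setMethod("show", "DoseMatchParams", function(object) {
  cat("Dose matching (areal-fluence match of CT to the XFET raster):\n")
  cat(sprintf("  Ib = %.6g photons over A0 = %g mm^2  ->  N = %.6g /mm^2\n",
              object@ib, object@a0, object@n))
  cat(sprintf("  wfan = %.6g mm, w = %.6g mm, wiso = %.6g mm\n",
              object@wfan, object@w, object@wiso))
  cat(sprintf("  Iproj = N h wiso / Nproj = %.6f  (nearest integer %d)\n",
              object@iproj, object@iprojInt))
})
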