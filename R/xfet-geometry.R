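#' @include AllClasses.R
NULL

#' Construct the XFET scanner geometry
#'
#' Defaults describe the slit-aperture ring used throughout: six hexagonally
#' arranged 1-mm lead apertures at d1 = 83 mm from the isocenter, each with a
#' 0.5-mm slit at axial coordinate 0, backed by a 92 x 120 mm detector plane
#' at d1 + d2 = 166 mm divided into 46 rows (2 mm, transverse) x 120 columns
#' (1 mm, along the beam axis). Unit magnification (d1 = d2) maps emissions
#' at axial z to the detector column at -z.
#'
#' @param d1 isocenter-to-aperture distance, mm.
#' @param d2 aperture-to-detector distance, mm (must equal d1).
#' @param slitWidth slit width, mm.
#' @param slitLength slit length (transverse), mm.
#' @param apertureThickness lead thickness, mm.
#' @param nPlanes number of slit-detector planes.
#' @param planeAzimuthDeg azimuths of the plane normals, degrees.
#' @param detColumns,detRows detector pixel grid.
#' @param columnPitch,rowPitch detector pixel pitches, mm.
#' @param energyBinWidth detector energy bin width, keV.
#' @return an [XFETGeometry-class].
#' @export
xfetGeometry <- function(d1 = 83, d2 = 83, slitWidth = 0.5, slitLength = 46,
                         apertureThickness = 1, nPlanes = 6,
                         planeAzimuthDeg = seq(0, 300, by = 60),
                         detColumns = 120, detRows = 46,
                         columnPitch = 1, rowPitch = 2, energyBinWidth = 1) {
  new("XFETGeometry", d1 = d1, d2 = d2, slitWidth = slitWidth,
      slitLength = slitLength, apertureThickness = apertureThickness,
      nPlanes = nPlanes, planeAzimuthDeg = planeAzimuthDeg,
      detColumns = detColumns, detRows = detRows, columnPitch = columnPitch,
      rowPitch = rowPitch, energyBinWidth = energyBinWidth)
}

#' Map an axial emission coordinate through the slit
#'
#' With unit magnification the image coordinate is -(d2/d1) z = -z; the
#' detector column is the one containing that coordinate. Emissions mapping
#' beyond the detector edge are undetected (NA column, zero acceptance).
#'
#' @param z axial emission coordinate(s) in mm (slit frame).
#' @param geometry an [XFETGeometry-class].
#' @param perpDistance perpendicular distance from the emission point to the
#'   aperture plane, mm (default: on the beam axis, d1).
#' @param transverseOffset offset of the emission point along the slit
#'   direction, mm.
#' @return data.frame with `detCoord` (mm), `column` (1-based index or NA)
#'   and `acceptance` (solid-angle fraction of 4 pi through the slit).
#' @export
slitMap <- function(z, geometry, perpDistance = geometry@d1,
                    transverseOffset = 0) {
  halfSpan <- geometry@detColumns * geometry@columnPitch / 2
  detCoord <- -(geometry@d2 / geometry@d1) * z
  column <- floor((detCoord + halfSpan) / geometry@columnPitch) + 1
  off <- detCoord <= -halfSpan | detCoord >= halfSpan
  column[off] <- NA_integer_
  omega <- slitSolidAngle(z, geometry, perpDistance, transverseOffset)
  omega[off] <- 0
  data.frame(detCoord = detCoord, column = column,
             acceptance = omega / (4 * pi))
}

#' Solid angle of the slit opening from an emission point
#'
#' Integral of cos(alpha)/r^2 over the open slit area, by midpoint quadrature
#' across the slit width with a closed form along the slit length.
#'
#' @param z axial offset(s) of the emission point from the slit centre, mm.
#' @param geometry an [XFETGeometry-class].
#' @param perpDistance perpendicular distance to the aperture plane, mm.
#' @param transverseOffset offset along the slit direction, mm.
#' @param nQuad quadrature points across the slit width.
#' @return solid angle(s) in steradians.
#' @export
slitSolidAngle <- function(z, geometry, perpDistance = geometry@d1,
                           transverseOffset = 0, nQuad = 8) {
  w <- geometry@slitWidth; L <- geometry@slitLength; D <- perpDistance
  du <- w / nQuad
  u <- seq(-w / 2 + du / 2, w / 2 - du / 2, length.out = nQuad)
  vHi <- L / 2 - transverseOffset
  vLo <- -L / 2 - transverseOffset
  fv <- function(v, rho2) v / (rho2 * sqrt(v^2 + rho2))
  omega <- 0
  for (uu in u) {
    rho2 <- D^2 + (z - uu)^2
    omega <- omega + D * (fv(vHi, rho2) - fv(vLo, rho2)) * du
  }
  omega
}
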