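#' @include materials.R
NULL

.ELECTRON_REST_KEV <- 510.99895
.R_E2 <- 7.94077e-26 # classical electron radius squared, cm^2

#' Compton-scattered photon energy
#'
#' @param energy incident photon energy in keV.
#' @param theta scattering angle in radians, in [0, pi].
#' @return scattered photon energy in keV.
#' @export
comptonScatteredEnergy <- function(energy, theta) {
  stopifnot(all(energy > 0), all(theta >= 0), all(theta <= pi + 1e-12))
  energy / (1 + energy / .ELECTRON_REST_KEV * (1 - cos(theta)))
}

#' Klein-Nishina differential cross section per electron
#'
#' @param energy incident photon energy in keV.
#' @param theta scattering angle in radians.
#' @return d(sigma)/d(Omega) in cm^2/sr per electron.
#' @export
kleinNishinaDifferential <- function(energy, theta) {
  r <- comptonScatteredEnergy(energy, theta) / energy
  0.5 * .R_E2 * r^2 * (r + 1 / r - sin(theta)^2)
}

#' Klein-Nishina total cross section per electron
#'
#' @param energy incident photon energy in keV.
#' @return sigma in cm^2 per electron.
#' @export
kleinNishinaTotal <- function(energy) {
  k <- energy / .ELECTRON_REST_KEV
  2 * pi * .R_E2 * ((1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
                    log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2)
}

#' Differential Compton scatter rate of a material
#'
#' Klein-Nishina differential cross section times electron density, with the
#' scattered photon energy from Compton kinematics.
#'
#' @param mat a [Material-class].
#' @param energy incident photon energy in keV.
#' @param theta scattering angle in radians, in [0, pi].
#' @return list with `rate` (probability per sr per mm of path) and
#'   `scatteredEnergy` (keV).
#' @export
comptonScatterRate <- function(mat, energy, theta) {
  ne <- electronDensity(mat) # per cm^3
  list(rate = ne * kleinNishinaDifferential(energy, theta) / 10,
       scatteredEnergy = comptonScatteredEnergy(energy, theta))
}

#' Expected gold K-alpha1 emissions from a voxel
#'
#' First-order (thin-voxel) fluorescence production: for each energy bin at
#' or above the gold K edge, fluence x tau_K(E) x voxel length x omega_K x
#' b_Kalpha1, where tau_K is the K-shell photoelectric linear attenuation at
#' the voxel's gold density. Emission is isotropic; this returns the total
#' emitted into 4 pi.
#'
#' @param goldDensity gold mass density in the voxel, g/cm^3.
#' @param fluencePerBin photons per energy bin reaching the voxel.
#' @param energies bin centre energies in keV (same length as fluence).
#' @param voxelLength illuminated path length through the voxel, mm.
#' @return expected number of K-alpha1 photons emitted.
#' @export
fluorescenceProduction <- function(goldDensity, fluencePerBin, energies,
                                   voxelLength = 1) {
  if (goldDensity < 0) stop("gold density must be non-negative")
  stopifnot(length(fluencePerBin) == length(energies))
  fc <- fluorescenceConstants()
  tau <- goldKPhotoelectric(energies, goldDensity)
  sum(fluencePerBin * tau * voxelLength) * fc$omegaK * fc$branchKalpha1
}
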