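#' @include AllClasses.R
NULL

.xfetsimCache <- new.env(parent = emptyenv())

.elementTable <- function() {
  if (is.null(.xfetsimCache$elements)) {
    path <- system.file("extdata", "element_mu_rho.csv", package = "xfetsim",
                        mustWork = TRUE)
    tab <- utils::read.csv(path)
    .xfetsimCache$elements <- split(tab, tab$element)
  }
  .xfetsimCache$elements
}

.materialRegistry <- function() {
  if (is.null(.xfetsimCache$materials)) {
    path <- system.file("extdata", "materials_icrp.csv", package = "xfetsim",
                        mustWork = TRUE)
    tab <- utils::read.csv(path)
    .xfetsimCache$materials <- split(tab, tab$material)
  }
  .xfetsimCache$materials
}

.muenTable <- function() {
  if (is.null(.xfetsimCache$muen)) {
    path <- system.file("extdata", "muen_soft_tissue.csv", package = "xfetsim",
                        mustWork = TRUE)
    .xfetsimCache$muen <- utils::read.csv(path)
  }
  .xfetsimCache$muen
}

.checkEnergyRange <- function(energy) {
  if (any(!is.finite(energy)) || any(energy < 1) || any(energy > 150))
    stop("energy must lie in [1, 150] keV (table range)")
}

#' Elemental mass attenuation coefficient
#'
#' Log-log interpolation of the packaged standard tables.
#'
#' @param element element symbol, e.g. "O" or "Au".
#' @param energy photon energy in keV (vectorised), in [1, 150].
#' @return mass attenuation coefficient mu/rho in cm^2/g.
#' @export
elementMassAttenuation <- function(element, energy) {
  tabs <- .elementTable()
  if (!element %in% names(tabs))
    stop("unknown element symbol: ", element)
  .checkEnergyRange(energy)
  tab <- tabs[[element]]
  exp(stats::approx(log(tab$energy_keV), log(tab$mu_rho), xout = log(energy),
                    rule = 2)$y)
}

#' Construct a Material
#'
#' @param name label.
#' @param composition named numeric vector of elemental mass fractions
#'   (must sum to 1).
#' @param density bulk density in g/cm^3.
#' @return a [Material-class].
#' @export
newMaterial <- function(name, composition, density) {
  known <- names(.elementTable())
  bad <- setdiff(names(composition), known)
  if (length(bad))
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(names(composition))) {
    merged <- tapply(composition, names(composition), sum)
    composition <- stats::setNames(as.numeric(merged), names(merged))
  }
  new("Material", name = name, composition = composition, density = density)
}

#' Look up a material in the packaged ICRP/ICRU registry
#'
#' @param name registry name, e.g. "soft_tissue", "cortical_bone", "gold",
#'   "lead", "water", "air".
#' @return a [Material-class].
#' @export
material <- function(name) {
  reg <- .materialRegistry()
  if (!name %in% names(reg))
    stop("unknown material '", name, "'; registry has: ",
         paste(names(reg), collapse = ", "))
  tab <- reg[[name]]
  newMaterial(name, stats::setNames(tab$mass_fraction, tab$element),
              tab$density[1])
}

#' Admix gold into a host material by weight
#'
#' The host composition is scaled by (1 - w) and gold added at mass fraction
#' w. The bulk density is kept at the host density (dilute admixture, w <=
#' 4 wt% in these studies), so mixture attenuation is the mass-weighted
#' mu/rho of gold and host at the host density.
#'
#' @param host a [Material-class].
#' @param goldFraction gold mass fraction in [0, 1).
#' @return a [Material-class].
#' @export
goldMix <- function(host, goldFraction) {
  stopifnot(goldFraction >= 0, goldFraction < 1)
  if (goldFraction == 0) return(host)
  comp <- host@composition * (1 - goldFraction)
  comp["Au"] <- sum(comp["Au"], goldFraction, na.rm = TRUE)
  newMaterial(sprintf("%s+Au%.3g%%", host@name, 100 * goldFraction),
              comp, host@density)
}

#' Mass attenuation coefficient of a material (mixture rule)
#'
#' @param mat a [Material-class].
#' @param energy photon energy in keV (vectorised).
#' @return mu/rho in cm^2/g.
#' @export
massAttenuation <- function(mat, energy) {
  stopifnot(is(mat, "Material"))
  out <- numeric(length(energy))
  for (el in names(mat@composition)) {
    w <- mat@composition[[el]]
    if (w > 0) out <- out + w * elementMassAttenuation(el, energy)
  }
  out
}

#' Linear attenuation coefficient per mm
#'
#' mu = rho x sum_i w_i (mu/rho)_i(E), converted to 1/mm.
#'
#' @param mat a [Material-class].
#' @param energy photon energy in keV (vectorised), in [1, 150].
#' @return linear attenuation coefficient in 1/mm.
#' @export
linearAttenuation <- function(mat, energy) {
  massAttenuation(mat, energy) * mat@density / 10
}

#' Electron density of a material
#'
#' @param mat a [Material-class].
#' @return electrons per cm^3.
#' @export
electronDensity <- function(mat) {
  tabs <- .elementTable()
  za <- vapply(names(mat@composition), function(el) {
    t1 <- tabs[[el]][1, ]
    t1$Z / t1$A
  }, 0)
  sum(mat@composition * za) * 6.02214076e23 * mat@density
}

#' Soft-tissue mass energy-absorption coefficient
#'
#' Used by the primary-beam dose tally.
#'
#' @param energy photon energy in keV (vectorised), in [1, 150].
#' @return mu_en/rho in cm^2/g.
#' @export
muEnSoftTissue <- function(energy) {
  .checkEnergyRange(energy)
  tab <- .muenTable()
  exp(stats::approx(log(tab$energy_keV), log(tab$muen_rho), xout = log(energy),
                    rule = 2)$y)
}

#' Gold K-fluorescence constants
#'
#' K-edge and K-alpha1 energies, K-shell fluorescence yield and the
#' K-alpha1 branching fraction of gold.
#'
#' @return named list: `kEdge` (keV), `kalpha1` (keV), `omegaK`, `branchKalpha1`.
#' @export
fluorescenceConstants <- function() {
  fc <- list(kEdge = 80.725, kalpha1 = 68.804, omegaK = 0.96,
             branchKalpha1 = 0.47)
  stopifnot(fc$omegaK > 0, fc$omegaK < 1,
            fc$branchKalpha1 > 0, fc$branchKalpha1 <= 1,
            fc$kalpha1 < fc$kEdge)
  fc
}

#' K-shell photoelectric linear attenuation of gold
#'
#' Edge-jump model: the K-shell photoelectric component equals the tabulated
#' total jump at the K edge scaled by (E_K / E)^2.55; zero below the edge.
#' Used for fluorescence production, where only K vacancies contribute.
#'
#' @param energy photon energy in keV (vectorised).
#' @param goldDensity local gold mass density in g/cm^3.
#' @return linear attenuation in 1/mm (same length as `energy`).
#' @export
goldKPhotoelectric <- function(energy, goldDensity = 19.32) {
  if (any(goldDensity < 0)) stop("gold density must be non-negative")
  kEdge <- fluorescenceConstants()$kEdge
  jump <- 8.904 - 2.066 # K-edge jump of the tabulated total mu/rho, cm^2/g
  tau <- ifelse(energy >= kEdge, jump * (kEdge / energy)^2.55, 0)
  tau * goldDensity / 10
}
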