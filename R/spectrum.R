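#' @include AllClasses.R materials.R
NULL

#' Generate a tungsten-anode tube spectrum
#'
#' Filtered-Kramers continuum model: unfiltered fluence proportional to
#' (kVp - E)/E, attenuated by an aluminium-equivalent inherent filtration,
#' binned at 1 keV. The spectrum is scaled so that the FULL (untruncated)
#' model integrates to `histories` photons; a low-energy cutoff then zeroes
#' bins below it without rescaling, so a truncated beam still represents an
#' "equivalent" full-beam history count.
#'
#' @param kvp tube potential in keV.
#' @param filtrationMmAl aluminium-equivalent filtration thickness in mm.
#' @param cutoff low-energy cutoff in keV; bins whose centre lies below it
#'   are zeroed. Must satisfy cutoff < kVp.
#' @param histories total photons of the full (untruncated) beam.
#' @return a [Spectrum-class].
#' @export
generateSpectrum <- function(kvp = 120, filtrationMmAl = 2.5, cutoff = 0,
                             histories = 1) {
  if (cutoff >= kvp) stop("cutoff >= kVp yields an empty spectrum")
  if (kvp > 150) stop("kVp beyond the 150-keV table range")
  edges <- 0:ceiling(kvp)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  f <- numeric(length(centers))
  ok <- centers >= 1 & centers < kvp
  f[ok] <- (kvp - centers[ok]) / centers[ok]
  if (filtrationMmAl > 0) {
    al <- material("aluminum")
    f[ok] <- f[ok] * exp(-linearAttenuation(al, centers[ok]) * filtrationMmAl)
  }
  tot <- sum(f)
  if (tot > 0 && histories > 0) f <- f * (histories / tot) else f[] <- 0
  f[centers < cutoff] <- 0
  new("Spectrum", energyEdges = as.numeric(edges), fluence = f,
      kvp = kvp, cutoff = cutoff)
}

#' Rescale a spectrum's fluence
#'
#' @param spectrum a [Spectrum-class].
#' @param factor non-negative multiplier.
#' @return a [Spectrum-class].
#' @export
scaleSpectrum <- function(spectrum, factor) {
  stopifnot(factor >= 0)
  initialize(spectrum, fluence = spectrum@fluence * factor)
}

#' Fraction of spectrum fluence above an energy threshold
#'
#' Reported fraction of the full-beam counts carried by bins above the
#' threshold (the bin containing the threshold contributes its fraction
#' above it, assuming uniform fluence within the bin).
#'
#' @param spectrum a [Spectrum-class] (untruncated).
#' @param threshold energy in keV.
#' @return a fraction in [0, 1].
#' @export
spectrumFractionAbove <- function(spectrum, threshold) {
  e <- spectrum@energyEdges
  lo <- e[-length(e)]; hi <- e[-1]
  wAbove <- pmin(pmax((hi - threshold) / (hi - lo), 0), 1)
  tot <- sum(spectrum@fluence)
  if (tot == 0) return(0)
  sum(spectrum@fluence * wAbove) / tot
}

#' Mean (fluence-weighted) energy of a spectrum
#'
#' @param spectrum a [Spectrum-class].
#' @return energy in keV.
#' @export
meanEnergy <- function(spectrum) {
  c <- binCenters(spectrum)
  sum(c * spectrum@fluence) / sum(spectrum@fluence)
}
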