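#' @include AllClasses.R materials.R xfet-simulator.R
NULL

#' Dose-matching per-view channel fluence
#'
#' Evaluates the areal-fluence dose-matching chain linking the XFET raster
#' scan to the CT acquisition: N = Ib / A0 photons per mm^2 delivered at the
#' isocenter, wiso = gamma_fan SID / Nchannels the channel width projected to
#' the isocenter, and Iproj = N h wiso / Nproj photons per channel per view.
#'
#' @param ib photons per XFET beam position.
#' @param a0 beam-position cross-section, mm^2.
#' @param h CT channel height = phantom slice width, mm.
#' @param gammaFanDeg full fan angle, degrees.
#' @param sid source-to-isocenter distance, mm.
#' @param nChannels detector channels.
#' @param nProj projection views.
#' @param sdd source-to-detector distance, mm (only enters the reported
#'   detector-plane widths wfan and w; it cancels in wiso).
#' @return a [DoseMatchParams-class]; `iproj()` gives the continuous value,
#'   `iprojInt()` the nearest integer.
#' @export
computeIproj <- function(ib, a0, h, gammaFanDeg = 19.37, sid = 100,
                         nChannels = 1024, nProj = 438, sdd = 2 * sid) {
  vals <- c(ib, a0, h, gammaFanDeg, sid, nChannels, nProj, sdd)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all dose-matching inputs must be positive")
  gfan <- gammaFanDeg * pi / 180
  n <- ib / a0
  wfan <- gfan * sdd
  w <- wfan / nChannels
  wiso <- w * sid / sdd
  ip <- n * h * wiso / nProj
  new("DoseMatchParams", ib = ib, a0 = a0, n = n, h = h, w = w, wfan = wfan,
      wiso = wiso, gammaFanRad = gfan, sid = sid, sdd = sdd,
      nChannels = nChannels, nProj = nProj, iproj = ip,
      iprojInt = as.integer(round(ip)))
}

#' Fold increase in local dose between two history counts
#'
#' @param historiesPartial histories per beam position in the partial scan.
#' @param historiesFull histories per beam position in the full scan.
#' @return list with `fold` (exact ratio) and `foldInt` (nearest integer,
#'   the reporting convention).
#' @export
foldIncrease <- function(historiesPartial, historiesFull) {
  if (historiesFull <= 0) stop("full-scan histories must be positive")
  r <- historiesPartial / historiesFull
  list(fold = r, foldInt = as.integer(round(r)))
}

#' Local dose of a partial-FOV scan
#'
#' @param fullDoseMGy full-FOV mean phantom dose, mGy.
#' @param fold local dose fold increase.
#' @return local dose in cGy.
#' @export
localDose <- function(fullDoseMGy, fold) {
  fullDoseMGy * fold / 10
}

#' Analytic primary-beam dose tally
#'
#' Mean phantom dose of a raster scan: per beam position, deposited energy is
#' accumulated as fluence(E, depth) x E x mu_en/rho x rho x dz along the
#' attenuated primary path (soft-tissue mass energy-absorption weighting for
#' all tissues; no scattered-dose transport), summed over positions and
#' divided by the phantom mass. Fidelity is order-of-magnitude (factor ~2):
#' scattered photons re-deposit elsewhere in reality.
#'
#' @param phantom a [VoxelPhantom-class].
#' @param spectrum full (untruncated) beam [Spectrum-class]; total fluence =
#'   histories per beam position. A truncated spectrum triggers a warning.
#' @param beamXs,beamYs raster grids in mm (default: every voxel column).
#' @return list with `meanDoseMGy` and `depositedJ`.
#' @export
estimateDose <- function(phantom, spectrum, beamXs = NULL, beamYs = NULL) {
  if (spectrum@cutoff > 1)
    warning("dose tally expects the full spectrum; cutoff = ",
            spectrum@cutoff, " keV truncates low-energy deposition")
  d <- dim(phantom@materialId)
  if (is.null(beamXs))
    beamXs <- phantom@origin[1] + (seq_len(d[1]) - 1) * phantom@pitch[1]
  if (is.null(beamYs))
    beamYs <- phantom@origin[2] + (seq_len(d[2]) - 1) * phantom@pitch[2]
  if (sum(fluence(spectrum)) == 0)
    return(list(meanDoseMGy = 0, depositedJ = 0, massG = NA_real_))
  tb <- .xfetTables(phantom, spectrum, c(66, 72))
  muen <- muEnSoftTissue(tb$En) # cm^2/g
  dz <- phantom@pitch[3]
  pixI <- .nearestIndex(beamXs, phantom@origin[1], phantom@pitch[1], d[1])
  pixJ <- .nearestIndex(beamYs, phantom@origin[2], phantom@pitch[2], d[2])
  # deposited energy per unique column profile
  key <- matrix("", length(pixI), length(pixJ))
  for (j in seq_along(pixJ)) for (i in seq_along(pixI)) {
    mcol <- phantom@materialId[pixI[i], pixJ[j], ]
    wcol <- phantom@goldFraction[pixI[i], pixJ[j], ]
    key[i, j] <- if (any(wcol > 0)) paste0("g", pixI[i], "_", pixJ[j]) else
      paste(rle(mcol)$values, rle(mcol)$lengths, collapse = ".")
  }
  ukey <- unique(as.vector(key))
  edep <- stats::setNames(numeric(length(ukey)), ukey)
  for (u in ukey) {
    kxy <- which(key == u)[1]
    i <- (kxy - 1) %% length(pixI) + 1; j <- (kxy - 1) %/% length(pixI) + 1
    matv <- phantom@materialId[pixI[i], pixJ[j], ]
    w <- phantom@goldFraction[pixI[i], pixJ[j], ]
    M <- .columnMu(tb, matv, w)
    fl <- .columnFluence(tb, M, dz)
    rho <- tb$rhoHost[matv]
    # keV deposited in this column for one beam position
    edep[u] <- sum(fl * outer(rho, muen) / 10 * dz *
                     matrix(tb$En, length(matv), length(tb$En), byrow = TRUE))
  }
  totalKeV <- sum(edep[as.vector(key)])
  voxVolCm3 <- prod(phantom@pitch) / 1000
  massG <- sum(tb$rhoHost[phantom@materialId] *
                 (phantom@materialId != 1L)) * voxVolCm3
  joules <- totalKeV * 1.602176634e-16
  list(meanDoseMGy = joules / (massG / 1000) * 1000, depositedJ = joules,
       massG = massG)
}
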