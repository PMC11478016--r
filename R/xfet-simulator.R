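#' @include AllClasses.R materials.R spectrum.R compton.R xfet-geometry.R phantoms.R
NULL

# --- internal helpers -------------------------------------------------------

# nearest voxel index along one axis
.nearestIndex <- function(coord, origin, pitch, n) {
  i <- round((coord - origin) / pitch) + 1
  pmin(pmax(i, 1L), n)
}

# per-material attenuation tables on the spectrum's nonzero bins
.xfetTables <- function(phantom, spectrum, window) {
  cent <- binCenters(spectrum)
  keep <- which(fluence(spectrum) > 0)
  En <- cent[keep]
  flu0 <- fluence(spectrum)[keep]
  nmat <- length(phantom@materials)
  muHost <- vapply(phantom@materials,
                   function(m) massAttenuation(m, En) * m@density / 10, En)
  muHost <- matrix(muHost, nrow = length(En)) # guard the single-bin case
  rhoHost <- vapply(phantom@materials, function(m) m@density, 0)
  neHost <- vapply(phantom@materials, electronDensity, 0)
  muAuRho <- elementMassAttenuation("Au", En) # cm^2/g
  tauKUnit <- goldKPhotoelectric(En, goldDensity = 1) # per mm per (g/cm^3)
  fc <- fluorescenceConstants()
  binEdges <- window[1]:window[2]
  binCent <- (binEdges[-1] + binEdges[-length(binEdges)]) / 2
  kalphaBin <- findInterval(fc$kalpha1, binEdges)
  muExitHost <- vapply(phantom@materials,
                       function(m) massAttenuation(m, fc$kalpha1) * m@density / 10, 0)
  muExitAuRho <- elementMassAttenuation("Au", fc$kalpha1)
  list(En = En, flu0 = flu0, muHost = muHost, rhoHost = rhoHost,
       neHost = neHost, muAuRho = muAuRho, tauKUnit = tauKUnit, fc = fc,
       binEdges = binEdges, binCent = binCent, kalphaBin = kalphaBin,
       muExitHost = muExitHost, muExitAuRho = muExitAuRho, nmat = nmat)
}

# attenuation per mm for one beam column: (nz x nE) matrix
.columnMu <- function(tb, matv, w) {
  M <- t(tb$muHost)[matv, , drop = FALSE] * (1 - w)
  if (any(w > 0))
    M <- M + outer(tb$rhoHost[matv] * w / 10, tb$muAuRho)
  M
}

# Beer-Lambert fluence at voxel centres along the column: (nz x nE)
.columnFluence <- function(tb, M, dz) {
  cums <- apply(M, 2, cumsum)
  matrix(tb$flu0, nrow(M), length(tb$flu0), byrow = TRUE) *
    exp(-(cums - M / 2) * dz)
}

#' Transport the pencil beam through the phantom
#'
#' Beer-Lambert attenuation of the entrance spectrum along the axis-parallel
#' illuminated line, evaluated on the voxel grid (fluence at voxel centres).
#'
#' @param phantom a [VoxelPhantom-class].
#' @param beamX,beamY transverse beam position in mm.
#' @param spectrum a [Spectrum-class]; its total fluence is the per-position
#'   history count.
#' @return list with `energies` (keV, nonzero bins), `depth` (mm from the
#'   entrance face) and `fluence` (depth x energy matrix).
#' @export
beamTransport <- function(phantom, beamX, beamY, spectrum) {
  d <- dim(phantom@materialId)
  ix <- .nearestIndex(beamX, phantom@origin[1], phantom@pitch[1], d[1])
  iy <- .nearestIndex(beamY, phantom@origin[2], phantom@pitch[2], d[2])
  tb <- .xfetTables(phantom, spectrum, c(66, 72))
  matv <- phantom@materialId[ix, iy, ]
  w <- phantom@goldFraction[ix, iy, ]
  if (all(matv == 1L) && phantom@materials[[1]]@name == "air")
    warning("beam misses the phantom: all-air column")
  M <- .columnMu(tb, matv, w)
  fl <- .columnFluence(tb, M, phantom@pitch[3])
  depth <- (seq_len(d[3]) - 0.5) * phantom@pitch[3]
  list(energies = tb$En, depth = depth, fluence = fl)
}

# exit-transmission maps at the fluorescence energy, one (nx x ny) matrix per
# (plane, detector column); returned as array (nx, ny, ncol, nplanes)
.exitTransmission <- function(phantom, geometry, tb, colZIdx) {
  d <- dim(phantom@materialId)
  nxy <- c(d[1], d[2])
  lower <- phantom@origin[1:2] - phantom@pitch[1:2] / 2
  az <- geometry@planeAzimuthDeg * pi / 180
  ncol <- length(colZIdx)
  out <- array(0, dim = c(d[1], d[2], ncol, geometry@nPlanes))
  step <- min(phantom@pitch[1:2]) / 2
  for (ci in seq_len(ncol)) {
    zi <- colZIdx[ci]
    matS <- phantom@materialId[, , zi]
    wS <- phantom@goldFraction[, , zi]
    mu2d <- matrix(tb$muExitHost[matS], d[1], d[2]) * (1 - wS) +
      tb$rhoHost[matS] * wS * tb$muExitAuRho / 10
    for (k in seq_len(geometry@nPlanes)) {
      A <- cpp_exit_integral(mu2d, lower, phantom@pitch[1:2],
                             cos(az[k]), sin(az[k]), step)
      out[, , ci, k] <- exp(-A)
    }
  }
  out
}

#' Expected XFET detector counts
#'
#' Analytic-expectation forward model: pencil-beam transport, first-order
#' fluorescence production, single-scatter Compton background into the 1-keV
#' detector window, slit solid-angle acceptance with unit-magnification
#' mapping, exit attenuation of the emitted photons through the phantom, and
#' a uniform axial leakage term for photons penetrating the 1-mm lead
#' aperture. Detector rows and the six planes are summed. Counts are
#' indexed (beam x, beam y, detector column, energy bin).
#'
#' @param phantom a [VoxelPhantom-class]; its z extent must be an integer
#'   number of detector columns.
#' @param spectrum a [Spectrum-class] whose total (full-beam) fluence is the
#'   per-position history count Ib.
#' @param geometry an [XFETGeometry-class].
#' @param beamXs,beamYs raster grids in mm (default: every voxel column).
#' @param window energy window in keV, default 66-72 (1-keV bins).
#' @return a [CountVolume-class] of expected (non-integer) counts.
#' @export
xfetExpectedCounts <- function(phantom, spectrum, geometry = xfetGeometry(),
                               beamXs = NULL, beamYs = NULL,
                               window = c(66, 72)) {
  d <- dim(phantom@materialId)
  pz <- phantom@pitch[3]
  zPerCol <- round(geometry@columnPitch / pz)
  if (abs(zPerCol * pz - geometry@columnPitch) > 1e-9)
    stop("voxel pitch must divide the detector column pitch")
  nzc <- d[3] %/% zPerCol
  if (nzc * zPerCol != d[3])
    stop("phantom z extent must be an integer number of detector columns")
  if (is.null(beamXs))
    beamXs <- phantom@origin[1] + (seq_len(d[1]) - 1) * phantom@pitch[1]
  if (is.null(beamYs))
    beamYs <- phantom@origin[2] + (seq_len(d[2]) - 1) * phantom@pitch[2]

  tb <- .xfetTables(phantom, spectrum, window)
  nb <- length(tb$binCent)
  dz <- pz
  zvox <- phantom@origin[3] + (seq_len(d[3]) - 1) * pz
  colZ <- colSums(matrix(zvox, zPerCol)) / zPerCol # column centres, mm
  colZIdx <- round(seq(ceiling(zPerCol / 2), by = zPerCol, length.out = nzc))

  # Compton kinematics to each plane: angle depends only on axial position.
  # Incident 1-keV bins are sub-sampled so the compressive energy mapping
  # does not alias into the discrete detector bins.
  cosTheta <- -2 * zvox / sqrt((geometry@d1 + geometry@d2)^2 + 4 * zvox^2)
  theta <- acos(pmin(pmax(cosTheta, -1), 1))
  nSub <- 8L
  Esub <- as.vector(outer((seq_len(nSub) - 0.5) / nSub - 0.5, tb$En, "+"))
  EscatS <- outer(theta, Esub, function(th, E) comptonScatteredEnergy(E, th))
  KNS <- outer(theta, Esub, function(th, E) kleinNishinaDifferential(E, th))
  destBin <- findInterval(EscatS, tb$binEdges)
  destBin[EscatS < tb$binEdges[1] | EscatS >= tb$binEdges[nb + 1]] <- 0L
  nzv <- length(theta)
  WB <- lapply(seq_len(nb), function(b) {
    w <- KNS * (destBin == b)
    dim(w) <- c(nzv, nSub, length(tb$En))
    matrix(colSums(aperm(w, c(2, 1, 3))), nzv, length(tb$En)) / nSub
  })

  # exit transmission per (pixel, column, plane) and slit acceptance
  Texit <- .exitTransmission(phantom, geometry, tb, colZIdx)
  az <- geometry@planeAzimuthDeg * pi / 180
  halfSpan <- geometry@detColumns * geometry@columnPitch / 2

  nx <- length(beamXs); ny <- length(beamYs)
  pixI <- .nearestIndex(beamXs, phantom@origin[1], phantom@pitch[1], d[1])
  pixJ <- .nearestIndex(beamYs, phantom@origin[2], phantom@pitch[2], d[2])

  # F[pos, col] = sum_k Omega_k T_k ; Tavg for the leakage term
  Fdir <- array(0, dim = c(nx, ny, nzc))
  Tavg <- array(0, dim = c(nx, ny, nzc))
  detected <- abs(colZ) < halfSpan
  for (k in seq_len(geometry@nPlanes)) {
    ux <- cos(az[k]); uy <- sin(az[k])
    for (j in seq_len(ny)) {
      Dk <- geometry@d1 - (beamXs * ux + beamYs[j] * uy)
      t0 <- -beamXs * sin(az[k]) + beamYs[j] * cos(az[k])
      Tk <- Texit[pixI, pixJ[j], , k] # nx x nzc
      for (i in seq_len(nx)) {
        om <- slitSolidAngle(colZ, geometry, Dk[i], t0[i])
        om[!detected] <- 0
        Fdir[i, j, ] <- Fdir[i, j, ] + om * Tk[i, ]
        Tavg[i, j, ] <- Tavg[i, j, ] + Tk[i, ] / geometry@nPlanes
      }
    }
  }

  # leakage through the lead aperture: uniform along the axial direction
  lead <- material("lead")
  pbT <- exp(-linearAttenuation(lead, tb$binCent) * geometry@apertureThickness)
  omegaDet <- geometry@columnPitch * (geometry@detRows * geometry@rowPitch) /
    (geometry@d1 + geometry@d2)^2

  # emissions per unique beam-column profile
  key <- character(nx * ny)
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    kxy <- (j - 1) * nx + i
    wcol <- phantom@goldFraction[pixI[i], pixJ[j], ]
    mcol <- phantom@materialId[pixI[i], pixJ[j], ]
    key[kxy] <- if (any(wcol > 0))
      paste0("g", pixI[i], "_", pixJ[j]) else paste(rle(mcol)$values,
                                                    rle(mcol)$lengths,
                                                    collapse = ".")
  }
  ukey <- unique(key)
  emis <- vector("list", length(ukey))
  names(emis) <- ukey
  aggCol <- function(v) colSums(matrix(v, zPerCol))
  for (u in ukey) {
    kxy <- which(key == u)[1]
    i <- (kxy - 1) %% nx + 1; j <- (kxy - 1) %/% nx + 1
    matv <- phantom@materialId[pixI[i], pixJ[j], ]
    w <- phantom@goldFraction[pixI[i], pixJ[j], ]
    M <- .columnMu(tb, matv, w)
    fl <- .columnFluence(tb, M, dz)
    rhoAu <- tb$rhoHost[matv] * w
    fluor <- tb$fc$omegaK * tb$fc$branchKalpha1 * dz * rhoAu *
      as.vector(fl %*% tb$tauKUnit)
    ne <- tb$neHost[matv] * (1 - w)
    scat <- vapply(seq_len(nb), function(b)
      aggCol(rowSums(fl * WB[[b]]) * ne * dz / 10), numeric(nzc))
    emis[[u]] <- list(fluorCol = aggCol(fluor), scatCol = scat)
  }

  counts <- array(0, dim = c(nx, ny, nzc, nb))
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    e <- emis[[key[(j - 1) * nx + i]]]
    f <- Fdir[i, j, ]; tv <- Tavg[i, j, ]
    block <- e$scatCol * f
    block[, tb$kalphaBin] <- block[, tb$kalphaBin] + e$fluorCol * f / (4 * pi)
    # leakage: emissions escaping toward closed aperture regions
    leakSrc <- colSums(e$scatCol * tv)
    leakSrc[tb$kalphaBin] <- leakSrc[tb$kalphaBin] +
      sum(e$fluorCol * tv) / (4 * pi)
    block <- block + matrix(leakSrc * pbT, nzc, nb, byrow = TRUE) *
      omegaDet * geometry@nPlanes * detected
    counts[i, j, , ] <- block
  }

  new("CountVolume", counts = counts, axialPitch = geometry@columnPitch,
      axialCoords = colZ, energyEdges = as.numeric(tb$binEdges),
      beamX = beamXs, beamY = beamYs,
      meta = list(expected = TRUE, histories = sum(fluence(spectrum)),
                  window = window,
                  attenuationTables = "Hubbell-Seltzer/XCOM transcription"))
}

#' Poisson-sample a CountVolume of expectations
#'
#' Independent Poisson draws per (beam position, axial bin, energy bin);
#' identical seeds give identical counts.
#'
#' @param expected a [CountVolume-class] of expected counts.
#' @param seed integer seed.
#' @return a [CountVolume-class] of integer counts.
#' @export
sampleCounts <- function(expected, seed) {
  lam <- counts(expected)
  if (any(lam < 0)) stop("negative expectation")
  set.seed(as.integer(seed))
  smp <- array(stats::rpois(length(lam), lam), dim = dim(lam))
  initialize(expected, counts = smp,
             meta = utils::modifyList(expected@meta,
                                      list(expected = FALSE, seed = seed)))
}

#' Partial field-of-view XFET scan (expected counts)
#'
#' Restricts the raster to a square region of interest at a finer step and
#' elevated per-position histories, the partial-FOV acquisition mode unique
#' to direct fluorescence imaging.
#'
#' @param phantom a [VoxelPhantom-class].
#' @param spectrum a [Spectrum-class] for the FULL-dose beam (its total
#'   fluence is multiplied by `histories / baseHistories`).
#' @param roiCenter c(x, y) centre of the square ROI, mm.
#' @param roiSize ROI side, mm.
#' @param fineStep raster step inside the ROI, mm.
#' @param histories full-beam photons per beam position for the partial scan.
#' @param baseHistories full-beam photons per position the supplied spectrum
#'   encodes (the full-FOV scan value); the spectrum's fluence is scaled by
#'   `histories / baseHistories`. With a truncated spectrum the encoded
#'   history count is the full-beam equivalent, not the truncated sum, so it
#'   must be given explicitly when it differs from the default.
#' @param geometry an [XFETGeometry-class].
#' @param window energy window, keV.
#' @return a [CountVolume-class] of expected counts on the ROI grid.
#' @export
partialFovScan <- function(phantom, spectrum, roiCenter, roiSize,
                           fineStep = 0.25, histories = 6.41e9,
                           baseHistories = 1.25e8,
                           geometry = xfetGeometry(), window = c(66, 72)) {
  d <- dim(phantom@materialId)
  ext <- c(phantom@origin[1] - phantom@pitch[1] / 2,
           phantom@origin[1] + (d[1] - 0.5) * phantom@pitch[1])
  if (any(roiCenter - roiSize / 2 < ext[1]) || any(roiCenter + roiSize / 2 > ext[2]))
    stop("ROI extends outside the phantom field of view")
  n <- round(roiSize / fineStep)
  off <- (seq_len(n) - (n + 1) / 2) * fineStep
  sp <- scaleSpectrum(spectrum, histories / baseHistories)
  xfetExpectedCounts(phantom, sp, geometry,
                     beamXs = roiCenter[1] + off, beamYs = roiCenter[2] + off,
                     window = window)
}
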