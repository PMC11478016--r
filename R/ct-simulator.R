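#' @include AllClasses.R materials.R spectrum.R phantoms.R
NULL

#' Construct the fan-beam CT geometry
#'
#' Defaults follow the micro-CT-like scanner used throughout: 100-mm SID,
#' 200-mm SDD, 1024 channels on a curved equiangular detector spanning a
#' 19.37-deg fan, 438 views over a 219-deg arc (> 180 deg + fan angle).
#'
#' @param sid source-to-isocenter distance, mm.
#' @param sdd source-to-detector distance, mm.
#' @param nChannels detector channels.
#' @param fanAngleDeg full fan angle, degrees.
#' @param nViews projection views.
#' @param arcDeg gantry arc, degrees.
#' @param channelHeight channel height (= phantom slice width), mm.
#' @return a [CTGeometry-class].
#' @export
ctGeometry <- function(sid = 100, sdd = 200, nChannels = 1024,
                       fanAngleDeg = 19.37, nViews = 438, arcDeg = 219,
                       channelHeight = 0.0625) {
  new("CTGeometry", sid = sid, sdd = sdd, nChannels = nChannels,
      fanAngleDeg = fanAngleDeg, nViews = nViews, arcDeg = arcDeg,
      channelHeight = channelHeight)
}

.ctAngles <- function(geometry) {
  dgamma <- geometry@fanAngleDeg * pi / 180 / geometry@nChannels
  gammas <- (seq_len(geometry@nChannels) - (geometry@nChannels + 1) / 2) * dgamma
  betas <- (seq_len(geometry@nViews) - 1) * geometry@arcDeg * pi / 180 /
    geometry@nViews
  list(gammas = gammas, dgamma = dgamma, betas = betas,
       dbeta = geometry@arcDeg * pi / 180 / geometry@nViews)
}

# ray endpoints (source, detector element) for every (view, channel);
# rays ordered view-major: ray index r = (v-1)*nChannels + c
.ctRays <- function(geometry) {
  a <- .ctAngles(geometry)
  nv <- geometry@nViews; nc <- geometry@nChannels
  p0 <- matrix(0, nv * nc, 2); p1 <- matrix(0, nv * nc, 2)
  for (v in seq_len(nv)) {
    b <- a$betas[v]
    sx <- geometry@sid * cos(b); sy <- geometry@sid * sin(b)
    # direction of channel c: central ray rotated by gamma
    ang <- (b + pi) + a$gammas # central ray points from source through origin
    rows <- (v - 1) * nc + seq_len(nc)
    p0[rows, 1] <- sx; p0[rows, 2] <- sy
    p1[rows, 1] <- sx + geometry@sdd * cos(ang)
    p1[rows, 2] <- sy + geometry@sdd * sin(ang)
  }
  list(p0 = p0, p1 = p1)
}

#' Exact voxel-path decomposition of a ray (Siddon traversal)
#'
#' @param p0,p1 ray endpoints (length 2 or 3), mm; must lie outside the grid.
#' @param origin centre of the first voxel, mm.
#' @param pitch voxel pitch per axis, mm.
#' @param dims voxel counts per axis.
#' @return data.frame with 1-based array `index` (matrix of per-axis indices)
#'   and `length` (mm). The lengths sum to the chord length inside the grid.
#' @export
siddonTrace <- function(p0, p1, origin, pitch, dims) {
  stopifnot(length(p0) == length(p1), length(p0) == length(dims))
  lower <- origin - pitch / 2
  res <- cpp_siddon(as.numeric(p0), as.numeric(p1), as.numeric(lower),
                    as.numeric(pitch), as.integer(dims))
  lin <- res$index
  nd <- length(dims)
  idx <- matrix(0L, length(lin), nd)
  rem <- lin
  for (a in seq_len(nd)) {
    idx[, a] <- rem %% dims[a] + 1L
    rem <- rem %/% dims[a]
  }
  list(index = idx, length = res$length)
}

#' Polychromatic fan-beam forward projection of a phantom slab
#'
#' Siddon raytracing of host- and gold-density basis maps for each thin
#' sub-slice of the slab, then per-energy expected counts
#' lambda(view, channel, E) = Iproj share(E) exp(-mu path), accumulated over
#' sub-slices (counts of adjacent slices are summed, matching an acquisition
#' of sequential slices).
#'
#' @param slices list of slices as returned by [contrastDepthSlice()] (each
#'   with `hostDensity`, `goldDensity`, `coords`).
#' @param spectrum a [Spectrum-class] (shares are normalised internally).
#' @param geometry a [CTGeometry-class].
#' @param iproj photons per channel per view delivered per sub-slice.
#' @param hostMaterial host material for mu/rho (default ICRP soft tissue).
#' @return list with `lambda` (nray x nE matrix of expected counts, rays
#'   view-major), `energies`, `share` (photons per bin per sub-slice),
#'   `nSlices`, `geometry`, `iproj`.
#' @export
forwardProject <- function(slices, spectrum, geometry, iproj,
                           hostMaterial = material("soft_tissue")) {
  cent <- binCenters(spectrum)
  keep <- which(fluence(spectrum) > 0)
  En <- cent[keep]
  share <- fluence(spectrum)[keep] / sum(fluence(spectrum)) * iproj
  muRhoHost <- massAttenuation(hostMaterial, En) # cm^2/g
  muRhoAu <- elementMassAttenuation("Au", En)
  rays <- .ctRays(geometry)
  nray <- nrow(rays$p0)
  lambda <- matrix(0, nray, length(En))
  for (s in slices) {
    pitch <- s$coords[2] - s$coords[1]
    lower <- rep(s$coords[1] - pitch / 2, 2)
    L <- cpp_project_rays(rays$p0, rays$p1, s$hostDensity, s$goldDensity,
                          lower, rep(pitch, 2)) # (g/cm^3)*mm
    for (e in seq_along(En)) {
      lambda[, e] <- lambda[, e] +
        share[e] * exp(-(muRhoHost[e] * L[, 1] + muRhoAu[e] * L[, 2]) / 10)
    }
  }
  list(lambda = lambda, energies = En, share = share, nSlices = length(slices),
       geometry = geometry, iproj = iproj)
}

#' Detect a forward projection with the EICT or PCCT noise model
#'
#' PCCT: direct Poisson counting, K ~ Poisson(sum_E lambda_E). EICT:
#' energy-weighted compound Poisson, S = sum_E E k_E with independent
#' k_E ~ Poisson(lambda_E). `noiseFree = TRUE` returns the expectation.
#' The reference air signal per channel (for log-normalisation) is recorded
#' in the `s0` slot.
#'
#' @param fp result of [forwardProject()].
#' @param mode "eict" or "pcct".
#' @param seed integer seed (ignored when noise-free).
#' @param noiseFree logical; skip the Poisson draws.
#' @return a [Sinogram-class] (views x channels).
#' @export
ctDetect <- function(fp, mode = c("pcct", "eict"), seed = 1, noiseFree = FALSE) {
  mode <- match.arg(mode)
  g <- fp$geometry
  wE <- if (mode == "eict") fp$energies else rep(1, length(fp$energies))
  if (!noiseFree) set.seed(as.integer(seed))
  if (noiseFree) {
    S <- as.vector(fp$lambda %*% wE)
  } else if (mode == "pcct") {
    lamTot <- rowSums(fp$lambda)
    S <- stats::rpois(length(lamTot), lamTot)
  } else {
    S <- numeric(nrow(fp$lambda))
    for (e in seq_along(fp$energies))
      S <- S + fp$energies[e] * stats::rpois(nrow(fp$lambda), fp$lambda[, e])
  }
  s0 <- sum(wE * fp$share) * fp$nSlices
  new("Sinogram",
      values = matrix(S, g@nViews, g@nChannels, byrow = TRUE),
      mode = mode, kind = if (noiseFree) "expected" else "counts",
      iproj = fp$iproj, s0 = s0,
      meta = list(seed = if (noiseFree) NA else seed, nSlices = fp$nSlices))
}

#' Water-based beam-hardening calibration
#'
#' Noise-free transmission through water slabs of 0-`maxThickness` mm for
#' the given spectrum and detection mode; a fourth-degree zero-intercept
#' polynomial maps raw log-normalised projections to mu_water(E_ref) x
#' thickness, with E_ref the fluence-weighted mean energy.
#'
#' @param spectrum a [Spectrum-class].
#' @param mode "eict" or "pcct".
#' @param maxThickness calibration range, mm.
#' @param degree polynomial degree.
#' @param calibrationMaterial the slab material; default water. Calibrating
#'   on the phantom host material (e.g. ICRP soft tissue) removes the
#'   residual cupping a density-mismatched calibration leaves behind.
#' @return list with `coef`, `eRef`, `muRef` (1/mm), `mode`.
#' @export
waterCalibration <- function(spectrum, mode = c("pcct", "eict"),
                             maxThickness = 40, degree = 4,
                             calibrationMaterial = material("water")) {
  mode <- match.arg(mode)
  water <- calibrationMaterial
  cent <- binCenters(spectrum)
  keep <- which(fluence(spectrum) > 0)
  En <- cent[keep]
  share <- fluence(spectrum)[keep]
  wE <- if (mode == "eict") En else rep(1, length(En))
  muW <- linearAttenuation(water, En) # 1/mm
  t <- seq(0, maxThickness, length.out = 81)
  S <- vapply(t, function(tt) sum(wE * share * exp(-muW * tt)), 0)
  praw <- -log(S / S[1])
  eRef <- meanEnergy(spectrum)
  muRef <- linearAttenuation(water, eRef)
  target <- muRef * t
  X <- outer(praw, seq_len(degree), "^")
  cf <- stats::coef(stats::lm.fit(X, target))
  list(coef = cf, eRef = eRef, muRef = muRef, mode = mode)
}

#' Beam-hardening correction and log-normalisation
#'
#' Maps detected channel signals to line integrals: p_raw = -ln(S / S_air)
#' passed through the calibration polynomial, so a water path of thickness t
#' maps to approximately mu_water(E_ref) t. Non-positive signals are flagged
#' and interpolated from neighbouring channels within the view.
#'
#' @param sinogram a counts-kind [Sinogram-class].
#' @param calibration from [waterCalibration()] (same spectrum and mode).
#' @return a line-integral [Sinogram-class].
#' @export
beamHardeningCorrect <- function(sinogram, calibration) {
  if (sinogram@kind == "lineintegral") stop("sinogram is already log-normalised")
  S <- sinogramValues(sinogram)
  bad <- S <= 0
  if (any(bad)) {
    for (v in which(rowSums(bad) > 0)) {
      row <- S[v, ]
      ok <- which(row > 0)
      row[-ok] <- stats::approx(ok, row[ok], xout = which(row <= 0),
                                rule = 2)$y
      S[v, ] <- row
    }
  }
  praw <- -log(S / sinogram@s0)
  p <- matrix(0, nrow(praw), ncol(praw))
  for (d in seq_along(calibration$coef))
    p <- p + calibration$coef[d] * praw^d
  new("Sinogram", values = p, mode = sinogram@mode, kind = "lineintegral",
      iproj = sinogram@iproj, s0 = sinogram@s0,
      meta = utils::modifyList(sinogram@meta,
                               list(eRef = calibration$eRef,
                                    badChannels = sum(bad))))
}

# generalised short-scan redundancy weights (smooth pairwise normalisation)
.redundancyWeights <- function(geometry) {
  a <- .ctAngles(geometry)
  arc <- geometry@arcDeg * pi / 180
  taper <- max((arc - pi) / 2 - max(abs(a$gammas)), 0.02)
  tfun <- function(b) sin(pi / 2 * pmin(pmax(pmin(b, arc - b), 0) / taper, 1))^2
  W <- matrix(1, geometry@nViews, geometry@nChannels)
  for (ci in seq_len(geometry@nChannels)) {
    g <- a$gammas[ci]
    b <- a$betas
    bConj <- b + pi + 2 * g
    bConj2 <- b + 2 * g - pi
    hasConj <- bConj <= arc | bConj2 >= 0
    bc <- ifelse(bConj <= arc, bConj, bConj2)
    tb <- tfun(b); tc <- tfun(bc)
    w <- ifelse(hasConj & (tb + tc) > 0, tb / (tb + tc), 1)
    W[, ci] <- w
  }
  W
}

# equiangular band-limited ramp kernel, apodised by a sinc window in the
# frequency domain (cutoff as a fraction of Nyquist)
.fanFilter <- function(p, dgamma, windowCutoff = 1) {
  nch <- ncol(p)
  n <- -(nch - 1):(nch - 1)
  h <- numeric(length(n))
  h[n == 0] <- 1 / (8 * dgamma^2)
  odd <- n %% 2 != 0
  h[odd] <- -0.5 / (pi * sin(n[odd] * dgamma))^2
  M <- 2^ceiling(log2(4 * nch))
  hp <- numeric(M)
  hp[1:(2 * nch - 1)] <- h
  H <- stats::fft(hp)
  freq <- pmin(0:(M - 1), M - (0:(M - 1))) / (M / 2)
  x <- pi * freq / (2 * windowCutoff)
  W <- ifelse(x == 0, 1, sin(pmin(x, pi)) / pmin(x, pi))
  W[freq > windowCutoff] <- 0
  Hw <- H * W
  out <- matrix(0, nrow(p), nch)
  for (v in seq_len(nrow(p))) {
    pp <- numeric(M)
    pp[1:nch] <- p[v, ]
    conv <- Re(stats::fft(stats::fft(pp) * Hw, inverse = TRUE)) / M
    out[v, ] <- conv[nch:(2 * nch - 1)] * dgamma
  }
  out
}

#' Fan-beam filtered backprojection (curved, equiangular detector)
#'
#' Cosine pre-weighting, sinc-apodised ramp filtering, smooth short-scan
#' redundancy weighting for the over-scanned arc, and distance-weighted
#' backprojection onto the requested grid.
#'
#' @param sinogram a line-integral [Sinogram-class].
#' @param geometry a [CTGeometry-class].
#' @param pitch reconstruction pixel pitch, mm.
#' @param n image matrix size (n x n).
#' @param windowCutoff sinc-window cutoff as a fraction of Nyquist.
#' @return a [ReconImage-class] in units of 1/mm.
#' @export
ffbpReconstruct <- function(sinogram, geometry, pitch = 0.5, n = 64,
                            windowCutoff = 1) {
  if (sinogram@kind != "lineintegral")
    stop("reconstruction expects a line-integral sinogram")
  a <- .ctAngles(geometry)
  fov <- n * pitch
  if (fov / 2 > geometry@sid * sin(max(abs(a$gammas))) * 1.5 + 1e-9)
    stop("requested grid extends far beyond the scan field of view")
  p <- sinogramValues(sinogram)
  W <- .redundancyWeights(geometry)
  pw <- p * W * matrix(geometry@sid * cos(a$gammas), nrow(p), ncol(p),
                       byrow = TRUE)
  q <- .fanFilter(pw, a$dgamma, windowCutoff)
  coords <- (seq_len(n) - (n + 1) / 2) * pitch
  pix <- expand.grid(x = coords, y = coords)
  img <- cpp_backproject(t(q), a$betas, a$gammas[1], a$dgamma, geometry@sid,
                         pix$x, pix$y)
  # pairwise redundancy weights sum to one per line; the equiangular kernel
  # carries the 1/2 of the double-covered full-scan formula, hence the 2.
  vals <- matrix(2 * img * a$dbeta, n, n)
  new("ReconImage", values = vals, pitch = pitch)
}

#' Sum congruent per-slice sinograms
#'
#' Elementwise sum of detected counts over the sub-slices of a slab.
#'
#' @param sinograms list of congruent count-kind [Sinogram-class] objects.
#' @return a [Sinogram-class] with summed values.
#' @export
slabSum <- function(sinograms) {
  stopifnot(length(sinograms) >= 1)
  ref <- sinograms[[1]]
  vals <- matrix(0, nrow(sinogramValues(ref)), ncol(sinogramValues(ref)))
  for (s in sinograms) {
    if (!identical(dim(sinogramValues(s)), dim(vals))) stop("shape mismatch")
    vals <- vals + sinogramValues(s)
  }
  initialize(ref, values = vals,
             meta = utils::modifyList(ref@meta,
                                      list(nSummed = length(sinograms))))
}

#' Sub-slice axial offsets of a slab
#'
#' @param slabWidth slab width, mm.
#' @param nSlices number of thin sub-slices.
#' @return offsets of the sub-slice centres from the slab centre, mm.
#' @export
slabOffsets <- function(slabWidth = 2, nSlices = 32) {
  (seq_len(nSlices) - (nSlices + 1) / 2) * slabWidth / nSlices
}
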