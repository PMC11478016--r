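# Shared fixtures and independent oracles for the test suite.

# independent Siddon oracle: sorted plane crossings, midpoint classification
oracleTrace <- function(p0, p1, origin, pitch, dims) {
  lower <- origin - pitch / 2
  ts <- c(0, 1)
  for (a in seq_along(dims)) {
    planes <- lower[a] + pitch[a] * (0:dims[a])
    d <- p1[a] - p0[a]
    if (abs(d) > 1e-14) ts <- c(ts, (planes - p0[a]) / d)
  }
  ts <- sort(unique(pmin(pmax(ts, 0), 1)))
  mids <- (ts[-1] + ts[-length(ts)]) / 2
  segs <- diff(ts) * sqrt(sum((p1 - p0)^2))
  idx <- sapply(seq_along(dims), function(a)
    floor((p0[a] + mids * (p1[a] - p0[a]) - lower[a]) / pitch[a]))
  keep <- apply(idx, 1, function(r) all(r >= 0 & r < dims)) & segs > 1e-12
  list(idx = idx[keep, , drop = FALSE] + 1, len = segs[keep])
}

# Monte Carlo estimate of the slit solid angle: isotropic rays from a point
# at perpendicular distance D and axial offset z from the slit centre.
mcSlitSolidAngle <- function(z, D, slitWidth, slitLength, nRays = 1e6, seed = 7) {
  set.seed(seed)
  # sample directions uniformly on the hemisphere facing the aperture plane
  u <- stats::runif(nRays); v <- stats::runif(nRays)
  cosP <- u                      # cos of angle to the plane normal
  sinP <- sqrt(1 - cosP^2)
  phi <- 2 * pi * v
  # normal = +y (toward plane at distance D); axial = x; transverse = z
  dy <- cosP
  dx <- sinP * cos(phi)
  dzt <- sinP * sin(phi)
  tHit <- D / dy
  ax <- z + dx * tHit            # axial coordinate at the aperture plane
  tr <- dzt * tHit               # transverse coordinate
  hit <- abs(ax) <= slitWidth / 2 & abs(tr) <= slitLength / 2
  # hemisphere solid angle is 2*pi
  mean(hit) * 2 * pi
}

# a tiny water slab with one optional gold voxel, beam along z
tinyPhantom <- function(goldFraction = 0, nz = 8, pitch = 0.5,
                        goldIndex = c(3, 3, 4)) {
  n <- 5
  matId <- array(2L, dim = c(n, n, nz))
  gold <- array(0, dim = c(n, n, nz))
  if (goldFraction > 0)
    gold[goldIndex[1], goldIndex[2], goldIndex[3]] <- goldFraction
  new("VoxelPhantom", materialId = matId, goldFraction = gold,
      pitch = rep(pitch, 3),
      origin = c(-(n - 1) / 2 * pitch, -(n - 1) / 2 * pitch,
                 -(nz - 1) / 2 * pitch),
      materials = list(material("air"), material("water")),
      inserts = data.frame(), rois = data.frame())
}

# monoenergetic spectrum helper: photons in the [energy, energy+1) keV bin,
# i.e. bin centre energy + 0.5
monoSpectrum <- function(energy, photons = 1e6, kvp = 120) {
  fl <- numeric(kvp)
  fl[energy + 1] <- photons
  new("Spectrum", energyEdges = as.numeric(0:kvp), fluence = fl,
      kvp = kvp, cutoff = 0)
}

emptyInserts <- function() {
  data.frame(plane = integer(), depth = numeric(), x = numeric(),
             y = numeric(), z = numeric(), diameter = numeric(),
             goldFraction = numeric())
}
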