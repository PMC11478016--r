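#' @include AllClasses.R materials.R
NULL

# Transverse slot layout for the contrast-depth phantom: two rings chosen so
# that all 24 sphere footprints are pairwise disjoint in (x, y), every sphere
# stays >= 1 mm inside the cylinder wall, and the inner ring clears the
# central background ROI (diameter 12 mm).
.contrastDepthSlots <- function() {
  angA <- seq(0, 336, by = 24) * pi / 180   # 15 slots, radius 13 mm
  angB <- seq(0, 320, by = 40) * pi / 180   # 9 slots, radius 8.5 mm
  rbind(data.frame(x = 13 * cos(angA), y = 13 * sin(angA)),
        data.frame(x = 8.5 * cos(angB), y = 8.5 * sin(angB)))
}

#' Build the contrast-depth cylinder phantom
#'
#' A 32-mm-diameter soft-tissue cylinder, long axis along the beam (z) axis,
#' holding 4-mm gold spheres at weight fractions 4.0, 2.0, 1.5, 1.0, 0.5 and
#' 0.05 % placed at beam depths 3.25, 28.75, 54.25 and 79.75 mm (sphere
#' centres). Each depth plane holds all six concentrations; transverse
#' footprints of all 24 spheres are pairwise disjoint, so any axis-parallel
#' ray meets at most one sphere. Circular gold ROIs (diameter = sphere
#' diameter) and a central background ROI (3x larger) are emitted per depth.
#'
#' The axial (z) coordinate is in the slit frame: the cylinder spans
#' [-length/2, +length/2] and beam depth d corresponds to z = d - length/2.
#'
#' @param pitch voxel pitch in mm (<= 0.5).
#' @param length cylinder length in mm (>= 84 so all depths fit).
#' @param concentrations gold weight fractions of the six inserts.
#' @param depths beam depths of the sphere centres in mm.
#' @return a [VoxelPhantom-class] with `sphereInserts()` and `phantomRois()`
#'   metadata.
#' @export
buildContrastDepthPhantom <- function(pitch = 0.5, length = 90,
                                      concentrations = c(0.04, 0.02, 0.015, 0.01, 0.005, 0.0005),
                                      depths = c(3.25, 28.75, 54.25, 79.75)) {
  if (pitch > 0.5 + 1e-9)
    stop("pitch must be <= 0.5 mm to resolve the 4-mm inserts")
  radius <- 16; sphereR <- 2
  if (max(depths) + sphereR > length || min(depths) < sphereR)
    stop("cylinder length does not cover the requested depths")
  slots <- .contrastDepthSlots()
  need <- base::length(depths) * base::length(concentrations)
  if (need > nrow(slots)) stop("transverse layout infeasible: too many inserts")

  nxy <- round(2 * radius / pitch); nz <- round(length / pitch)
  cx <- seq(-radius + pitch / 2, radius - pitch / 2, length.out = nxy)
  cz <- seq(-length / 2 + pitch / 2, length / 2 - pitch / 2, length.out = nz)

  r2 <- outer(cx^2, cx^2, "+")
  diskMask <- r2 <= radius^2
  matId <- array(1L, dim = c(nxy, nxy, nz))
  matId[rep(as.vector(diskMask), nz)] <- 2L
  gold <- array(0, dim = c(nxy, nxy, nz))

  inserts <- data.frame(plane = integer(), depth = numeric(), x = numeric(),
                        y = numeric(), z = numeric(), diameter = numeric(),
                        goldFraction = numeric())
  k <- 0
  for (p in seq_along(depths)) {
    slotIdx <- seq(p, nrow(slots), by = base::length(depths))[seq_along(concentrations)]
    for (j in seq_along(concentrations)) {
      k <- k + 1
      sx <- slots$x[slotIdx[j]]; sy <- slots$y[slotIdx[j]]
      sz <- depths[p] - length / 2
      inserts[k, ] <- list(p, depths[p], sx, sy, sz, 2 * sphereR,
                           concentrations[j])
      ix <- which(abs(cx - sx) <= sphereR + pitch)
      iy <- which(abs(cx - sy) <= sphereR + pitch)
      iz <- which(abs(cz - sz) <= sphereR + pitch)
      dd <- outer(outer((cx[ix] - sx)^2, (cx[iy] - sy)^2, "+"),
                  (cz[iz] - sz)^2, "+")
      inside <- dd <= sphereR^2
      sub <- gold[ix, iy, iz]; sub[inside] <- concentrations[j]
      gold[ix, iy, iz] <- sub
    }
  }
  # pairwise transverse disjointness (construction guarantee, verified)
  dmat <- as.matrix(stats::dist(inserts[, c("x", "y")]))
  if (any(dmat[upper.tri(dmat)] <= 2 * sphereR))
    stop("transverse sphere layout infeasible at the requested geometry")

  rois <- do.call(rbind, lapply(seq_along(depths), function(p) {
    ins <- inserts[inserts$plane == p, ]
    rbind(data.frame(label = sprintf("d%05.2f_c%g", ins$depth, 100 * ins$goldFraction),
                     shape = "circle", x = ins$x, y = ins$y, z = ins$z,
                     size = 2 * sphereR, role = "gold", plane = p,
                     goldFraction = ins$goldFraction, depth = ins$depth),
          data.frame(label = sprintf("d%05.2f_bkg", depths[p]), shape = "circle",
                     x = 0, y = 0, z = depths[p] - length / 2, size = 6 * sphereR,
                     role = "background", plane = p, goldFraction = 0,
                     depth = depths[p]))
  }))

  new("VoxelPhantom", materialId = matId, goldFraction = gold,
      pitch = rep(pitch, 3),
      origin = c(cx[1], cx[1], cz[1]),
      materials = list(material("air"), material("soft_tissue")),
      inserts = inserts, rois = rois)
}

#' Analytic 2D slice of the contrast-depth phantom
#'
#' Host and gold mass-density maps of the transverse plane at axial
#' coordinate z, sampled on an independent pitch. Used by the CT simulator so
#' that forward projection is not tied to the XFET voxelisation.
#'
#' @param inserts the `sphereInserts()` table of the phantom.
#' @param z axial coordinate of the slice (slit frame, mm).
#' @param pitch in-plane pitch in mm.
#' @param radius cylinder radius in mm.
#' @param hostDensity host tissue density in g/cm^3.
#' @return list with matrices `hostDensity` and `goldDensity` (g/cm^3) and
#'   the coordinate vector `coords` (mm).
#' @export
contrastDepthSlice <- function(inserts, z, pitch = 0.125, radius = 16,
                               hostDensity = 1.06) {
  n <- round(2 * radius / pitch)
  cx <- seq(-radius + pitch / 2, radius - pitch / 2, length.out = n)
  disk <- outer(cx^2, cx^2, "+") <= radius^2
  host <- matrix(0, n, n); host[disk] <- hostDensity
  goldW <- matrix(0, n, n)
  for (i in seq_len(nrow(inserts))) {
    dz2 <- (z - inserts$z[i])^2
    r2 <- (inserts$diameter[i] / 2)^2 - dz2
    if (r2 <= 0) next
    inside <- outer((cx - inserts$x[i])^2, (cx - inserts$y[i])^2, "+") <= r2
    goldW[inside] <- inserts$goldFraction[i]
  }
  list(hostDensity = host * (1 - goldW), goldDensity = host * goldW,
       coords = cx)
}

.paintEllipsoid <- function(matId, gold, coords, organ, idMap) {
  cx <- coords$x; cy <- coords$y; cz <- coords$z
  ix <- which(abs(cx - organ$cx) <= organ$ax)
  iy <- which(abs(cy - organ$cy) <= organ$ay)
  iz <- which(abs(cz - organ$cz) <= organ$az)
  if (!base::length(ix) || !base::length(iy) || !base::length(iz))
    return(list(matId = matId, gold = gold, painted = 0L))
  dd <- outer(outer(((cx[ix] - organ$cx) / organ$ax)^2,
                    ((cy[iy] - organ$cy) / organ$ay)^2, "+"),
              ((cz[iz] - organ$cz) / organ$az)^2, "+")
  inside <- dd <= 1
  subM <- matId[ix, iy, iz]; subG <- gold[ix, iy, iz]
  subM[inside] <- idMap[[organ$material]]
  subG[inside] <- organ$gold
  matId[ix, iy, iz] <- subM; gold[ix, iy, iz] <- subG
  list(matId = matId, gold = gold, painted = sum(inside))
}

#' Build a procedural mouse-like phantom
#'
#' A stand-in for a whole-body mouse phantom: an elliptical soft-tissue body
#' with ellipsoidal organs in ICRP tissues and the stated gold loadings --
#' 4 wt% in the kidneys, 0.75 wt% in spleen, lung, heart and a spherical
#' hind-leg tumour, and 0.12 wt% in the liver. Square ROIs are emitted over
#' each kidney, the tumour, and background abdomen. The organ layout is
#' schematic, not anatomical; absolute CNRs from it are qualitative.
#'
#' @param pitch voxel pitch in mm (<= 1).
#' @return a [VoxelPhantom-class]; the organ table is in `sphereInserts()`.
#' @export
buildMousePhantom <- function(pitch = 1) {
  if (pitch > 1 + 1e-9) stop("pitch must be <= 1 mm")
  ax <- 14; ay <- 12; len <- 90
  nx <- round(2 * (ax + 1) / pitch); ny <- round(2 * (ay + 1) / pitch)
  nz <- round(len / pitch)
  cx <- seq(-(ax + 1) + pitch / 2, (ax + 1) - pitch / 2, length.out = nx)
  cy <- seq(-(ay + 1) + pitch / 2, (ay + 1) - pitch / 2, length.out = ny)
  cz <- seq(-len / 2 + pitch / 2, len / 2 - pitch / 2, length.out = nz)

  mats <- list(material("air"), material("soft_tissue"), material("cortical_bone"),
               material("skeletal_muscle"), material("brain"),
               material("adipose"), material("lung_inflated"))
  idMap <- list(air = 1L, soft_tissue = 2L, cortical_bone = 3L,
                skeletal_muscle = 4L, brain = 5L, adipose = 6L,
                lung_inflated = 7L)

  matId <- array(1L, dim = c(nx, ny, nz))
  body <- outer((cx / ax)^2, (cy / ay)^2, "+") <= 1
  matId[rep(as.vector(body), nz)] <- 2L
  gold <- array(0, dim = c(nx, ny, nz))
  coords <- list(x = cx, y = cy, z = cz)

  organs <- data.frame(
    name = c("brain", "spine", "lung_L", "lung_R", "heart", "liver",
             "spleen", "kidney_L", "kidney_R", "tumor", "leg_muscle", "fat"),
    cx = c(0,  0, -5,  5,  0,  3, -8, -5,  5,  7,  6.5, -8),
    cy = c(0,  9, -2, -2,  2,  0,  1,  2,  2, -5, -5,   -5),
    cz = c(40, 0, 18, 18, 12,  2, -4, -12, -12, -34, -34, 6),
    ax = c(6, 1.5, 4, 4, 3, 6, 2.5, 2.5, 2.5, 2.8, 4, 3),
    ay = c(6, 1.5, 4, 4, 3, 5, 2,   2.5, 2.5, 2.8, 4, 3),
    az = c(5, 44,  7, 7, 3.5, 5, 3.5, 4.5, 4.5, 2.8, 8, 5),
    material = c("brain", "cortical_bone", "lung_inflated", "lung_inflated",
                 "skeletal_muscle", "soft_tissue", "soft_tissue", "soft_tissue",
                 "soft_tissue", "soft_tissue", "skeletal_muscle", "adipose"),
    gold = c(0, 0, 0.0075, 0.0075, 0.0075, 0.0012, 0.0075, 0.04, 0.04,
             0.0075, 0, 0))

  painted <- integer(nrow(organs))
  for (i in seq_len(nrow(organs))) {
    res <- .paintEllipsoid(matId, gold, coords, organs[i, ], idMap)
    matId <- res$matId; gold <- res$gold; painted[i] <- res$painted
  }
  organs$voxels <- painted

  rois <- data.frame(
    label = c("kidney_L", "kidney_R", "tumor", "background"),
    shape = "square",
    x = c(-5, 5, 7, 0), y = c(2, 2, -5, -5),
    z = c(-12, -12, -34, -12),
    size = c(5, 5, 5, 8),
    role = c("gold", "gold", "gold", "background"),
    plane = c(1, 1, 2, 1), goldFraction = c(0.04, 0.04, 0.0075, 0),
    depth = NA_real_)

  new("VoxelPhantom", materialId = matId, goldFraction = gold,
      pitch = rep(pitch, 3), origin = c(cx[1], cy[1], cz[1]),
      materials = mats, inserts = organs, rois = rois)
}
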