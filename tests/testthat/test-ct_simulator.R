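test_that("Siddon traversal: axis-aligned rays, misses and chord conservation", {
  org <- c(0.5, 0.5, 0.5); pit <- c(1, 1, 1); dims <- c(16, 16, 16)
  tr <- siddonTrace(c(-3, 7.2, 8.3), c(20, 7.2, 8.3), org, pit, dims)
  expect_equal(length(tr$length), 16)
  expect_true(all(abs(tr$length - 1) < 1e-9))
  expect_equal(tr$index[, 2], rep(8L, 16))
  miss <- siddonTrace(c(-3, 99, 8), c(20, 99, 8), org, pit, dims)
  expect_equal(length(miss$length), 0)
  expect_error(siddonTrace(c(1, 1, 1), c(1, 1, 1), org, pit, dims), "degenerate")
  # random rays: chord length and mu-weighted integrals vs the oracle
  set.seed(5)
  mu <- array(runif(16^3), dim = dims)
  for (k in 1:50) {
    th <- runif(2, 0, 2 * pi)
    dir <- c(sin(th[1]) * cos(th[2]), sin(th[1]) * sin(th[2]), cos(th[1]))
    p0 <- c(8, 8, 8) + 30 * dir
    p1 <- c(8, 8, 8) - 30 * dir + runif(3, -2, 2)
    tr <- siddonTrace(p0, p1, org, pit, dims)
    or <- oracleTrace(p0, p1, org, pit, dims)
    s1 <- if (length(tr$length)) sum(mu[tr$index] * tr$length) else 0
    s2 <- if (length(or$len)) sum(mu[or$idx] * or$len) else 0
    expect_equal(s1, s2, tolerance = 1e-9)
  }
})

test_that("forward projection: air, mono Beer-Lambert and polychromatic oracle", {
  geom <- ctGeometry(nChannels = 64, nViews = 30)
  # empty phantom: lambda sums to Iproj per channel-view per slice
  blank <- list(hostDensity = matrix(0, 64, 64), goldDensity = matrix(0, 64, 64),
                coords = seq(-15.875, 15.875, by = 0.5))
  sp <- generateSpectrum(120, 2.5, 0, 1e8)
  fp <- forwardProject(list(blank, blank), sp, geom, iproj = 1000)
  expect_equal(rowSums(fp$lambda), rep(2000, nrow(fp$lambda)), tolerance = 1e-9)
  # central ray through a 32-mm water square, monoenergetic
  slab <- list(hostDensity = matrix(1, 256, 256),
               goldDensity = matrix(0, 256, 256),
               coords = seq(-15.9375, 15.9375, by = 0.125))
  spm <- monoSpectrum(60, 1e6)
  fpm <- forwardProject(list(slab), spm, geom, iproj = 1e4,
                        hostMaterial = material("water"))
  muW <- linearAttenuation(material("water"), 60.5)
  a <- xfetsim:::.ctAngles(geom)
  central <- which.min(abs(a$gammas))
  lamC <- fpm$lambda[central, ]
  expect_equal(sum(lamC), 1e4 * exp(-muW * 32 / abs(cos(a$gammas[central]))),
               tolerance = 1e-6)
  # polychromatic central ray matches a bin-by-bin brute-force evaluation
  fpp <- forwardProject(list(slab), sp, geom, iproj = 1e4,
                        hostMaterial = material("water"))
  En <- fpp$energies
  share <- fluence(sp)[fluence(sp) > 0] / sum(fluence(sp)) * 1e4
  muE <- linearAttenuation(material("water"), En)
  oracle <- share * exp(-muE * 32 / abs(cos(a$gammas[central])))
  expect_equal(fpp$lambda[central, ], oracle, tolerance = 1e-6)
})

test_that("detection: zero beam, seeded draws and mono EICT = E x PCCT", {
  geom <- ctGeometry(nChannels = 8, nViews = 4)
  fp <- list(lambda = matrix(0, 32, 3), energies = c(50, 60, 70),
             share = c(1, 1, 1), nSlices = 1, geometry = geom, iproj = 3)
  expect_true(all(sinogramValues(ctDetect(fp, "pcct", 1)) == 0))
  expect_true(all(sinogramValues(ctDetect(fp, "eict", 1)) == 0))
  fp$lambda <- matrix(rep(c(0, 0, 40), each = 32), 32, 3)
  # single nonzero bin: EICT equals 70 x PCCT for identical seeds
  e <- sinogramValues(ctDetect(fp, "eict", seed = 42))
  p <- sinogramValues(ctDetect(fp, "pcct", seed = 42))
  expect_equal(e, 70 * p)
  expect_identical(sinogramValues(ctDetect(fp, "pcct", 9)),
                   sinogramValues(ctDetect(fp, "pcct", 9)))
})

test_that("EICT replicate variance matches the compound-Poisson formula", {
  geom <- ctGeometry(nChannels = 5, nViews = 1)
  En <- c(30.5, 50.5, 70.5, 90.5)
  lam <- matrix(c(200, 150, 100, 50), 5, 4, byrow = TRUE) *
    matrix(seq(0.5, 1.5, length.out = 5), 5, 4)
  fp <- list(lambda = lam, energies = En, share = colMeans(lam), nSlices = 1,
             geometry = geom, iproj = 1)
  nrep <- 4000
  draws <- matrix(0, nrep, 5)
  for (r in seq_len(nrep))
    draws[r, ] <- sinogramValues(ctDetect(fp, "eict", seed = 5000 + r))[1, ]
  vHat <- apply(draws, 2, var)
  vTrue <- as.vector(lam %*% En^2)
  expect_equal(vHat, vTrue, tolerance = 0.1)
  mTrue <- as.vector(lam %*% En)
  expect_equal(colMeans(draws), mTrue, tolerance = 0.02)
})

test_that("beam-hardening correction: zero point, mono identity, water self-consistency", {
  sp <- generateSpectrum(120, 2.5, 0, 1e8)
  for (mode in c("pcct", "eict")) {
    cal <- waterCalibration(sp, mode)
    # zero thickness maps to zero (zero-intercept fit)
    evalPoly <- function(p) sum(cal$coef * p^seq_along(cal$coef))
    expect_equal(evalPoly(0), 0)
    # 20-mm water slab maps to muRef x 20 within 0.5%
    water <- material("water")
    cent <- binCenters(sp); keep <- fluence(sp) > 0
    En <- cent[keep]; share <- fluence(sp)[keep]
    wE <- if (mode == "eict") En else rep(1, length(En))
    S <- sum(wE * share * exp(-linearAttenuation(water, En) * 20))
    praw <- -log(S / sum(wE * share))
    expect_equal(evalPoly(praw), cal$muRef * 20, tolerance = 0.005)
  }
  # monoenergetic spectrum: correction is the identity up to fit residual
  spm <- monoSpectrum(60, 1e6)
  calm <- waterCalibration(spm, "pcct")
  for (p in c(0.1, 0.4, 0.7))
    expect_equal(sum(calm$coef * p^seq_along(calm$coef)), p, tolerance = 1e-6)
})

test_that("non-positive channels are interpolated before the log", {
  geom <- ctGeometry(nChannels = 6, nViews = 2)
  vals <- matrix(100, 2, 6); vals[1, 3] <- 0
  sino <- new("Sinogram", values = vals, mode = "pcct", kind = "counts",
              iproj = 100, s0 = 100, meta = list())
  cal <- waterCalibration(monoSpectrum(60), "pcct")
  li <- beamHardeningCorrect(sino, cal)
  expect_true(all(is.finite(sinogramValues(li))))
  expect_equal(li@meta$badChannels, 1)
})

test_that("FFBP: zero data, water-cylinder fidelity and centroid localisation", {
  geom <- ctGeometry()
  zeroSino <- new("Sinogram",
                  values = matrix(0, geom@nViews, geom@nChannels),
                  mode = "pcct", kind = "lineintegral", iproj = 1, s0 = 1,
                  meta = list())
  expect_true(all(imageValues(ffbpReconstruct(zeroSino, geom, 0.5, 64)) == 0))
  spm <- monoSpectrum(60, 1e6)
  sl <- contrastDepthSlice(emptyInserts(), z = 0, pitch = 0.125,
                           hostDensity = 1.0)
  fp <- forwardProject(list(sl), spm, geom, 1e6,
                       hostMaterial = material("water"))
  cal <- waterCalibration(spm, "pcct")
  rec <- ffbpReconstruct(beamHardeningCorrect(ctDetect(fp, "pcct",
                                                       noiseFree = TRUE), cal),
                         geom, 0.5, 64)
  muW <- linearAttenuation(material("water"), 60.5)
  co <- (seq_len(64) - 32.5) * 0.5
  roi <- outer(co^2, co^2, "+") <= 25
  expect_equal(mean(imageValues(rec)[roi]), muW, tolerance = 0.02)
  # offset high-contrast disk: centroid within one voxel
  ins <- data.frame(plane = 1, depth = 0, x = 6, y = -4, z = 0, diameter = 3,
                    goldFraction = 0.04)
  sl2 <- contrastDepthSlice(ins, z = 0, pitch = 0.125, hostDensity = 1.0)
  fp2 <- forwardProject(list(sl2), spm, geom, 1e6,
                        hostMaterial = material("water"))
  rec2 <- ffbpReconstruct(beamHardeningCorrect(ctDetect(fp2, "pcct",
                                                        noiseFree = TRUE), cal),
                          geom, 0.5, 64)
  vd <- imageValues(rec2) - imageValues(rec)
  m <- pmax(vd - 0.5 * max(vd), 0)
  cxy <- c(sum(outer(co, rep(1, 64)) * m), sum(outer(rep(1, 64), co) * m)) / sum(m)
  expect_lt(max(abs(cxy - c(6, -4))), 0.5)
})

test_that("short-scan redundancy weights sum to one over conjugate ray pairs", {
  geom <- ctGeometry()
  W <- xfetsim:::.redundancyWeights(geom)
  a <- xfetsim:::.ctAngles(geom)
  arc <- geom@arcDeg * pi / 180
  set.seed(1)
  for (k in 1:200) {
    ci <- sample(geom@nChannels, 1)
    g <- a$gammas[ci]
    bc1 <- a$betas + pi + 2 * g
    vsel <- which(bc1 <= arc)
    if (!length(vsel)) next
    v <- sample(vsel, 1)
    # conjugate ray: view at beta + pi + 2 gamma, channel at -gamma
    cj <- which.min(abs(a$gammas + g))
    vj <- which.min(abs(a$betas - bc1[v]))
    expect_equal(W[v, ci] + W[vj, cj], 1, tolerance = 0.06)
  }
})

test_that("slab summation is linear and permutation invariant", {
  mk <- function(v) new("Sinogram", values = v, mode = "pcct", kind = "counts",
                        iproj = 1, s0 = 1, meta = list())
  set.seed(2)
  v <- matrix(rpois(60, 10), 6, 10)
  s32 <- slabSum(rep(list(mk(v)), 32))
  expect_equal(sinogramValues(s32), 32 * v)
  sl <- lapply(1:5, function(i) mk(matrix(rpois(60, 5), 6, 10)))
  expect_equal(sinogramValues(slabSum(sl)), sinogramValues(slabSum(rev(sl))))
  air <- slabSum(rep(list(mk(matrix(7, 6, 10))), 4))
  expect_true(all(sinogramValues(air) == 28))
  expect_error(slabSum(list(mk(v), mk(matrix(0, 2, 2)))), "mismatch")
})
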