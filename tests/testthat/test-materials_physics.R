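test_that("mixture rule: zero admixture is the identity and mixing is linear", {
  st <- material("soft_tissue")
  E <- c(20, 40, 68.804, 100)
  expect_equal(massAttenuation(goldMix(st, 0), E), massAttenuation(st, E))
  # 50/50 mass mixture at equal density averages the component mu/rho
  a <- material("water"); b <- material("adipose")
  mix <- newMaterial("half", c(a@composition * 0.5, b@composition * 0.5),
                     a@density)
  expect_equal(massAttenuation(mix, E),
               0.5 * massAttenuation(a, E) + 0.5 * massAttenuation(b, E),
               tolerance = 1e-12)
})

test_that("1-mm lead transmits on the order of 1-2% at the gold Kalpha1 energy", {
  pb <- material("lead")
  trans <- exp(-linearAttenuation(pb, 68.804) * 1)
  expect_gt(trans, 0.005)
  expect_lt(trans, 0.025)
})

test_that("mu decreases with energy between edges and attenuation is convex in mass fractions", {
  E <- seq(12, 148, by = 2)
  for (m in c("soft_tissue", "water", "cortical_bone", "adipose"))
    expect_true(all(diff(massAttenuation(material(m), E)) < 0), info = m)
  # convexity (here: exact linearity) of the mixture rule
  a <- material("water"); b <- material("cortical_bone")
  for (f in c(0.25, 0.5, 0.75)) {
    mix <- newMaterial("m", c(a@composition * f, b@composition * (1 - f)), 1)
    expect_equal(massAttenuation(mix, 50),
                 f * massAttenuation(a, 50) + (1 - f) * massAttenuation(b, 50),
                 tolerance = 1e-12)
  }
})

test_that("unknown elements and out-of-range energies are rejected", {
  expect_error(elementMassAttenuation("Xx", 50), "unknown element")
  expect_error(newMaterial("bad", c(Qq = 1), 1), "unknown element")
  expect_error(elementMassAttenuation("O", 0.5), "energy")
  expect_error(elementMassAttenuation("O", 200), "energy")
  expect_error(material("unobtainium"), "unknown material")
})

test_that("material validity enforces normalised composition and positive density", {
  expect_error(newMaterial("bad", c(H = 0.5, O = 0.4), 1), "sum to 1")
  expect_error(newMaterial("bad", c(H = 0.1119, O = 0.8881), -1), "density")
})

test_that("spectrum model: degenerate windows, scaling and validity", {
  one <- generateSpectrum(120, 2.5, cutoff = 119, histories = 1e6)
  expect_equal(sum(fluence(one) > 0), 1)
  zero <- generateSpectrum(120, 2.5, cutoff = 0, histories = 0)
  expect_true(all(fluence(zero) == 0))
  expect_error(generateSpectrum(120, cutoff = 120), "empty")
  sp <- generateSpectrum(120, 2.5, 0, 1.25e8)
  expect_equal(sum(fluence(sp)), 1.25e8)
  # truncation keeps the full-beam scale: the >cutoff part is unchanged
  spc <- generateSpectrum(120, 2.5, cutoff = 65.263, histories = 1.25e8)
  cent <- binCenters(sp)
  keep <- cent >= 65.263
  expect_equal(fluence(spc)[keep], fluence(sp)[keep])
  frac <- spectrumFractionAbove(sp, 65.263)
  expect_gt(frac, 0.05); expect_lt(frac, 0.5)
})

test_that("fluorescence production is linear and matches a bin-by-bin oracle", {
  expect_equal(fluorescenceProduction(0, 1e6, 85), 0)
  p1 <- fluorescenceProduction(0.01, c(1e5, 2e5), c(85, 95), voxelLength = 0.5)
  p2 <- fluorescenceProduction(0.02, c(1e5, 2e5), c(85, 95), voxelLength = 0.5)
  expect_equal(p2 / p1, 2, tolerance = 1e-9)
  expect_error(fluorescenceProduction(-1, 1e5, 85), "non-negative")
  # 4 wt% voxel (rho_host 1.06) under monoenergetic 85-keV fluence:
  # independent product-chain evaluation
  rhoAu <- 0.04 * 1.06
  flu <- 2.5e6; len <- 0.5
  tau <- (8.904 - 2.066) * (80.725 / 85)^2.55 * rhoAu / 10
  oracle <- flu * tau * len * 0.96 * 0.47
  expect_equal(fluorescenceProduction(rhoAu, flu, 85, len), oracle,
               tolerance = 1e-12)
  # below the K edge nothing is produced
  expect_equal(fluorescenceProduction(rhoAu, flu, 79), 0)
})

test_that("Compton kinematics and Klein-Nishina limits", {
  expect_equal(comptonScatteredEnergy(80, 0), 80)
  expect_true(all(comptonScatteredEnergy(c(20, 80, 120), pi / 3) <=
                    c(20, 80, 120)))
  # Thomson limit of the total cross section
  sigmaT <- 6.6524587e-25
  expect_equal(kleinNishinaTotal(0.01), sigmaT, tolerance = 2e-4)
  # differential integrates to the closed-form total (quadrature oracle,
  # midpoint rule refined to convergence)
  for (E in c(30, 80)) {
    nq <- 4000
    th <- (seq_len(nq) - 0.5) * pi / nq
    num <- sum(kleinNishinaDifferential(E, th) * 2 * pi * sin(th)) * pi / nq
    expect_equal(num, kleinNishinaTotal(E), tolerance = 1e-6)
  }
  # material rate = electron density x KN
  st <- material("soft_tissue")
  r <- comptonScatterRate(st, 80, pi / 2)
  expect_equal(r$rate,
               electronDensity(st) * kleinNishinaDifferential(80, pi / 2) / 10)
  expect_equal(r$scatteredEnergy, 80 / (1 + 80 / 510.99895))
})
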