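# Builds the plain-text physics tables shipped under inst/extdata/.
# Anchor values (>= 10 keV) transcribed from the standard Hubbell & Seltzer /
# XCOM mass-attenuation compilations; below 10 keV the tables are extended with
# a photoelectric E^-3 term plus the exact Klein-Nishina incoherent term.
# Run from the repository root: Rscript tools/make-attenuation-tables.R

e10 <- c(10, 15, 20, 30, 40, 50, 60, 80, 100, 150)

anchors <- list(
  H  = list(Z = 1,  A = 1.008,
            mu = c(0.3854, 0.3764, 0.3695, 0.3570, 0.3458, 0.3355, 0.3260, 0.3091, 0.2944, 0.2651)),
  C  = list(Z = 6,  A = 12.011,
            mu = c(2.373, 0.8071, 0.4420, 0.2562, 0.2076, 0.1871, 0.1753, 0.1610, 0.1514, 0.1347)),
  N  = list(Z = 7,  A = 14.007,
            mu = c(3.879, 1.236, 0.6178, 0.3066, 0.2288, 0.1980, 0.1817, 0.1639, 0.1529, 0.1353)),
  O  = list(Z = 8,  A = 15.999,
            mu = c(5.952, 1.836, 0.8651, 0.3779, 0.2585, 0.2132, 0.1907, 0.1678, 0.1551, 0.1361)),
  Na = list(Z = 11, A = 22.990,
            mu = c(15.43, 4.694, 2.057, 0.7197, 0.3969, 0.2804, 0.2268, 0.1796, 0.1585, 0.1335)),
  Mg = list(Z = 12, A = 24.305,
            mu = c(20.99, 6.358, 2.763, 0.9306, 0.4881, 0.3292, 0.2570, 0.1944, 0.1686, 0.1394)),
  Al = list(Z = 13, A = 26.982,
            mu = c(26.23, 7.955, 3.441, 1.128, 0.5685, 0.3681, 0.2778, 0.2018, 0.1704, 0.1378)),
  P  = list(Z = 15, A = 30.974,
            mu = c(40.52, 12.45, 5.358, 1.700, 0.8096, 0.5033, 0.3604, 0.2435, 0.1992, 0.1516)),
  S  = list(Z = 16, A = 32.06,
            mu = c(50.12, 15.47, 6.708, 2.113, 0.9872, 0.5984, 0.4166, 0.2704, 0.2149, 0.1585)),
  Cl = list(Z = 17, A = 35.45,
            mu = c(57.30, 17.84, 7.739, 2.426, 1.117, 0.6618, 0.4505, 0.2815, 0.2190, 0.1566)),
  K  = list(Z = 19, A = 39.098,
            mu = c(79.10, 24.77, 10.79, 3.382, 1.541, 0.8887, 0.5863, 0.3418, 0.2541, 0.1678)),
  Ca = list(Z = 20, A = 40.078,
            mu = c(93.41, 29.32, 12.81, 4.023, 1.830, 1.048, 0.6837, 0.3877, 0.2810, 0.1768))
)

# Heavy elements carry their own grids with K-edge pairs (L-edge fine structure
# below 15-16 keV is smoothed over; negligible for a 120-kVp beam in tissue).
heavy <- list(
  Au = list(Z = 79, A = 196.967,
            e  = c(10, 15, 20, 30, 40, 50, 60, 70, 80, 80.724, 80.726, 90, 100, 120, 150),
            mu = c(113.0, 164.0, 77.5, 27.2, 13.09, 7.256, 4.528, 3.034, 2.137,
                   2.066, 8.904, 6.661, 5.158, 3.240, 1.856)),
  Pb = list(Z = 82, A = 207.2,
            e  = c(10, 15, 20, 30, 40, 50, 60, 70, 80, 88.004, 88.006, 100, 120, 150),
            mu = c(130.6, 111.6, 86.36, 30.32, 14.36, 8.041, 5.021, 3.518, 2.419,
                   1.910, 7.683, 5.549, 3.500, 2.014))
)

# Klein-Nishina total cross section per electron (cm^2), E in keV
kn_sigma <- function(E) {
  k <- E / 510.99895
  r_e2 <- 7.94077e-26 # classical electron radius squared, cm^2
  2 * pi * r_e2 * ((1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
                   log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2)
}

NA_AVOG <- 6.02214076e23
elow <- c(1, 1.5, 2, 3, 4, 5, 6, 8)

rows <- list()
for (el in names(anchors)) {
  a <- anchors[[el]]
  kn10 <- a$Z / a$A * NA_AVOG * kn_sigma(10)
  pe10 <- max(a$mu[1] - kn10, 0)
  mu_low <- pe10 * (10 / elow)^3 + a$Z / a$A * NA_AVOG * kn_sigma(elow)
  rows[[el]] <- data.frame(element = el, Z = a$Z, A = a$A,
                           energy_keV = c(elow, e10),
                           mu_rho = c(mu_low, a$mu))
}
for (el in names(heavy)) {
  h <- heavy[[el]]
  # extend below 10 keV with an E^-2.6 photoelectric slope from the 10-keV anchor
  mu_low <- h$mu[1] * (10 / elow)^2.6
  rows[[el]] <- data.frame(element = el, Z = h$Z, A = h$A,
                           energy_keV = c(elow, h$e),
                           mu_rho = c(mu_low, h$mu))
}
tab <- do.call(rbind, rows)
write.csv(tab, "inst/extdata/element_mu_rho.csv", row.names = FALSE, quote = FALSE)

# Mass energy-absorption coefficients for ICRP soft tissue (cm^2/g); the dose
# tally only claims order-of-magnitude fidelity, so the water-like compound
# values are used for all tissues.
muen <- data.frame(
  energy_keV = c(1, 1.5, 2, 3, 4, 5, 6, 8, 10, 15, 20, 30, 40, 50, 60, 80, 100, 150),
  muen_rho   = c(rep(NA_real_, 8),
                 4.944, 1.374, 0.5503, 0.1557, 0.06947, 0.04223, 0.03190,
                 0.02597, 0.02546, 0.02764))
# entries below 10 keV: E^-3 photoelectric scaling of the 10-keV anchor
muen$muen_rho[1:8] <- 4.944 * (10 / muen$energy_keV[1:8])^3
write.csv(muen, "inst/extdata/muen_soft_tissue.csv", row.names = FALSE, quote = FALSE)

# ICRP/ICRU material compositions (mass fractions) and densities (g/cm^3)
comp <- function(name, density, ...) {
  w <- c(...)
  data.frame(material = name, density = density,
             element = names(w), mass_fraction = unname(w))
}
mats <- rbind(
  comp("soft_tissue", 1.06, H = 0.102, C = 0.143, N = 0.034, O = 0.708,
       Na = 0.002, P = 0.003, S = 0.003, Cl = 0.002, K = 0.003),
  comp("water", 1.00, H = 0.1119, O = 0.8881),
  comp("cortical_bone", 1.92, H = 0.034, C = 0.155, N = 0.042, O = 0.435,
       Na = 0.001, Mg = 0.002, P = 0.103, S = 0.003, Ca = 0.225),
  comp("skeletal_muscle", 1.05, H = 0.102, C = 0.143, N = 0.034, O = 0.710,
       Na = 0.001, P = 0.002, S = 0.003, Cl = 0.001, K = 0.004),
  comp("adipose", 0.95, H = 0.114, C = 0.598, N = 0.007, O = 0.278,
       Na = 0.001, S = 0.001, Cl = 0.001),
  comp("brain", 1.04, H = 0.107, C = 0.145, N = 0.022, O = 0.712,
       Na = 0.002, P = 0.004, S = 0.002, Cl = 0.003, K = 0.003),
  comp("lung_inflated", 0.26, H = 0.103, C = 0.105, N = 0.031, O = 0.749,
       Na = 0.002, P = 0.002, S = 0.003, Cl = 0.003, K = 0.002),
  comp("gold", 19.32, Au = 1),
  comp("lead", 11.35, Pb = 1),
  comp("aluminum", 2.699, Al = 1),
  comp("air", 0.0012, N = 0.767, O = 0.233)
)
write.csv(mats, "inst/extdata/materials_icrp.csv", row.names = FALSE, quote = FALSE)

cat("tables written\n")
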