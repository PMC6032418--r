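test_that("generators are deterministic given a seed", {
  a <- sim_inversion_recovery(1.54, noise_sd = 1, seed = 3)
  b <- sim_inversion_recovery(1.54, noise_sd = 1, seed = 3)
  expect_identical(a$heights, b$heights)

  i1 <- sim_isotherm(17.1, 0.05, noise_sd = 1e-3, seed = 3)
  i2 <- sim_isotherm(17.1, 0.05, noise_sd = 1e-3, seed = 3)
  expect_identical(i1$delta_A, i2$delta_A)

  s1 <- sim_soret_spectrum(0.27, noise_sd = 0.01, seed = 3)
  s2 <- sim_soret_spectrum(0.27, noise_sd = 0.01, seed = 3)
  expect_identical(s1$absorbance, s2$absorbance)

  g1 <- sim_study_from_distances(c(a = 6.5), 0.017, 171, 17.1, 0.27,
                                 3.38e-10, noise_sd = 0.01, seed = 3)
  g2 <- sim_study_from_distances(c(a = 6.5), 0.017, 171, 17.1, 0.27,
                                 3.38e-10, noise_sd = 0.01, seed = 3)
  expect_identical(g1$t1_pairs, g2$t1_pairs)
  # different seed gives different noise
  g3 <- sim_study_from_distances(c(a = 6.5), 0.017, 171, 17.1, 0.27,
                                 3.38e-10, noise_sd = 0.01, seed = 4)
  expect_false(identical(g1$t1_pairs$t1_ferric, g3$t1_pairs$t1_ferric))
})

test_that("inversion-recovery generator honours the recovery limits", {
  s <- sim_inversion_recovery(2, h_inf = 50, b = 1,
                              delays = c(0, 1, 2, 100), noise_sd = 0)
  expect_equal(s$heights[1], -50)            # perfect inversion at d = 0
  expect_equal(s$heights[4], 50, tolerance = 1e-12)  # full recovery
})

test_that("isotherm generator honours the hyperbola's landmarks", {
  iso <- sim_isotherm(10, 0.04, concentrations = c(0, 1, 5, 10, 50),
                      noise_sd = 0)
  expect_equal(iso$delta_A[1], 0)
  expect_equal(iso$delta_A[iso$substrate_conc == 10], 0.02)
})

test_that("Soret generator partitions area by the spin fractions", {
  lam <- seq(320, 500, by = 0.5)
  sp <- sim_soret_spectrum(0, total_area = 100, delta_area = 30,
                           wavelengths = lam, noise_sd = 0)
  # no high-spin band: the 392 nm region carries only band tails
  tails <- 100 / (12 * sqrt(2 * pi)) * exp(-(392 - 417)^2 / (2 * 12^2)) +
    30 / (18 * sqrt(2 * pi)) * exp(-(392 - 360)^2 / (2 * 18^2))
  expect_equal(sp$absorbance[lam == 392], tails, tolerance = 1e-9)
  # integrated spectrum equals total band area (trapezoid quadrature)
  total <- sum(diff(lam) * (head(sp$absorbance, -1) +
                              sp$absorbance[-1]) / 2)
  # band tails truncated at the window edges cost a few tenths of a unit
  expect_equal(total, 130, tolerance = 0.01)
})

test_that("distance-generated studies embed consistent ground truth", {
  st <- sim_study_from_distances(c("-OCH2-" = 6.55), p450_uM = 0.017,
                                 substrate_uM = 171, ks_uM = 17.1,
                                 f_high = 0.27, tau_c_s = 3.38e-10,
                                 noise_sd = 0, seed = 12)
  # implied T1P matches the forward rate-difference computation
  gt <- st$ground_truth
  p <- st$t1_pairs
  expect_equal(t1p_from_pair(p$t1_ferric, p$t1_ferrous_co)$t1p,
               unname(gt$t1p), tolerance = 1e-9)
  # the WT -OCH2- target implies a T1P in the measured pair's family
  expect_equal(unname(gt$t1p), 9.19, tolerance = 0.15)
  expect_true(p$t1_ferrous_co >= 1 && p$t1_ferrous_co <= 5)
  expect_lt(p$t1_ferric, p$t1_ferrous_co)
})
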