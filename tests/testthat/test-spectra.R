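test_that("stick strengths match the direct cross-section arithmetic", {
  # omega = 10 hartree, |d|^2 = 0.01
  tab <- transition_table(0, eps_core = -10, eps_vac = 0,
                          dip_x = 0.1, dip_y = 0, dip_z = 0)
  got <- stick_strength(tab)
  oracle <- brute_stick(-10, 0, c(0.1, 0, 0))
  expect_equal(got$strength, oracle$strength, tolerance = 1e-12)
  expect_equal(got$strength, 9.602931e-3, tolerance = 1e-6)
  expect_equal(got$energy_ev, oracle$energy_ev, tolerance = 1e-12)

  # |d|^2 homogeneity: doubling every component quadruples the strength
  tab2 <- transition_table(0, -10, 0, 0.2, 0, 0)
  expect_equal(stick_strength(tab2)$strength, 4 * got$strength,
               tolerance = 1e-12)

  # dark transition
  expect_equal(stick_strength(transition_table(0, -10, 0, 0, 0, 0))$strength, 0)
})

test_that("broadening uses unit-area Lorentzians of the stated FWHM", {
  grid <- seq(280, 300, by = 0.002)
  sticks <- data.frame(energy_ev = 290, strength = 0.7)
  sp <- broaden(sticks, grid, line_shape_params(lorentz_fwhm = 0.5))
  # peak of a unit-area Lorentzian is 2/(pi*Gamma)
  expect_equal(max(sp$sigma), 0.7 * 2 / (pi * 0.5), tolerance = 1e-6)
  expect_equal(grid[which.max(sp$sigma)], 290, tolerance = 0.002)

  # quadrature over +/- 50 Gamma recovers the stick strength within 2%
  wide <- seq(290 - 25, 290 + 25, by = 0.005)
  spw <- broaden(sticks, wide, line_shape_params(lorentz_fwhm = 0.5))
  area <- sum(spw$sigma) * 0.005
  expect_lt(abs(area - 0.7) / 0.7, 0.02)

  # linearity: two identical sticks = exactly twice one stick
  two <- broaden(rbind(sticks, sticks), grid, line_shape_params())
  expect_equal(two$sigma, 2 * sp$sigma, tolerance = 1e-14)

  # empty stick list is a zero spectrum, not an error
  none <- broaden(data.frame(energy_ev = numeric(0), strength = numeric(0)),
                  grid, line_shape_params())
  expect_true(all(none$sigma == 0))
})

test_that("ensemble averaging equals the direct double-loop oracle", {
  grid <- seq(284, 292, by = 0.05)
  t1 <- transition_table(c(0, 1), eps_core = -11.4,
                         eps_vac = -11.4 + c(10.53, 10.56) / 27.211386,
                         dip_x = c(0.1, 0.12), dip_y = 0, dip_z = 0.02)
  t2 <- transition_table(c(0, 1), eps_core = -11.4,
                         eps_vac = -11.4 + c(10.50, 10.58) / 27.211386,
                         dip_x = 0, dip_y = c(0.05, 0.2), dip_z = 0)
  m <- ensemble_map(list(t1, t2), grid, line_shape_params(lorentz_fwhm = 0.5))
  for (i in 1:2) {
    s1 <- brute_stick(t1$eps_core[i], t1$eps_vac[i],
                      c(t1$dip_x[i], t1$dip_y[i], t1$dip_z[i]))
    s2 <- brute_stick(t2$eps_core[i], t2$eps_vac[i],
                      c(t2$dip_x[i], t2$dip_y[i], t2$dip_z[i]))
    oracle <- (brute_lorentzian(s1$energy_ev, s1$strength, grid, 0.5) +
                 brute_lorentzian(s2$energy_ev, s2$strength, grid, 0.5)) / 2
    expect_equal(m$values[i, ], oracle, tolerance = 1e-12)
  }

  # mean of identical trajectories is the single-trajectory map
  same <- ensemble_map(list(t1, t1, t1), grid)
  single <- ensemble_map(list(t1), grid)
  expect_equal(same$values, single$values, tolerance = 1e-14)

  # one dark trajectory halves the map
  dark <- t1
  dark$dip_x <- dark$dip_y <- dark$dip_z <- 0
  half <- ensemble_map(list(t1, dark), grid)
  expect_equal(half$values, single$values / 2, tolerance = 1e-14)

  # ragged time grids are refused with advice
  t3 <- transition_table(c(0, 2), -11.4, -11, 0.1, 0, 0)
  expect_error(ensemble_map(list(t1, t3), grid), "resample")
})

test_that("time convolution preserves DC signals and areas, and has the right FWHM", {
  delays <- seq(-100, 100, by = 0.5)
  grid <- c(287, 288)
  const <- transient_map(delays, grid, matrix(3.2, length(delays), 2),
                         kind = "sigma")
  conv <- convolve_time(const, 10)
  expect_equal(conv$values, const$values, tolerance = 1e-12)

  # impulse response: FWHM = 10 fs measured by interpolation
  imp <- matrix(0, length(delays), 2)
  imp[delays == 0, ] <- 1
  m <- transient_map(delays, grid, imp, kind = "sigma")
  r <- convolve_time(m, 10)$values[, 1]
  half <- max(r) / 2
  above <- which(r >= half)
  lo <- above[1]; hi <- above[length(above)]
  f_lo <- delays[lo - 1] + (half - r[lo - 1]) / (r[lo] - r[lo - 1]) * 0.5
  f_hi <- delays[hi] + (r[hi] - half) / (r[hi] - r[hi + 1]) * 0.5
  expect_equal(f_hi - f_lo, 10, tolerance = 0.1)
  # interior signal area is conserved
  expect_equal(sum(r) * 0.5, sum(imp[, 1]) * 0.5, tolerance = 1e-3)

  non_uniform <- transient_map(c(0, 1, 3), grid, matrix(0, 3, 2))
  expect_error(convolve_time(non_uniform, 10), "uniform")
})

test_that("calibration shifts the axis and commutes with broadening", {
  cal <- calibration_constants()
  expect_equal(cal$downshift, 15.7, tolerance = 1e-9)
  grid <- seq(280, 300, by = 0.02)
  tab <- transition_table(0, -11.4, -11.4 + 299 / 27.211386, 0.1, 0, 0)
  m <- ensemble_map(list(tab), grid)
  shifted <- apply_calibration(m, cal)
  expect_equal(shifted$energies, m$energies - 15.7 + 3.2, tolerance = 1e-9)
  expect_identical(shifted$values, m$values)

  # zero constants = identity; negated constants invert
  id <- apply_calibration(m, calibration_constants(300, 300, upshift = 0))
  expect_equal(id$energies, m$energies)
  inv <- apply_calibration(shifted,
                           calibration_constants(downshift = -15.7,
                                                 upshift = -3.2,
                                                 calc_core_binding = NULL,
                                                 exp_core_ip = NULL))
  expect_equal(inv$energies, m$energies, tolerance = 1e-9)

  # shift-then-broaden equals broaden-then-shift on a common grid
  sticks <- stick_strength(tab)
  direct <- broaden(data.frame(energy_ev = sticks$energy_ev - 12.5,
                               strength = sticks$strength), grid - 12.5,
                    line_shape_params())
  expect_equal(shifted$values[1, ], direct$sigma, tolerance = 1e-12)
})

test_that("calibration arithmetic is enforced on construction", {
  expect_error(calibration_constants(310.21, 294.51, downshift = 10),
               "inconsistent")
  expect_error(estimate_valence_ip(287.6, 294.51), "swapped")
  expect_error(gas_phase_lowering(6.91, 10.28), "swapped")
  expect_equal(correct_reference_ip(294.0, 11.16, 11.16), 294.0)
  expect_equal(correct_reference_ip(294.0, 11.16, 11.41), 294.25)
  expect_equal(derive_downshift(295.0, 294.51), 0.49, tolerance = 1e-12)
})

test_that("delta-OD follows the decade definition and the bleach sign pattern", {
  delays <- c(0, 100)
  en <- seq(285, 292, by = 0.1)
  I0 <- transient_map(delays, en, matrix(1, 2, length(en)), kind = "sigma")
  expect_equal(delta_od(I0, I0)$values, matrix(0, 2, length(en)))

  Ip <- I0
  Ip$values[1, 10] <- 0.1
  dod <- delta_od(Ip, I0)
  expect_equal(dod$values[1, 10], 1)
  expect_identical(dod$kind, "dod")

  expect_error(delta_od(transient_map(delays, en,
                                      matrix(-1, 2, length(en)), kind = "dod"),
                        I0), "positive")

  # two-species model: pump converts a fraction of ground state (pi* at 290)
  # to an excited species absorbing at 287.6 -> bleach at 290, gain below
  od_gs <- 0.5 * exp(-(en - 290)^2 / (2 * 0.3^2))
  od_exc <- 0.5 * exp(-(en - 287.6)^2 / (2 * 0.3^2))
  f <- 0.2
  I_unpump <- transient_map(delays, en,
                            matrix(10^-od_gs, 2, length(en), byrow = TRUE),
                            kind = "sigma")
  I_pump <- transient_map(delays, en,
                          matrix(10^-((1 - f) * od_gs + f * od_exc), 2,
                                 length(en), byrow = TRUE), kind = "sigma")
  dod2 <- delta_od(I_pump, I_unpump)
  expect_lt(dod2$values[1, which.min(abs(en - 290))], 0)
  expect_gt(dod2$values[1, which.min(abs(en - 287.6))], 0)
})

test_that("whole synthesis chain is linear in stick strengths", {
  grid <- seq(284, 292, by = 0.1)
  tab <- transition_table(c(0, 1, 2), -11.4,
                          -11.4 + c(10.5, 10.55, 10.6) / 27.211386,
                          dip_x = c(0.1, 0.15, 0.2), dip_y = 0, dip_z = 0)
  tab2 <- tab
  tab2$dip_x <- tab$dip_x * 3   # strengths scale by 9
  m1 <- convolve_time(ensemble_map(list(tab), grid), 10)
  m2 <- convolve_time(ensemble_map(list(tab2), grid), 10)
  expect_equal(m2$values, 9 * m1$values, tolerance = 1e-10)
  expect_true(all(m1$values >= 0))
})
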