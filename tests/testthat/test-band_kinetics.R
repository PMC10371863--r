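three_bands <- function(amp = c(1, 1, 1)) {
  data.frame(center = c(286.7, 287.3, 287.6), width = c(0.15, 0.18, 0.22),
             amplitude = amp, kind = c("decay", "decay", "rise"),
             tau = c(110, 290, 591))
}
default_init <- function() band_model(c(286.6, 287.35, 287.7), c(0.2, 0.2, 0.2))

test_that("band model fit recovers a noiseless map to numerical precision", {
  bands <- three_bands()
  m <- generate_experimental_map(bands, irf_fwhm = 30, noise_sd = 0,
                                 energies = seq(285.5, 288.5, by = 0.05))
  bf <- fit_band_model(m, default_init(), c(285.5, 288.5), n_starts = 2)
  expect_equal(bf$centers, bands$center, tolerance = 1e-6)
  expect_equal(bf$widths, bands$width, tolerance = 1e-6)
  truth <- attr(m, "truth")
  # reconstruct amplitudes: truth is peak-height parameterised
  sd_irf <- 30 / (2 * sqrt(2 * log(2)))
  for (k in 1:3) {
    a_true <- bands$amplitude[k] *
      txas:::exp_kinetics(m$delays, bands$tau[k], bands$kind[k], sd_irf)
    expect_equal(unname(bf$amplitudes[k, ]), a_true, tolerance = 1e-5)
  }
})

test_that("an identically zero map yields zero amplitudes and the init shape", {
  m <- transient_map(seq(-200, 2000, by = 100), seq(285.5, 288.5, by = 0.05),
                     matrix(0, 23, 61), kind = "dod")
  bf <- fit_band_model(m, default_init(), c(285.5, 288.5), n_starts = 1)
  expect_true(all(bf$amplitudes == 0))
  expect_equal(bf$centers, default_init()$centers, tolerance = 1e-9)
})

test_that("amplitude traces at 5% noise stay within 3 standard errors", {
  bands <- three_bands()
  sd_irf <- 30 / (2 * sqrt(2 * log(2)))
  n_rep <- 20
  hit <- 0; tot <- 0
  for (i in seq_len(n_rep)) {
    m <- generate_experimental_map(bands, irf_fwhm = 30, noise_sd = 0.05,
                                   seed = 200 + i,
                                   energies = seq(285.5, 288.5, by = 0.05))
    bf <- fit_band_model(m, default_init(), c(285.5, 288.5), n_starts = 2,
                         seed = i)
    for (k in 1:3) {
      a_true <- bands$amplitude[k] *
        txas:::exp_kinetics(m$delays, bands$tau[k], bands$kind[k], sd_irf)
      ok <- abs(bf$amplitudes[k, ] - a_true) <= 3 * bf$amplitude_se[k, ]
      # non-negativity clipping makes near-zero points one-sided; count the
      # clearly-constrained points only
      keep <- a_true > 0.05
      hit <- hit + sum(ok[keep]); tot <- tot + sum(keep)
    }
  }
  expect_gt(hit / tot, 0.95)
})

test_that("fitted amplitudes are non-negative by construction", {
  m <- generate_experimental_map(three_bands(), irf_fwhm = 30, noise_sd = 0.1,
                                 seed = 4, energies = seq(285.5, 288.5, 0.05))
  bf <- fit_band_model(m, default_init(), c(285.5, 288.5), n_starts = 2)
  expect_true(all(bf$amplitudes >= 0))
})

test_that("exponential fits are exact on noiseless traces and affine invariant", {
  t <- seq(0, 2000, by = 100)
  y <- 0.8 * exp(-t / 290) + 0.1
  r <- fit_exponential(t, y, "decay", irf_fwhm = 0)
  expect_equal(r$tau_or_thalf, 290, tolerance = 1e-8)
  expect_equal(r$baseline, 0.1, tolerance = 1e-8)
  expect_false(r$flagged)

  # affine rescaling of the trace leaves tau unchanged
  r2 <- fit_exponential(t, 5 * y + 3, "decay", irf_fwhm = 0)
  expect_equal(r2$tau_or_thalf, r$tau_or_thalf, tolerance = 1e-7)

  yr <- 0.5 * (1 - exp(-t / 591))
  rr <- fit_exponential(t, yr, "rise", irf_fwhm = 0)
  expect_equal(rr$tau_or_thalf, 591, tolerance = 1e-6)

  # constant trace: amplitude ~ 0 and flagged
  rc <- fit_exponential(t, rep(1, length(t)), "rise", irf_fwhm = 0)
  expect_true(rc$flagged)
  expect_lt(abs(rc$amplitude), 1e-6)

  expect_error(fit_exponential(1:5, 1:5, "decay"), "8 points")
})

test_that("IRF-convolved rise recovery works at experiment-like noise", {
  sd_irf <- 30 / (2 * sqrt(2 * log(2)))
  t <- seq(-200, 3000, by = 100)
  truth <- txas:::exp_kinetics(t, 591, "rise", sd_irf)
  set.seed(31)
  taus <- ses <- numeric(30)
  for (i in 1:30) {
    y <- truth + rnorm(length(t), sd = 0.05)
    r <- fit_exponential(t, y, "rise", irf_fwhm = 30)
    taus[i] <- r$tau_or_thalf; ses[i] <- r$uncertainty
  }
  expect_lt(abs(median(taus) - 591) / 591, 0.1)
  expect_gt(mean(abs(taus - 591) <= 3 * ses), 0.85)
  # standard errors at this SNR are of order 10^2 fs
  expect_gt(median(ses), 10)
  expect_lt(median(ses), 1000)
})

test_that("sigmoid fits return the midpoint time and respect symmetry", {
  t <- seq(0, 600, by = 0.5)
  y <- 0.2 + 1.0 / (1 + exp(-(t - 126) / 25))
  r <- fit_sigmoid(t, y)
  expect_equal(r$tau_or_thalf, 126, tolerance = 1e-6)
  expect_equal(r$amplitude, 1.0, tolerance = 1e-6)

  # time-reversed (falling) trace gives the same crossing magnitude
  rf <- fit_sigmoid(t, rev(y))
  expect_equal(rf$tau_or_thalf, max(t) - 126, tolerance = 1e-4)
  expect_equal(abs(rf$amplitude), 1.0, tolerance = 1e-4)

  # affine invariance of the midpoint
  ra <- fit_sigmoid(t, -4 * y + 7)
  expect_equal(ra$tau_or_thalf, 126, tolerance = 1e-5)

  # unbracketed trace is refused with window advice
  expect_error(fit_sigmoid(t[t < 130], y[t < 130]), "window")
})

test_that("single-trajectory sigmoid traces recover the generator half-rises", {
  set.seed(77)
  cfg <- ensemble_config(n_traj = 1, pt_fraction = 1, t_half_shift = 80,
                         onset_jitter = 0, seed = 42)
  ens <- generate_ensemble(cfg)
  tr <- ensemble_traces(ens$tables)
  fe <- fit_sigmoid(tr$time, tr$energy)
  # vibrational oscillation (0.05 eV) plus noise: 3-s.e. agreement
  expect_lt(abs(fe$tau_or_thalf - 80), 3 * max(fe$uncertainty, 1))
  expect_lt(abs(fe$amplitude - 1.2), 3 * max(fe$extra$amplitude_se, 0.01))
  fa <- fit_sigmoid(tr$time, tr$strength)
  expect_lt(abs(fa$tau_or_thalf - 134), 3 * max(fa$uncertainty, 1))
})

test_that("erf rise reports the 10-90 interval from the fitted width", {
  t <- seq(-60, 60, by = 0.5)
  y <- 2 + 3 * pnorm(t / 10)
  r <- fit_erf_rise(t, y)
  expect_equal(r$tau_or_thalf, 2 * qnorm(0.9) * 10, tolerance = 1e-6)
  expect_equal(r$extra$sigma_t, 10, tolerance = 1e-6)

  # a Gaussian IRF of FWHM f has 10-90 rise 1.0885 f
  fwhm <- 27 / 1.0885
  y2 <- pnorm(t / (fwhm / (2 * sqrt(2 * log(2)))))
  r2 <- fit_erf_rise(t, y2)
  expect_equal(r2$tau_or_thalf,
               2 * qnorm(0.9) / (2 * sqrt(2 * log(2))) * fwhm,
               tolerance = 1e-6)

  # sharper and sharper steps: rise -> 0
  y3 <- pnorm(t / 0.2)
  r3 <- fit_erf_rise(t, y3)
  expect_lt(r3$tau_or_thalf, 1)

  expect_warning(fit_erf_rise(t, sin(t / 5)), "monotone")
})

test_that("sequence check orders the three bands and handles ties", {
  m <- generate_experimental_map(three_bands(), irf_fwhm = 30, noise_sd = 0,
                                 energies = seq(285.5, 288.5, by = 0.05))
  bf <- fit_band_model(m, default_init(), c(285.5, 288.5), n_starts = 2)
  sc <- sequence_check(bf)
  expect_true(sc$ordering_ok)
  expect_true(all(diff(sc$half_times) > 0))

  # shuffled kinetics: band iii rises immediately, band i decays slowly
  shuffled <- three_bands()
  shuffled$tau <- c(900, 290, 30)
  m2 <- generate_experimental_map(shuffled, irf_fwhm = 30, noise_sd = 0,
                                  energies = seq(285.5, 288.5, by = 0.05))
  bf2 <- fit_band_model(m2, default_init(), c(285.5, 288.5), n_starts = 2)
  expect_false(isTRUE(sequence_check(bf2)$ordering_ok))

  # a flat band is excluded and the ordering is indeterminate
  bm <- band_model(c(286.7, 287.3, 287.6), c(0.15, 0.18, 0.22),
                   amplitudes = rbind(exp(-(0:10) / 2), 0.5, 1 - exp(-(0:10) / 4)),
                   delays = seq(0, 1000, by = 100))
  sc3 <- sequence_check(bm)
  expect_true(sc3$indeterminate)
  expect_true(2 %in% sc3$excluded)

  # identical kinetics for bands i and ii: tie -> indeterminate
  a <- exp(-(0:10) / 2)
  bm4 <- band_model(c(286.7, 287.3, 287.6), c(0.15, 0.18, 0.22),
                    amplitudes = rbind(a, a, 1 - exp(-(0:10) / 4)),
                    delays = seq(0, 1000, by = 100))
  sc4 <- sequence_check(bm4)
  expect_true(sc4$indeterminate)
})

test_that("electronic half-rise exceeds structural half-rise on suitable ensembles", {
  # generator property: t_half_amp > t_half_shift must survive the fitter
  ok <- 0
  for (i in 1:10) {
    cfg <- ensemble_config(n_traj = 8, pt_fraction = 1, seed = 400 + i)
    tr <- ensemble_traces(generate_ensemble(cfg)$tables)
    fa <- fit_sigmoid(tr$time, tr$strength)
    fe <- fit_sigmoid(tr$time, tr$energy)
    ok <- ok + (fa$tau_or_thalf > fe$tau_or_thalf)
  }
  expect_gte(ok, 9)
})
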