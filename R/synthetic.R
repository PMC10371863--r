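#' Configuration for a synthetic ionised-trajectory ensemble
#'
#' Defines the statistical structure of synthetic transition tables emulating
#' valence-ionised urea-dimer trajectories: a subpopulation undergoing proton
#' transfer in which the carbon-site absorption strength grows sigmoidally
#' and the core-to-valence transition energy shifts sigmoidally upwards, with
#' a superposed vibrational oscillation and optional noise.
#'
#' Defaults mirror the conditions of the study the generator emulates:
#' 149 dimer trajectories of which ~7% transfer a proton after HOMO
#' ionisation, ensemble half-rise times of 134 fs (absorption strength) and
#' 107 fs (energy shift), a 1.2 eV asymptotic upward shift of the band from
#' 286.4 eV, and a 30 fs electronically excited-state decay used when
#' emulating deeper-orbital ionisation.
#'
#' @param n_traj number of trajectories.
#' @param pt_fraction probability that a trajectory undergoes proton
#'   transfer.
#' @param t_half_amp fs, half-rise time of the sigmoidal growth of the
#'   squared transition dipole (carbon-site hole amplitude).
#' @param t_half_shift fs, half-rise time of the sigmoidal transition-energy
#'   upshift.
#' @param shift_magnitude eV, asymptotic upward energy shift.
#' @param base_energy eV, pre-transfer transition energy.
#' @param sigmoid_slope fs, logistic slope parameter (10--90 rise of each
#'   sigmoid is `log(81) * sigmoid_slope`).
#' @param vib_period,vib_amp fs and eV, superposed vibrational oscillation of
#'   the transition energy.
#' @param excited_state_tau fs, exponential decay constant of the
#'   electronically excited cation population (deeper-orbital ionisation).
#' @param dipole_sq_max asymptotic squared transition dipole, atomic units.
#'   The pre-transfer floor is 10% of this value (a weak, nearly
#'   time-independent feature).
#' @param noise_sd relative noise level: Gaussian noise with s.d.
#'   `noise_sd * dipole_sq_max` on the squared dipole and
#'   `noise_sd * shift_magnitude` on the transition energy.
#' @param window length-2 fs vector, simulated time window.
#' @param dt fs, frame spacing (uniform grid).
#' @param onset_jitter fs, width of the zero-mean uniform jitter applied to
#'   each trajectory's sigmoid onset (trajectory-to-trajectory spread that
#'   leaves the ensemble half-rise at the configured value).
#' @param eps_core hartree, core-orbital energy (fixed).
#' @param seed integer seed; a fixed seed gives bit-identical output.
#' @return List of class `ensemble_config`.
#' @export
ensemble_config <- function(n_traj = 149, pt_fraction = 0.07,
                            t_half_amp = 134, t_half_shift = 107,
                            shift_magnitude = 1.2, base_energy = 286.4,
                            sigmoid_slope = 25,
                            vib_period = 20, vib_amp = 0.05,
                            excited_state_tau = 30,
                            dipole_sq_max = 0.04,
                            noise_sd = 0.02,
                            window = c(0, 600), dt = 0.5,
                            onset_jitter = 50,
                            eps_core = -310.21 / 27.211386,
                            seed = 1L) {
  cfg <- list(n_traj = as.integer(n_traj), pt_fraction = pt_fraction,
              t_half_amp = t_half_amp, t_half_shift = t_half_shift,
              shift_magnitude = shift_magnitude, base_energy = base_energy,
              sigmoid_slope = sigmoid_slope,
              vib_period = vib_period, vib_amp = vib_amp,
              excited_state_tau = excited_state_tau,
              dipole_sq_max = dipole_sq_max, noise_sd = noise_sd,
              window = window, dt = dt, onset_jitter = onset_jitter,
              eps_core = eps_core, seed = as.integer(seed))
  validate_ensemble_config(cfg)
}

validate_ensemble_config <- function(cfg) {
  if (cfg$n_traj < 1L) stop("n_traj must be >= 1", call. = FALSE)
  if (cfg$pt_fraction < 0 || cfg$pt_fraction > 1)
    stop("pt_fraction must lie in [0, 1]", call. = FALSE)
  for (nm in c("t_half_amp", "t_half_shift", "sigmoid_slope", "vib_period",
               "excited_state_tau", "dipole_sq_max", "dt"))
    stopifnot_scalar_number(cfg[[nm]], nm, positive = TRUE)
  for (nm in c("shift_magnitude", "base_energy", "vib_amp", "noise_sd",
               "onset_jitter"))
    stopifnot_scalar_number(cfg[[nm]], nm)
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (cfg$onset_jitter < 0) stop("onset_jitter must be >= 0", call. = FALSE)
  if (length(cfg$window) != 2L || cfg$window[2] <= cfg$window[1])
    stop("window must be c(t0, t1) with t1 > t0", call. = FALSE)
  structure(cfg, class = "ensemble_config")
}

# Logistic sigmoid rising from 0 to 1 with midpoint t_half and slope k (fs).
logistic_rise <- function(t, t_half, k) 1 / (1 + exp(-(t - t_half) / k))

#' Generate one synthetic ionised trajectory's transition table
#'
#' Produces one core-to-valence transition record per frame on a uniform
#' `cfg$dt` grid over `cfg$window`. For a proton-transferring trajectory the
#' squared transition dipole rises logistically from 10% of
#' `cfg$dipole_sq_max` to its asymptote with half-rise `t_half_amp + onset`,
#' and the transition energy follows `base_energy` plus a logistic upshift of
#' amplitude `shift_magnitude` with half-rise `t_half_shift + onset`, plus
#' the vibrational oscillation. A non-transferring trajectory keeps both
#' channels at their initial values (oscillation only).
#'
#' The logistic value at the half-rise time is exactly the midpoint of the
#' two asymptotes.
#'
#' @param cfg an [ensemble_config()].
#' @param undergoes_pt logical flag.
#' @param onset fs, onset shift of both sigmoids (per-trajectory jitter).
#' @param vib_phase radians, phase of the vibrational oscillation.
#' @param traj_id trajectory identifier.
#' @param ion_label,system_label metadata labels (see [transition_table()]).
#' @return A `transition_table` with one row per frame and attribute
#'   `undergoes_pt`. Uses the current RNG stream for noise; seed at the
#'   ensemble level via [generate_ensemble()].
#' @export
generate_pt_trajectory <- function(cfg, undergoes_pt = TRUE, onset = 0,
                                   vib_phase = 0, traj_id = "traj1",
                                   ion_label = "HOMO",
                                   system_label = "dimer") {
  cfg <- validate_ensemble_config(cfg)
  t <- seq(cfg$window[1], cfg$window[2], by = cfg$dt)
  d2_floor <- 0.1 * cfg$dipole_sq_max
  if (undergoes_pt) {
    s_amp <- logistic_rise(t, cfg$t_half_amp + onset, cfg$sigmoid_slope)
    s_shift <- logistic_rise(t, cfg$t_half_shift + onset, cfg$sigmoid_slope)
  } else {
    s_amp <- s_shift <- numeric(length(t))
  }
  d2 <- d2_floor + (cfg$dipole_sq_max - d2_floor) * s_amp
  energy <- cfg$base_energy + cfg$shift_magnitude * s_shift +
    cfg$vib_amp * sin(2 * pi * t / cfg$vib_period + vib_phase)
  if (cfg$noise_sd > 0) {
    d2 <- d2 + stats::rnorm(length(t), sd = cfg$noise_sd * cfg$dipole_sq_max)
    d2 <- pmax(d2, 0)
    energy <- energy +
      stats::rnorm(length(t), sd = cfg$noise_sd * abs(cfg$shift_magnitude))
  }
  eps_vac <- cfg$eps_core + energy / .HARTREE_EV
  d <- sqrt(d2 / 3)
  tab <- transition_table(time = t, eps_core = cfg$eps_core,
                          eps_vac = eps_vac,
                          dip_x = d, dip_y = d, dip_z = d,
                          traj_id = traj_id, ion_label = ion_label,
                          system_label = system_label)
  attr(tab, "undergoes_pt") <- undergoes_pt
  tab
}

#' Generate a seeded trajectory ensemble
#'
#' Draws per-trajectory proton-transfer flags (Bernoulli with
#' `cfg$pt_fraction`), sigmoid-onset jitters (uniform, zero-mean, width
#' `cfg$onset_jitter`) and vibrational phases (uniform on the circle) from
#' the seeded stream, then generates one transition table per trajectory.
#' Identical config and seed give byte-identical output.
#'
#' @param cfg an [ensemble_config()].
#' @return List with `tables` (list of `transition_table`), `pt` (logical
#'   flags), `onsets`, `phases` and `config`.
#' @export
generate_ensemble <- function(cfg) {
  cfg <- validate_ensemble_config(cfg)
  with_seed(cfg$seed, {
    pt <- stats::runif(cfg$n_traj) < cfg$pt_fraction
    onsets <- stats::runif(cfg$n_traj, -cfg$onset_jitter / 2,
                           cfg$onset_jitter / 2)
    phases <- stats::runif(cfg$n_traj, 0, 2 * pi)
    tables <- vector("list", cfg$n_traj)
    for (i in seq_len(cfg$n_traj)) {
      tables[[i]] <- generate_pt_trajectory(
        cfg, undergoes_pt = pt[i], onset = onsets[i], vib_phase = phases[i],
        traj_id = sprintf("traj%03d", i))
    }
    list(tables = tables, pt = pt, onsets = onsets, phases = phases,
         config = cfg)
  })
}

#' Generate a synthetic experiment-like delta-OD map
#'
#' Builds a pump--probe map from Gaussian spectral bands with exponential
#' amplitude kinetics, convolves it in time with a Gaussian instrument
#' response and adds i.i.d. Gaussian noise. The default three-band layout
#' emulates the proton-transfer band region: two pre-transfer bands that
#' decay and one post-transfer band that rises. An optional depletion band
#' with negative amplitude and step kinetics emulates the ground-state
#' bleach at the neutral pi* resonance.
#'
#' @param bands data.frame with columns `center` (eV), `width` (Gaussian
#'   s.d., eV), `amplitude` (peak height), `kind` (`"decay"` or `"rise"`) and
#'   `tau` (fs).
#' @param irf_fwhm fs, FWHM of the Gaussian instrument response (0 for
#'   none).
#' @param delays sorted delay grid (fs).
#' @param energies sorted photon-energy grid (eV).
#' @param noise_sd noise standard deviation as a fraction of the peak
#'   absolute noiseless signal.
#' @param seed integer seed.
#' @param depletion optional list `list(center=, width=, amplitude=)` with
#'   `amplitude < 0`; its kinetics are an IRF-limited step.
#' @return A [transient_map()] with `kind = "dod"` and attribute `truth`
#'   (the noiseless map).
#' @export
generate_experimental_map <- function(bands, irf_fwhm = 30,
                                      delays = seq(-200, 2000, by = 100),
                                      energies = seq(285.5, 288.5, by = 0.02),
                                      noise_sd = 0.05, seed = 1L,
                                      depletion = NULL) {
  stopifnot(all(c("center", "width", "amplitude", "kind", "tau") %in%
                  names(bands)))
  if (!is_sorted_strict(delays) || !is_sorted_strict(energies))
    stop("'delays' and 'energies' must be strictly increasing", call. = FALSE)
  sd_irf <- if (irf_fwhm > 0) irf_fwhm / .FWHM_SIGMA else 0
  clean <- matrix(0, length(delays), length(energies))
  for (k in seq_len(nrow(bands))) {
    a_t <- bands$amplitude[k] *
      exp_kinetics(delays, bands$tau[k], bands$kind[k], sd_irf)
    g <- exp(-(energies - bands$center[k])^2 / (2 * bands$width[k]^2))
    clean <- clean + a_t %o% g
  }
  if (!is.null(depletion)) {
    step <- if (sd_irf > 0) stats::pnorm(delays / sd_irf) else as.numeric(delays >= 0)
    g <- exp(-(energies - depletion$center)^2 / (2 * depletion$width^2))
    clean <- clean + (depletion$amplitude * step) %o% g
  }
  vals <- clean
  if (noise_sd > 0) {
    scale <- max(abs(clean))
    vals <- with_seed(seed, clean + matrix(
      stats::rnorm(length(clean), sd = noise_sd * scale),
      nrow(clean), ncol(clean)))
  }
  out <- transient_map(delays, energies, vals, kind = "dod")
  attr(out, "truth") <- clean
  out
}

# Exponential population kinetics analytically convolved with a Gaussian
# IRF of s.d. sd_irf: decay = H(t) exp(-t/tau) (x) G, rise = step - decay.
# Computed in log space for numerical stability at large |t|/tau.
exp_kinetics <- function(t, tau, kind = c("decay", "rise"), sd_irf = 0) {
  kind <- match.arg(kind)
  if (sd_irf <= 0) {
    dec <- ifelse(t >= 0, exp(-t / tau), 0)
    stp <- as.numeric(t >= 0)
  } else {
    dec <- exp(sd_irf^2 / (2 * tau^2) - t / tau +
                 stats::pnorm((t - sd_irf^2 / tau) / sd_irf, log.p = TRUE))
    stp <- stats::pnorm(t / sd_irf)
  }
  if (kind == "decay") dec else stp - dec
}

#' Configuration for synthetic hydrogen-bond formation times
#'
#' Waiting times for the formation of proximal hydrogen bonds are modelled
#' as a two-component exponential mixture: a fast channel (local
#' hydrogen-bond fluctuations) and a slow channel (diffusion-controlled
#' encounters). Defaults use 227 fs and 4100 fs with equal weights.
#'
#' @param tau_fast,tau_slow fs, component time constants
#'   (`tau_fast < tau_slow`).
#' @param weight_fast mixture weight of the fast channel, in `[0, 1]`.
#' @param n_events number of waiting times to draw.
#' @param seed integer seed.
#' @return List of class `hbond_kinetics_config`.
#' @export
hbond_kinetics_config <- function(tau_fast = 227, tau_slow = 4100,
                                  weight_fast = 0.5, n_events = 10000L,
                                  seed = 1L) {
  stopifnot_scalar_number(tau_fast, "tau_fast", positive = TRUE)
  stopifnot_scalar_number(tau_slow, "tau_slow", positive = TRUE)
  if (tau_fast >= tau_slow) stop("tau_fast must be < tau_slow", call. = FALSE)
  if (weight_fast < 0 || weight_fast > 1)
    stop("weight_fast must lie in [0, 1]", call. = FALSE)
  structure(list(tau_fast = tau_fast, tau_slow = tau_slow,
                 weight_fast = weight_fast, n_events = as.integer(n_events),
                 seed = as.integer(seed)),
            class = "hbond_kinetics_config")
}

#' Draw synthetic hydrogen-bond formation waiting times
#'
#' i.i.d. draws from
#' `weight_fast * Exp(tau_fast) + (1 - weight_fast) * Exp(tau_slow)`.
#'
#' @param cfg an [hbond_kinetics_config()].
#' @return Numeric vector of `cfg$n_events` waiting times (fs).
#' @export
generate_hbond_event_series <- function(cfg) {
  if (!inherits(cfg, "hbond_kinetics_config"))
    stop("cfg must be an hbond_kinetics_config()", call. = FALSE)
  if (cfg$n_events <= 0) stop("n_events must be > 0", call. = FALSE)
  with_seed(cfg$seed, {
    fast <- stats::runif(cfg$n_events) < cfg$weight_fast
    ifelse(fast, stats::rexp(cfg$n_events, rate = 1 / cfg$tau_fast),
           stats::rexp(cfg$n_events, rate = 1 / cfg$tau_slow))
  })
}
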