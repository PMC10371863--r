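#' Line-shape parameters for spectral synthesis
#'
#' @param lorentz_fwhm Lorentzian full width at half maximum in eV applied to
#'   every transition stick (natural line width of the core-excited state
#'   plus detector resolution). Default 0.5 eV.
#' @param time_fwhm FWHM in fs of the Gaussian used to convolve maps in time
#'   (finite experimental time resolution). Default 10 fs.
#' @return List of class `line_shape_params`.
#' @export
line_shape_params <- function(lorentz_fwhm = 0.5, time_fwhm = 10) {
  stopifnot_scalar_number(lorentz_fwhm, "lorentz_fwhm", positive = TRUE)
  stopifnot_scalar_number(time_fwhm, "time_fwhm", positive = TRUE)
  structure(list(lorentz_fwhm = lorentz_fwhm, time_fwhm = time_fwhm),
            class = "line_shape_params")
}

#' Stick energies and strengths from transition records
#'
#' For a core electron excited into a valence vacancy the absorption
#' cross-section of one transition is
#' \deqn{\sigma = \frac{4}{3}\pi^2 \omega \alpha \, |d|^2}
#' in atomic units, where \eqn{\omega} is the transition energy
#' (`eps_vac - eps_core`, hartree), \eqn{\alpha} the fine-structure constant
#' and \eqn{|d|^2} the squared norm of the transition-dipole vector (the
#' isotropic orientation average is absorbed in the 1/3 factor). The delta
#' line shape is replaced by a finite-width profile in [broaden()].
#'
#' @param records a `transition_table` (or data.frame with its columns).
#' @return data.frame with columns `energy_ev` (transition energy in eV) and
#'   `strength` (integrated stick cross-section, atomic units).
#' @export
stick_strength <- function(records) {
  records <- validate_transition_table(as.data.frame(records))
  omega_au <- records$eps_vac - records$eps_core
  if (any(omega_au <= 0))
    stop("unphysical transition: eps_vac <= eps_core", call. = FALSE)
  d2 <- records$dip_x^2 + records$dip_y^2 + records$dip_z^2
  data.frame(
    energy_ev = omega_au * .HARTREE_EV,
    strength  = (4 / 3) * pi^2 * omega_au * .ALPHA * d2
  )
}

#' Broaden sticks into an absorption spectrum
#'
#' Sums unit-area Lorentzians of FWHM `params$lorentz_fwhm` centred at the
#' stick energies, weighted by the stick strengths. Lorentzians are evaluated
#' analytically on the full grid (no truncation radius).
#'
#' @param sticks data.frame with `energy_ev` and `strength` columns (from
#'   [stick_strength()]). An empty stick list yields a zero spectrum.
#' @param grid sorted photon-energy grid (eV).
#' @param params a [line_shape_params()].
#' @return An `absorption_spectrum`: list with `energies` (eV) and `sigma`
#'   (atomic units, non-negative).
#' @export
broaden <- function(sticks, grid, params = line_shape_params()) {
  if (!is_sorted_strict(grid))
    stop("'grid' must be strictly increasing", call. = FALSE)
  gam <- params$lorentz_fwhm / 2  # Lorentzian HWHM = Cauchy scale
  sigma <- numeric(length(grid))
  if (NROW(sticks) > 0) {
    for (j in seq_len(NROW(sticks))) {
      sigma <- sigma + sticks$strength[j] *
        stats::dcauchy(grid, location = sticks$energy_ev[j], scale = gam)
    }
  }
  structure(list(energies = grid, sigma = sigma),
            class = "absorption_spectrum")
}

#' Ensemble-averaged transient cross-section map
#'
#' Each trajectory's transition sticks are broadened per time step and the
#' resulting spectra are averaged over trajectories, giving the ensemble
#' cross-section map \eqn{\bar\sigma(t,\omega)}. All trajectories must share
#' one common time grid; ragged grids are rejected with instructions to
#' resample first.
#'
#' @param tables list of `transition_table`s, one per trajectory.
#' @param grid sorted photon-energy grid (eV).
#' @param params a [line_shape_params()].
#' @return A [transient_map()] with `kind = "sigma"`.
#' @export
ensemble_map <- function(tables, grid, params = line_shape_params()) {
  if (length(tables) == 0) stop("need at least one trajectory", call. = FALSE)
  tables <- lapply(tables, function(x) validate_transition_table(as.data.frame(x)))
  times <- sort(unique(tables[[1]]$time))
  for (k in seq_along(tables)) {
    tk <- sort(unique(tables[[k]]$time))
    if (length(tk) != length(times) || any(abs(tk - times) > 1e-9))
      stop("trajectories have ragged time grids; resample all tables onto a ",
           "common delay grid before calling ensemble_map()", call. = FALSE)
  }
  acc <- matrix(0, length(times), length(grid))
  for (tab in tables) {
    sticks <- stick_strength(tab)
    idx <- match(round(tab$time, 9), round(times, 9))
    for (i in seq_along(times)) {
      sel <- which(idx == i)
      if (length(sel))
        acc[i, ] <- acc[i, ] + broaden(sticks[sel, , drop = FALSE], grid,
                                       params)$sigma
    }
  }
  transient_map(times, grid, acc / length(tables), kind = "sigma")
}

#' Ensemble-averaged stick traces
#'
#' Reduces a trajectory ensemble to the two time traces used for
#' electronic/structural timescale separation: the mean stick cross-section
#' (tracking the hole amplitude at the absorbing site) and the mean
#' transition energy (tracking the band position) versus time.
#'
#' @param tables list of `transition_table`s on a common time grid.
#' @return data.frame with columns `time` (fs), `strength` (mean stick
#'   cross-section, a.u.) and `energy` (mean transition energy, eV).
#' @export
ensemble_traces <- function(tables) {
  if (length(tables) == 0) stop("need at least one trajectory", call. = FALSE)
  times <- sort(unique(tables[[1]]$time))
  S <- matrix(NA_real_, length(tables), length(times))
  E <- matrix(NA_real_, length(tables), length(times))
  for (k in seq_along(tables)) {
    tab <- validate_transition_table(as.data.frame(tables[[k]]))
    tk <- sort(unique(tab$time))
    if (length(tk) != length(times) || any(abs(tk - times) > 1e-9))
      stop("trajectories have ragged time grids", call. = FALSE)
    sticks <- stick_strength(tab)
    idx <- match(round(tab$time, 9), round(times, 9))
    S[k, ] <- vapply(seq_along(times),
                     function(i) sum(sticks$strength[idx == i]), 0)
    E[k, ] <- vapply(seq_along(times), function(i) {
      sel <- idx == i
      stats::weighted.mean(sticks$energy_ev[sel],
                           pmax(sticks$strength[sel], 1e-300))
    }, 0)
  }
  data.frame(time = times, strength = colMeans(S), energy = colMeans(E))
}

#' Convolve a transient map in time with a Gaussian
#'
#' Every energy column is convolved along the (uniform) delay axis with a
#' unit-area discrete Gaussian of the stated FWHM. Edges are handled by
#' nearest-value padding, so a map constant in time is left unchanged and the
#' time integral of signals well inside the window is preserved.
#'
#' @param map a [transient_map()] on a uniform delay grid.
#' @param time_fwhm Gaussian FWHM in fs.
#' @return The convolved [transient_map()].
#' @export
convolve_time <- function(map, time_fwhm = 10) {
  stopifnot_scalar_number(time_fwhm, "time_fwhm", positive = TRUE)
  dt <- diff(map$delays)
  if (length(dt) == 0) return(map)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("convolve_time() requires a uniform delay grid", call. = FALSE)
  dt <- dt[1]
  sd_t <- time_fwhm / .FWHM_SIGMA
  half <- max(1L, ceiling(5 * sd_t / dt))
  kt <- stats::dnorm(seq(-half, half) * dt, sd = sd_t)
  kt <- kt / sum(kt)
  n <- length(map$delays)
  vals <- map$values
  # nearest-value padding at both ends
  padded <- rbind(vals[rep(1L, half), , drop = FALSE], vals,
                  vals[rep(n, half), , drop = FALSE])
  out <- matrix(0, n, ncol(vals))
  for (i in seq_len(n)) {
    block <- padded[i:(i + 2L * half), , drop = FALSE]
    out[i, ] <- colSums(block * kt)
  }
  transient_map(map$delays, map$energies, out, kind = map$kind)
}

#' Energy-calibration constants
#'
#' Two-stage calibration of computed spectra: a downshift correcting for
#' core-hole relaxation missing from orbital-energy differences (difference
#' between the calculated core binding energy and the experimentally
#' corrected core-level ionisation potential), and an upshift accounting for
#' solvation effects on the valence ionisation energy. Defaults reproduce the
#' carbon K-edge bookkeeping for aqueous urea: 310.21 - 294.51 = 15.70 eV
#' down, 3.2 eV up.
#'
#' @param calc_core_binding calculated core binding energy, eV.
#' @param exp_core_ip corrected experimental core ionisation potential, eV.
#' @param upshift environment correction, eV.
#' @param downshift overrides the derived downshift when the components are
#'   not supplied.
#' @return List of class `calibration_constants`.
#' @export
calibration_constants <- function(calc_core_binding = 310.21,
                                  exp_core_ip = 294.51,
                                  upshift = 3.2,
                                  downshift = NULL) {
  if (is.null(downshift)) {
    downshift <- derive_downshift(calc_core_binding, exp_core_ip)
  } else if (!is.null(calc_core_binding) && !is.null(exp_core_ip) &&
             abs(downshift - (calc_core_binding - exp_core_ip)) > 1e-9) {
    stop("downshift inconsistent with calc_core_binding - exp_core_ip",
         call. = FALSE)
  }
  structure(list(downshift = downshift, upshift = upshift,
                 calc_core_binding = calc_core_binding,
                 exp_core_ip = exp_core_ip),
            class = "calibration_constants")
}

#' Calibration arithmetic
#'
#' Small bookkeeping operations for the two-stage energy calibration:
#' \describe{
#'   \item{`derive_downshift`}{core-relaxation correction = calculated core
#'     binding energy minus corrected experimental core IP.}
#'   \item{`correct_reference_ip`}{propagate a revised reference binding
#'     energy: `ip_old + (ref_new - ref_old)` (e.g. updating a solute core IP
#'     when the water 1b1 reference moves from 11.16 to 11.67 eV).}
#'   \item{`estimate_valence_ip`}{valence ionisation energy = core IP minus
#'     the core-to-valence resonance energy.}
#'   \item{`gas_phase_lowering`}{solvation-induced lowering = gas-phase IP
#'     minus solution-phase IP.}
#' }
#'
#' @param calc_core_binding,exp_core_ip,ip_old,ref_old,ref_new,core_ip,resonance_energy,gas_ip,solution_ip
#'   energies in eV.
#' @return The derived energy in eV.
#' @export
derive_downshift <- function(calc_core_binding, exp_core_ip) {
  stopifnot_scalar_number(calc_core_binding, "calc_core_binding", positive = TRUE)
  stopifnot_scalar_number(exp_core_ip, "exp_core_ip", positive = TRUE)
  calc_core_binding - exp_core_ip
}

#' @rdname derive_downshift
#' @export
correct_reference_ip <- function(ip_old, ref_old, ref_new) {
  stopifnot_scalar_number(ip_old, "ip_old", positive = TRUE)
  stopifnot_scalar_number(ref_old, "ref_old", positive = TRUE)
  stopifnot_scalar_number(ref_new, "ref_new", positive = TRUE)
  ip_old + (ref_new - ref_old)
}

#' @rdname derive_downshift
#' @export
estimate_valence_ip <- function(core_ip, resonance_energy) {
  stopifnot_scalar_number(core_ip, "core_ip", positive = TRUE)
  stopifnot_scalar_number(resonance_energy, "resonance_energy", positive = TRUE)
  out <- core_ip - resonance_energy
  if (out <= 0)
    stop("core_ip must exceed resonance_energy (arguments swapped?)",
         call. = FALSE)
  out
}

#' @rdname derive_downshift
#' @export
gas_phase_lowering <- function(gas_ip, solution_ip) {
  stopifnot_scalar_number(gas_ip, "gas_ip", positive = TRUE)
  stopifnot_scalar_number(solution_ip, "solution_ip", positive = TRUE)
  out <- gas_ip - solution_ip
  if (out <= 0)
    stop("gas_ip must exceed solution_ip (arguments swapped?)", call. = FALSE)
  out
}

#' Apply the energy calibration to a map
#'
#' Translates the photon-energy axis by `-downshift + upshift`; values are
#' untouched.
#'
#' @param map a [transient_map()].
#' @param cal a [calibration_constants()].
#' @return The calibrated [transient_map()].
#' @export
apply_calibration <- function(map, cal = calibration_constants()) {
  transient_map(map$delays, map$energies - cal$downshift + cal$upshift,
                map$values, kind = map$kind)
}

#' Delta-OD from pumped and unpumped intensities
#'
#' \deqn{\Delta OD(t,\omega) = -\log_{10}(I_{pump}/I_{unpump})}
#' When the inputs are built from model cross-sections via Beer--Lambert
#' transmissions, the result scales (to first order) with the excited-state
#' fraction; `excited_fraction` applies that overall scaling.
#'
#' @param pumped,unpumped strictly positive intensity [transient_map()]s on a
#'   common delay/energy grid (`unpumped` may also be a single spectrum
#'   replicated across delays, supplied as a numeric vector over energies).
#' @param excited_fraction overall scaling of the model delta-OD (default 1).
#' @return A [transient_map()] with `kind = "dod"` (either sign allowed).
#' @export
delta_od <- function(pumped, unpumped, excited_fraction = 1) {
  stopifnot_scalar_number(excited_fraction, "excited_fraction")
  if (is.numeric(unpumped) && is.null(dim(unpumped))) {
    unpumped <- transient_map(pumped$delays, pumped$energies,
                              matrix(unpumped, nrow = length(pumped$delays),
                                     ncol = length(pumped$energies),
                                     byrow = TRUE), kind = pumped$kind)
  }
  if (length(pumped$delays) != length(unpumped$delays) ||
      length(pumped$energies) != length(unpumped$energies) ||
      any(abs(pumped$energies - unpumped$energies) > 1e-9))
    stop("pumped and unpumped maps must share one grid", call. = FALSE)
  if (any(pumped$values <= 0) || any(unpumped$values <= 0))
    stop("intensities must be strictly positive", call. = FALSE)
  dod <- -log10(pumped$values / unpumped$values) * excited_fraction
  transient_map(pumped$delays, pumped$energies, dod, kind = "dod")
}
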