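#' Three-Gaussian band model
#'
#' Transient spectra in the proton-transfer band region are decomposed into
#' three Gaussian spectral components with centres and widths shared across
#' all delays and a free non-negative amplitude per band and delay: two
#' pre-transfer bands that decay and one post-transfer band that rises.
#'
#' @param centers 3 strictly increasing band centres (eV).
#' @param widths 3 Gaussian standard deviations (eV), > 0.
#' @param amplitudes optional 3 x n_delays matrix of non-negative peak
#'   heights.
#' @param delays optional delay vector matching `amplitudes`.
#' @return List of class `band_model`.
#' @export
band_model <- function(centers, widths, amplitudes = NULL, delays = NULL) {
  if (length(centers) != 3L || !is_sorted_strict(centers))
    stop("'centers' must be 3 strictly increasing energies", call. = FALSE)
  if (length(widths) != 3L || any(widths <= 0))
    stop("'widths' must be 3 positive numbers", call. = FALSE)
  if (!is.null(amplitudes)) {
    amplitudes <- as.matrix(amplitudes)
    if (nrow(amplitudes) != 3L)
      stop("'amplitudes' must have 3 rows", call. = FALSE)
    if (any(amplitudes < -1e-12))
      stop("'amplitudes' must be non-negative", call. = FALSE)
    if (!is.null(delays) && length(delays) != ncol(amplitudes))
      stop("'delays' must match ncol(amplitudes)", call. = FALSE)
  }
  structure(list(centers = as.numeric(centers), widths = as.numeric(widths),
                 amplitudes = amplitudes, delays = delays),
            class = "band_model")
}

#' @export
print.band_model <- function(x, ...) {
  cat("<band_model>\n  centers (eV):", sprintf("%.3f", x$centers),
      "\n  widths  (eV):", sprintf("%.3f", x$widths), "\n")
  if (!is.null(x$amplitudes))
    cat("  amplitudes: 3 x", ncol(x$amplitudes), "delays\n")
  invisible(x)
}

# Exact non-negative least squares for a 3-column design by KKT enumeration
# over the 8 active sets. GtG = t(G) %*% G, Gty = t(G) %*% y.
nnls3 <- function(GtG, Gty) {
  p <- length(Gty)
  subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  best <- NULL
  best_obj <- Inf
  for (S in subsets) {
    a <- numeric(p)
    if (length(S)) {
      sol <- tryCatch(solve(GtG[S, S, drop = FALSE], Gty[S]),
                      error = function(e) NULL)
      if (is.null(sol) || any(!is.finite(sol))) next
      a[S] <- sol
    }
    if (any(a < -1e-10)) next
    g <- GtG %*% a - Gty           # gradient/2
    if (all(g[setdiff(seq_len(p), S)] >= -1e-8 * max(1, max(abs(Gty))))) {
      return(pmax(a, 0))
    }
    obj <- sum(a * g) - sum(a * Gty)  # monitor in case KKT never exact
    if (obj < best_obj) { best_obj <- obj; best <- pmax(a, 0) }
  }
  if (is.null(best)) numeric(p) else best
}

#' Fit the three-Gaussian band model to a transient map
#'
#' Global least squares: the three centres and widths are shared across all
#' delays while each band has a free non-negative amplitude at every delay.
#' For given centres/widths the amplitudes are the exact non-negative
#' least-squares solution per delay (solved by active-set enumeration), and
#' the six nonlinear shape parameters are optimised by Levenberg--Marquardt
#' over the stacked residuals, with seeded multi-start from jittered initial
#' values.
#'
#' @param map a [transient_map()].
#' @param init a [band_model()] carrying the initial centres and widths
#'   (band count is fixed at three; no automatic guessing).
#' @param energy_window length-2 eV window containing all three centres.
#' @param n_starts number of jittered starts (>= 1).
#' @param seed seed for the start jitter.
#' @param max_iter Levenberg--Marquardt iteration cap per start.
#' @return A `band_model` with fitted `centers`, `widths`, `amplitudes`,
#'   `amplitude_se` (per-delay linear-fit standard errors), `delays`,
#'   `residual_norm` per delay and `deviance`.
#' @export
fit_band_model <- function(map, init, energy_window = range(map$energies),
                           n_starts = 5L, seed = 1L, max_iter = 200L) {
  if (!inherits(init, "band_model"))
    stop("'init' must be a band_model()", call. = FALSE)
  sel <- map$energies >= energy_window[1] & map$energies <= energy_window[2]
  if (any(init$centers < energy_window[1] | init$centers > energy_window[2]))
    stop("energy_window must cover all three band centres", call. = FALSE)
  w <- map$energies[sel]
  Y <- t(map$values[, sel, drop = FALSE])   # energies x delays
  n_delay <- ncol(Y)

  design <- function(centers, widths) {
    vapply(1:3, function(k) exp(-(w - centers[k])^2 / (2 * widths[k]^2)),
           numeric(length(w)))
  }
  amps_for <- function(centers, widths) {
    G <- design(centers, widths)
    GtG <- crossprod(G)
    GtY <- crossprod(G, Y)
    A <- vapply(seq_len(n_delay), function(j) nnls3(GtG, GtY[, j]),
                numeric(3))
    list(G = G, A = A)
  }
  resid_fn <- function(par) {
    centers <- par[1:3]
    widths <- exp(par[4:6])
    fa <- amps_for(centers, widths)
    as.numeric(Y - fa$G %*% fa$A)
  }

  base_par <- c(init$centers, log(init$widths))
  starts <- with_seed(seed, {
    lapply(seq_len(max(1L, n_starts)), function(i) {
      if (i == 1L) return(base_par)
      c(init$centers + stats::rnorm(3, sd = 0.05),
        log(init$widths) + stats::rnorm(3, sd = 0.2))
    })
  })
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ptol = 1e-12, ftol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("band-model fit did not converge from any start", call. = FALSE)

  centers <- best$par[1:3]
  widths <- exp(best$par[4:6])
  ord <- order(centers)
  centers <- centers[ord]; widths <- widths[ord]
  fa <- amps_for(centers, widths)
  resid_mat <- Y - fa$G %*% fa$A
  # per-delay amplitude s.e. from the linear subproblem at fixed shape
  dof <- max(length(w) - 3L, 1L)
  GtG_inv <- tryCatch(solve(crossprod(fa$G)), error = function(e) NULL)
  amp_se <- if (is.null(GtG_inv)) matrix(NA_real_, 3, n_delay) else {
    s2 <- colSums(resid_mat^2) / dof
    sqrt(pmax(outer(diag(GtG_inv), s2), 0))
  }
  out <- band_model(centers, widths, amplitudes = fa$A, delays = map$delays)
  out$amplitude_se <- amp_se
  out$residual_norm <- sqrt(colSums(resid_mat^2))
  out$deviance <- best$deviance
  out$convergence <- best$info
  out
}

#' Kinetics fit result
#'
#' @param kind one of `"exp_decay"`, `"exp_rise"`, `"sigmoid"`, `"erf_rise"`.
#' @param tau_or_thalf fitted time constant / half-rise / 10--90 rise (fs).
#' @param uncertainty 1 standard error from the fit covariance (fs).
#' @param amplitude,baseline model units.
#' @param flagged logical, TRUE when the fit is degenerate (parameter at a
#'   bound, unconstrained timescale, ...).
#' @param extra optional named list of additional fitted quantities.
#' @return List of class `kinetics_result`.
#' @export
kinetics_result <- function(kind, tau_or_thalf, uncertainty, amplitude = NA,
                            baseline = NA, flagged = FALSE, extra = list()) {
  structure(list(kind = kind, tau_or_thalf = tau_or_thalf,
                 uncertainty = uncertainty, amplitude = amplitude,
                 baseline = baseline, flagged = flagged, extra = extra),
            class = "kinetics_result")
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat(sprintf("<kinetics_result> %s: %.4g +/- %.2g fs%s\n", x$kind,
              x$tau_or_thalf, x$uncertainty,
              if (isTRUE(x$flagged)) " [flagged]" else ""))
  invisible(x)
}

#' Fit an exponential decay or rise with IRF convolution
#'
#' Fits `baseline + A * k(t)` where `k` is `H(t) exp(-t/tau)` (decay) or
#' `H(t) (1 - exp(-t/tau))` (rise), analytically convolved with a Gaussian
#' instrument response of FWHM `irf_fwhm`. Uncertainty is 1 s.e. from the
#' least-squares covariance.
#'
#' @param delays fs.
#' @param values amplitude trace.
#' @param kind `"decay"` or `"rise"`.
#' @param irf_fwhm fs (0 disables the convolution).
#' @param tau_init optional initial time constant.
#' @param value_se optional known per-point standard deviations of `values`
#'   (e.g. `amplitude_se` from [fit_band_model()]). When supplied the fit is
#'   weighted by `1/value_se^2` and the parameter covariance uses the known
#'   variances instead of the residual-variance estimate (which non-negative
#'   amplitude clipping would otherwise deflate).
#' @return A [kinetics_result()]; `flagged` is TRUE when the time constant
#'   runs into a bound or the amplitude is consistent with zero.
#' @export
fit_exponential <- function(delays, values, kind = c("decay", "rise"),
                            irf_fwhm = 0, tau_init = NULL, value_se = NULL) {
  kind <- match.arg(kind)
  if (length(delays) < 8L)
    stop("need at least 8 points for an exponential fit", call. = FALSE)
  sd_irf <- if (irf_fwhm > 0) irf_fwhm / .FWHM_SIGMA else 0
  if (is.null(tau_init)) {
    span <- diff(range(delays[delays >= 0]))
    tau_init <- max(span / 4, 1e-3)
  }
  wts <- if (is.null(value_se)) rep(1, length(values)) else {
    if (length(value_se) != length(values) || any(value_se <= 0))
      stop("'value_se' must be positive and match 'values'", call. = FALSE)
    1 / value_se
  }
  model <- function(par, t) {
    par[3] + par[1] * exp_kinetics(t, exp(par[2]), kind, sd_irf)
  }
  a0 <- if (kind == "decay") max(values) - min(values) else
    values[length(values)] - min(values)
  p0 <- c(a0, log(tau_init), min(values))
  fit <- minpack.lm::nls.lm(
    par = p0, fn = function(p) wts * (values - model(p, delays)),
    control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-14,
                                         ftol = 1e-14))
  par <- fit$par
  res <- wts * (values - model(par, delays))
  J <- num_jacobian(function(p) -wts * (values - model(p, delays)), par)
  se <- if (is.null(value_se)) lsq_se(res, J) else {
    # known variances: cov = (J' J)^-1 on the standardised residual scale
    cv <- tryCatch(solve(crossprod(J)), error = function(e)
      matrix(NA_real_, length(par), length(par)))
    sqrt(pmax(diag(cv), 0))
  }
  tau <- exp(par[2])
  se_tau <- tau * se[2]          # delta method from log-tau
  tau_bound <- !is.finite(se_tau) || tau > 50 * diff(range(delays)) ||
    tau < 1e-6
  amp_zero <- is.finite(se[1]) && abs(par[1]) < 2 * se[1]
  kinetics_result(
    kind = if (kind == "decay") "exp_decay" else "exp_rise",
    tau_or_thalf = tau, uncertainty = se_tau,
    amplitude = par[1], baseline = par[3],
    flagged = tau_bound || amp_zero,
    extra = list(amplitude_se = se[1], deviance = fit$deviance))
}

#' Fit a logistic sigmoid to a time trace
#'
#' Fits `y0 + A / (1 + exp(-(t - t_half)/k))` with free asymptotes, midpoint
#' and slope. The reported time is `t_half`, the time at which the trace
#' crosses the midpoint of its asymptotes. The trace must bracket the
#' transition (plateaus at both ends inside the window).
#'
#' @param times fs.
#' @param values trace values.
#' @return A [kinetics_result()] with `kind = "sigmoid"`; `amplitude` is the
#'   difference of asymptotes and `extra$slope` the logistic slope (fs).
#' @export
fit_sigmoid <- function(times, values) {
  if (length(times) < 6L)
    stop("need at least 6 points for a sigmoid fit", call. = FALSE)
  n <- length(times)
  head_mean <- mean(values[seq_len(max(3L, floor(0.15 * n)))])
  tail_mean <- mean(values[seq(n - max(3L, floor(0.15 * n)) + 1L, n)])
  rng <- max(values) - min(values)
  if (rng <= 0) stop("flat trace: nothing to fit", call. = FALSE)
  if (abs(tail_mean - head_mean) < 0.5 * rng)
    stop("trace does not bracket the transition; extend the time window",
         call. = FALSE)
  mid <- (head_mean + tail_mean) / 2
  sgn <- sign(tail_mean - head_mean)
  cross <- which(sgn * (values - mid) >= 0)[1]
  t_half0 <- if (is.na(cross) || cross <= 1) stats::median(times)
             else times[cross]
  k0 <- max(diff(range(times)) / 20, 1e-3)
  model <- function(p, t) p[1] + p[2] / (1 + exp(-(t - p[3]) / exp(p[4])))
  p0 <- c(head_mean, tail_mean - head_mean, t_half0, log(k0))
  fit <- minpack.lm::nls.lm(
    par = p0, fn = function(p) values - model(p, times),
    control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-14,
                                         ftol = 1e-14))
  par <- fit$par
  res <- values - model(par, times)
  J <- num_jacobian(function(p) -(values - model(p, times)), par)
  se <- lsq_se(res, J)
  # the transition region (midpoint +/- 2 logistic slopes) must sit inside
  # the window, otherwise the asymptotes are extrapolated, not measured
  slope <- exp(par[4])
  if (par[3] - 2 * slope < min(times) || par[3] + 2 * slope > max(times))
    stop("fitted transition region extends beyond the trace; ",
         "extend the time window", call. = FALSE)
  kinetics_result("sigmoid", tau_or_thalf = par[3], uncertainty = se[3],
                  amplitude = par[2], baseline = par[1],
                  flagged = FALSE,
                  extra = list(slope = slope,
                               amplitude_se = se[2],
                               deviance = fit$deviance))
}

#' Fit an error-function step and report the 10--90 rise
#'
#' Fits `y0 + A * Phi((t - t0)/sigma_t)` (Gaussian CDF). The 10--90 rise is
#' `2 * qnorm(0.9) * sigma_t = 2.5631 * sigma_t`; for a Gaussian IRF of FWHM
#' f this equals `1.0885 * f`.
#'
#' @param times fs.
#' @param values step-like trace.
#' @return A [kinetics_result()] with `kind = "erf_rise"`; `tau_or_thalf` is
#'   the 10--90 rise time and `extra` carries `sigma_t` and `t0`. A warning
#'   is issued when the trace trend is not monotone beyond noise.
#' @export
fit_erf_rise <- function(times, values) {
  if (length(times) < 5L)
    stop("need at least 5 points for an erf fit", call. = FALSE)
  if (stats::cor(times, values, method = "spearman") < 0.5)
    warning("trace is not monotone beyond noise; erf fit may be unreliable",
            call. = FALSE)
  rng <- diff(range(values))
  mid <- (max(values) + min(values)) / 2
  t0_0 <- times[which.min(abs(values - mid))]
  s0 <- max(diff(range(times)) / 10, 1e-3)
  model <- function(p, t) p[1] + p[2] * stats::pnorm((t - p[3]) / exp(p[4]))
  p0 <- c(min(values), rng, t0_0, log(s0))
  fit <- minpack.lm::nls.lm(
    par = p0, fn = function(p) values - model(p, times),
    control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-14,
                                         ftol = 1e-14))
  par <- fit$par
  res <- values - model(par, times)
  J <- num_jacobian(function(p) -(values - model(p, times)), par)
  se <- lsq_se(res, J)
  sigma_t <- exp(par[4])
  rise <- 2 * stats::qnorm(0.9) * sigma_t
  kinetics_result("erf_rise", tau_or_thalf = rise,
                  uncertainty = 2 * stats::qnorm(0.9) * sigma_t * se[4],
                  amplitude = par[2], baseline = par[1],
                  extra = list(sigma_t = sigma_t, t0 = par[3],
                               deviance = fit$deviance))
}

#' Check the sequential ordering of the three bands
#'
#' From fitted per-delay amplitudes, computes for each band the time at
#' which it crosses half of its extremal amplitude (downward crossing for
#' decaying bands, upward for rising ones, by linear interpolation) and
#' reports whether the crossings follow the first-band-decays-first,
#' last-band-rises-last ordering (band 1 before band 2 before band 3).
#'
#' @param bm a fitted [band_model()] with `amplitudes` and `delays`.
#' @param flat_tol bands whose amplitude range is below `flat_tol` times the
#'   overall amplitude maximum are excluded from the ordering.
#' @return List with `half_times` (fs, NA for excluded bands),
#'   `ordering_ok` (logical; NA when indeterminate), `indeterminate`
#'   (logical) and `excluded` (band indices).
#' @export
sequence_check <- function(bm, flat_tol = 0.05) {
  if (is.null(bm$amplitudes) || is.null(bm$delays))
    stop("band model carries no fitted amplitudes", call. = FALSE)
  A <- bm$amplitudes
  t <- bm$delays
  overall <- max(A)
  half_times <- rep(NA_real_, 3)
  excluded <- integer(0)
  for (k in 1:3) {
    a <- A[k, ]
    if (diff(range(a)) < flat_tol * overall) {
      excluded <- c(excluded, k)
      next
    }
    level <- (max(a) + min(a)) / 2
    rising <- a[length(a)] >= level   # band ends high: rise; ends low: decay
    if (rising) {
      cross <- which(a[-1] >= level & a[-length(a)] < level)
      idx <- cross[1]
    } else {
      # decay crossing after the (possibly IRF-delayed) amplitude peak
      cross <- which(a[-1] <= level & a[-length(a)] > level)
      cross <- cross[cross >= which.max(a)]
      idx <- cross[1]
    }
    if (is.na(idx) || length(idx) == 0L) { excluded <- c(excluded, k); next }
    # linear interpolation inside the crossing interval
    f <- (level - a[idx]) / (a[idx + 1] - a[idx])
    half_times[k] <- t[idx] + f * (t[idx + 1] - t[idx])
  }
  usable <- which(!is.na(half_times))
  if (length(usable) < 3L) {
    ordering_ok <- NA
    indeterminate <- TRUE
  } else {
    d <- diff(half_times)
    indeterminate <- any(d == 0)
    ordering_ok <- if (indeterminate) NA else all(d > 0)
  }
  list(half_times = half_times, ordering_ok = ordering_ok,
       indeterminate = indeterminate, excluded = excluded)
}
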