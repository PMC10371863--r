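# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state on
# exit so seeded generators do not perturb the global stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

is_sorted_strict <- function(x) all(diff(x) > 0)

# Numeric Jacobian of a residual function, central differences.
num_jacobian <- function(fn, par, eps = 1e-6) {
  f0 <- fn(par)
  J <- matrix(NA_real_, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(1, abs(par[j]))
    pp <- pm <- par
    pp[j] <- par[j] + h
    pm[j] <- par[j] - h
    J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  J
}

# Standard errors from a residual vector and Jacobian at the optimum.
lsq_se <- function(resid, J) {
  n <- length(resid)
  p <- ncol(J)
  dof <- max(n - p, 1L)
  s2 <- sum(resid^2) / dof
  JtJ <- crossprod(J)
  cov <- tryCatch(solve(JtJ) * s2, error = function(e) {
    matrix(NA_real_, p, p)
  })
  sqrt(pmax(diag(cov), 0))
}
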