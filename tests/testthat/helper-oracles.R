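# Independent oracles and fixture builders. These deliberately re-derive
# results by direct summation / exhaustive scans, without calling the
# package's synthesis or detection code paths.

# Direct Lorentzian sum: sigma(w) = sum_k S_k * (G/(2*pi)) / ((w-E_k)^2 + (G/2)^2)
brute_lorentzian <- function(energies_ev, strengths, grid, fwhm) {
  half <- fwhm / 2
  out <- numeric(length(grid))
  for (i in seq_along(grid)) {
    s <- 0
    for (k in seq_along(energies_ev)) {
      s <- s + strengths[k] * (fwhm / (2 * pi)) /
        ((grid[i] - energies_ev[k])^2 + half^2)
    }
    out[i] <- s
  }
  out
}

# Direct per-record cross-section arithmetic in atomic units.
brute_stick <- function(eps_core, eps_vac, dip) {
  omega <- eps_vac - eps_core
  list(energy_ev = omega * 27.211386,
       strength = (4 / 3) * pi^2 * omega * (1 / 137.035999) * sum(dip^2))
}

# Exhaustive O(N^3) hydrogen-bond scan: loops over every (donor, H, acceptor)
# atom triple with explicit distance/angle arithmetic.
brute_hbond_scan <- function(frame, d_max, theta_max) {
  el <- frame$elements
  xyz <- frame$coords
  mol <- frame$molecule_ids
  radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66)
  n <- length(el)
  hits <- list()
  for (D in seq_len(n)) {
    if (!(el[D] %in% c("N", "O"))) next
    for (H in seq_len(n)) {
      if (el[H] != "H" || H == D) next
      dDH <- sqrt(sum((xyz[H, ] - xyz[D, ])^2))
      if (dDH >= 1.2 * (radii[el[D]] + radii["H"])) next  # not covalent
      for (A in seq_len(n)) {
        if (!(el[A] %in% c("N", "O")) || A == D) next
        if (mol[A] == mol[D]) next
        dDA <- sqrt(sum((xyz[A, ] - xyz[D, ])^2))
        if (dDA > d_max) next
        u <- xyz[H, ] - xyz[D, ]
        v <- xyz[A, ] - xyz[D, ]
        ang <- acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) *
          180 / pi
        if (ang > theta_max) next
        hits[[length(hits) + 1L]] <- c(D, H, A)
      }
    }
  }
  if (length(hits) == 0) return(matrix(integer(0), 0, 3))
  do.call(rbind, hits)
}

# Random frame of 2-6 small N/O-hydride molecules in a tight box, so that
# some donor-H...acceptor triples fall inside and some outside the cuts.
random_hbond_frame <- function(seed) {
  set.seed(seed)
  n_mol <- sample(2:6, 1)
  elements <- character(0)
  coords <- NULL
  mol_ids <- integer(0)
  for (m in seq_len(n_mol)) {
    heavy <- sample(c("N", "O"), 1)
    center <- runif(3, 0, 5.5)
    n_h <- sample(1:2, 1)
    elements <- c(elements, heavy)
    coords <- rbind(coords, center)
    mol_ids <- c(mol_ids, m)
    for (h in seq_len(n_h)) {
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      elements <- c(elements, "H")
      coords <- rbind(coords, center + runif(1, 0.95, 1.05) * dir)
      mol_ids <- c(mol_ids, m)
    }
  }
  xyz_frame(elements, coords, time = 0, molecule_ids = mol_ids)
}

# Idealised planar urea (Angstrom). Atom order: C O N N Hp Hd Hp Hd where
# Hp is the amine hydrogen cis to the carbonyl oxygen.
urea_coords <- function() {
  rbind(
    C   = c(0, 0, 0),
    O   = c(0, 1.23, 0),
    N1  = c(1.195, -0.69, 0),
    N2  = c(-1.195, -0.69, 0),
    H1p = c(2.07, -0.185, 0),
    H1d = c(1.195, -1.70, 0),
    H2p = c(-2.07, -0.185, 0),
    H2d = c(-1.195, -1.70, 0))
}

urea_elements <- function() c("C", "O", "N", "N", "H", "H", "H", "H")

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# Place a second urea so that its carbonyl O accepts a bond from the first
# urea's N1-H1p at the requested donor-acceptor distance and angle (deg).
urea_dimer_frame <- function(d_NA = 2.9, angle_deg = 0) {
  u1 <- urea_coords()
  N1 <- u1["N1", ]
  dirH <- (u1["H1p", ] - N1) / sqrt(sum((u1["H1p", ] - N1)^2))
  # rotate the acceptor direction away from the N-H axis by angle_deg in-plane
  ax <- rot_z(angle_deg) %*% dirH
  O_target <- N1 + d_NA * as.numeric(ax)
  u2 <- urea_coords() %*% t(rot_z(145))       # arbitrary orientation
  shift <- O_target - u2[2, ]
  u2 <- sweep(u2, 2, shift, `+`)
  xyz_frame(c(urea_elements(), urea_elements()), rbind(u1, u2),
            molecule_ids = rep(1:2, each = 8))
}

water_coords <- function(center = c(0, 0, 0)) {
  rbind(O = center,
        H1 = center + c(0.96, 0, 0),
        H2 = center + c(-0.24, 0.93, 0))
}
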