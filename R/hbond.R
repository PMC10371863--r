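# Covalent radii (Angstrom) for the elements handled here.
.COV_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05)

#' Geometric hydrogen-bond criterion
#'
#' A donor--hydrogen...acceptor triple is accepted when the donor--acceptor
#' distance is at most `d_max` and the hydrogen donor--acceptor angle is at
#' most `theta_max`. By default the angle is measured at the donor, between
#' the donor-to-hydrogen and donor-to-acceptor vectors (the usual convention
#' for a tight <= 20--30 degree cut); `angle_at = "hydrogen"` instead uses
#' the deviation of the D-H...A angle from linearity.
#'
#' @param d_max donor--acceptor distance ceiling, Angstrom.
#' @param theta_max angle ceiling, degrees (0 < theta_max < 90).
#' @param angle_at `"donor"` (default) or `"hydrogen"`.
#' @return List of class `hbond_criterion`.
#' @export
hbond_criterion <- function(d_max = 3.0, theta_max = 20,
                            angle_at = c("donor", "hydrogen")) {
  stopifnot_scalar_number(d_max, "d_max", positive = TRUE)
  stopifnot_scalar_number(theta_max, "theta_max", positive = TRUE)
  if (theta_max >= 90) stop("theta_max must be < 90 degrees", call. = FALSE)
  structure(list(d_max = d_max, theta_max = theta_max,
                 angle_at = match.arg(angle_at)),
            class = "hbond_criterion")
}

#' Covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance is below 1.2 times the sum of
#' their covalent radii. No topology file is needed.
#'
#' @param elements chemical symbols.
#' @param coords N x 3 coordinates, Angstrom.
#' @return Two-column integer matrix of bonded atom index pairs.
#' @export
guess_bonds <- function(elements, coords) {
  coords <- as.matrix(coords)
  n <- length(elements)
  radii <- .COV_RADII[elements]
  if (anyNA(radii))
    stop("unknown element(s): ",
         paste(unique(elements[is.na(radii)]), collapse = ", "), call. = FALSE)
  if (n < 2L) return(matrix(integer(0), 0, 2))
  d <- as.matrix(stats::dist(coords))
  cut <- 1.2 * outer(radii, radii, `+`)
  hit <- which(d < cut & upper.tri(d), arr.ind = TRUE)
  unname(hit)
}

molecule_ids_from_bonds <- function(elements, coords) {
  n <- length(elements)
  bonds <- guess_bonds(elements, coords)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(bonds)) for (r in seq_len(nrow(bonds))) {
    a <- find(bonds[r, 1]); b <- find(bonds[r, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, 1L)
  as.integer(match(roots, unique(roots)))
}

.vec_angle_deg <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect hydrogen bonds in a frame
#'
#' Enumerates donor--H...acceptor triples: donors are N or O atoms with a
#' covalently bonded hydrogen, acceptors are N or O atoms of a different
#' molecule. A triple is recorded when it passes the geometric criterion.
#' Urea donor hydrogens are additionally classified proximal/distal with
#' respect to their own carbonyl oxygen (see [classify_urea_hydrogens()]);
#' water hydrogens are labelled `"water"`, anything else `"other"`.
#'
#' @param frame an [xyz_frame()] with molecule ids.
#' @param crit an [hbond_criterion()].
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor` (atom
#'   indices), `donor_mol`, `acceptor_mol`, `distance` (Angstrom), `angle`
#'   (degrees) and `donor_class`. Zero rows (with a warning) when the frame
#'   has no hydrogens.
#' @export
detect_hbonds <- function(frame, crit = hbond_criterion()) {
  el <- frame$elements
  xyz <- frame$coords
  mol <- frame$molecule_ids
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), donor_mol = integer(0),
                      acceptor_mol = integer(0), distance = numeric(0),
                      angle = numeric(0), donor_class = character(0),
                      stringsAsFactors = FALSE)
  if (!any(el == "H")) {
    warning("frame contains no hydrogens; no donors possible", call. = FALSE)
    return(empty)
  }
  bonds <- guess_bonds(el, xyz)
  # donor-H pairs: N/O covalently bonded to H
  dh <- matrix(integer(0), 0, 2)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      a <- bonds[r, 1]; b <- bonds[r, 2]
      if (el[a] %in% c("N", "O") && el[b] == "H") dh <- rbind(dh, c(a, b))
      if (el[b] %in% c("N", "O") && el[a] == "H") dh <- rbind(dh, c(b, a))
    }
  }
  acceptors <- which(el %in% c("N", "O"))
  hclass <- .hydrogen_classes(frame)
  recs <- empty
  for (r in seq_len(nrow(dh))) {
    D <- dh[r, 1]; H <- dh[r, 2]
    for (A in acceptors) {
      if (mol[A] == mol[D]) next   # intramolecular pairs excluded
      dDA <- sqrt(sum((xyz[A, ] - xyz[D, ])^2))
      if (dDA > crit$d_max) next
      ang <- if (crit$angle_at == "donor") {
        .vec_angle_deg(xyz[H, ] - xyz[D, ], xyz[A, ] - xyz[D, ])
      } else {
        180 - .vec_angle_deg(xyz[D, ] - xyz[H, ], xyz[A, ] - xyz[H, ])
      }
      if (ang > crit$theta_max) next
      recs <- rbind(recs, data.frame(
        donor = D, hydrogen = H, acceptor = A,
        donor_mol = mol[D], acceptor_mol = mol[A],
        distance = dDA, angle = ang,
        donor_class = hclass[H], stringsAsFactors = FALSE))
    }
  }
  rownames(recs) <- NULL
  recs
}

# Per-hydrogen class across the whole frame: proximal/distal for urea,
# "water" for water hydrogens, "other" otherwise.
.hydrogen_classes <- function(frame) {
  el <- frame$elements
  cls <- rep("other", length(el))
  for (m in unique(frame$molecule_ids)) {
    idx <- which(frame$molecule_ids == m)
    comp <- table(el[idx])
    if (identical(sort(names(comp)), c("H", "O")) &&
        comp[["O"]] == 1 && comp[["H"]] == 2) {
      cls[idx[el[idx] == "H"]] <- "water"
    } else if (.is_urea_like(comp)) {
      pd <- tryCatch(classify_urea_hydrogens(frame, m), error = function(e) NULL)
      if (!is.null(pd)) cls[as.integer(names(pd))] <- pd
    }
  }
  cls
}

.is_urea_like <- function(comp) {
  all(c("C", "N", "O", "H") %in% names(comp)) &&
    comp[["C"]] == 1 && comp[["O"]] == 1 && comp[["N"]] == 2 &&
    comp[["H"]] %in% 3:4
}

#' Classify urea amine hydrogens as proximal or distal
#'
#' Within each NH2 group of a urea molecule (connectivity recovered from
#' covalent radii) the hydrogen whose through-space distance to that urea's
#' own carbonyl oxygen is smallest is proximal (cis to C=O), the other
#' distal. For planar urea this reproduces the cis/trans assignment about
#' the C--N bond and is robust to mild pyramidalisation. A deprotonated urea
#' (3 hydrogens) is still classified group by group and the count asymmetry
#' is reported in the `"counts"` attribute.
#'
#' @param frame an [xyz_frame()].
#' @param molecule_id id of the urea molecule within the frame.
#' @return Named character vector (names = atom indices of the hydrogens,
#'   values `"proximal"` or `"distal"`), with attribute `counts` =
#'   `c(proximal = , distal = )`.
#' @export
classify_urea_hydrogens <- function(frame, molecule_id) {
  idx <- which(frame$molecule_ids == molecule_id)
  el <- frame$elements[idx]
  comp <- table(el)
  if (!.is_urea_like(comp))
    stop("molecule ", molecule_id, " does not have urea composition ",
         "(C1 N2 O1 H3-4); found: ",
         paste(names(comp), as.integer(comp), collapse = " "), call. = FALSE)
  xyz <- frame$coords
  bonds <- guess_bonds(frame$elements, frame$coords)
  o_atom <- idx[el == "O"]
  n_atoms <- idx[el == "N"]
  out <- character(0)
  for (N in n_atoms) {
    hs <- integer(0)
    for (r in seq_len(nrow(bonds))) {
      a <- bonds[r, 1]; b <- bonds[r, 2]
      if (a == N && frame$elements[b] == "H") hs <- c(hs, b)
      if (b == N && frame$elements[a] == "H") hs <- c(hs, a)
    }
    hs <- hs[hs %in% idx]
    if (length(hs) == 0L) next
    dO <- vapply(hs, function(h) sqrt(sum((xyz[h, ] - xyz[o_atom, ])^2)), 0)
    ord <- order(dO)
    lab <- rep("distal", length(hs))
    lab[ord[1]] <- "proximal"
    names(lab) <- hs
    out <- c(out, lab)
  }
  counts <- c(proximal = sum(out == "proximal"), distal = sum(out == "distal"))
  attr(out, "counts") <- counts
  if (sum(counts) != 4L)
    attr(out, "asymmetry") <- sprintf(
      "urea molecule %d carries %d amine hydrogens (expected 4)",
      molecule_id, sum(counts))
  out
}

#' Select hydrogen-bonded QM-region candidates
#'
#' Scans frames for molecule pairs satisfying the hydrogen-bond criterion
#' and the requested composition (`"dimer"`: two urea molecules;
#' `"monomer_water"`: a urea and a water molecule), then draws a seeded
#' uniform sample. For dimers the class of the linking hydrogen (proximal /
#' distal, from the shortest qualifying bond) is recorded.
#'
#' @param frames list of [xyz_frame()]s.
#' @param crit an [hbond_criterion()].
#' @param mode `"dimer"` or `"monomer_water"`.
#' @param n_select number of candidates to draw (capped at the number of
#'   qualifying pairs).
#' @param seed integer seed.
#' @return data.frame with columns `frame`, `mol_a`, `mol_b`,
#'   `linking_class`; zero rows (with a message) when nothing qualifies.
#' @export
select_qm_candidates <- function(frames, crit = hbond_criterion(),
                                 mode = c("dimer", "monomer_water"),
                                 n_select = Inf, seed = 1L) {
  mode <- match.arg(mode)
  cand <- data.frame(frame = integer(0), mol_a = integer(0),
                     mol_b = integer(0), linking_class = character(0),
                     stringsAsFactors = FALSE)
  for (fi in seq_along(frames)) {
    fr <- frames[[fi]]
    kinds <- .molecule_kinds(fr)
    hb <- suppressWarnings(detect_hbonds(fr, crit))
    if (nrow(hb) == 0) next
    key <- paste(pmin(hb$donor_mol, hb$acceptor_mol),
                 pmax(hb$donor_mol, hb$acceptor_mol))
    for (ky in unique(key)) {
      rows <- hb[key == ky, , drop = FALSE]
      a <- rows$donor_mol[1]; b <- rows$acceptor_mol[1]
      ka <- kinds[as.character(a)]; kb <- kinds[as.character(b)]
      ok <- switch(mode,
        dimer = identical(unname(c(ka, kb)), c("urea", "urea")),
        monomer_water = setequal(c(ka, kb), c("urea", "water")))
      if (!isTRUE(ok)) next
      best <- rows[which.min(rows$distance), ]
      cand <- rbind(cand, data.frame(
        frame = fi, mol_a = min(a, b), mol_b = max(a, b),
        linking_class = best$donor_class, stringsAsFactors = FALSE))
    }
  }
  if (nrow(cand) == 0) {
    message("no qualifying ", mode, " pair found")
    return(cand)
  }
  n <- min(n_select, nrow(cand))
  pick <- with_seed(seed, sample.int(nrow(cand), n))
  out <- cand[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.molecule_kinds <- function(frame) {
  ids <- unique(frame$molecule_ids)
  kinds <- vapply(ids, function(m) {
    comp <- table(frame$elements[frame$molecule_ids == m])
    if (.is_urea_like(comp)) "urea"
    else if (identical(sort(names(comp)), c("H", "O")) &&
             comp[["O"]] == 1 && comp[["H"]] == 2) "water"
    else "other"
  }, "")
  names(kinds) <- as.character(ids)
  kinds
}
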