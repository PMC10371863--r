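#' Construct a trajectory frame
#'
#' A frame holds one snapshot of a molecular trajectory: element symbols,
#' Cartesian coordinates in Angstrom, an optional per-atom molecule id
#' partitioning the atoms into molecules, and a time stamp in femtoseconds.
#'
#' @param elements character vector of chemical symbols.
#' @param coords numeric N x 3 matrix of Cartesian coordinates (Angstrom).
#' @param time time stamp in fs.
#' @param molecule_ids integer vector, one id per atom, grouping atoms into
#'   molecules. Defaults to a single molecule.
#' @return An object of class `xyz_frame`.
#' @export
xyz_frame <- function(elements, coords, time = 0, molecule_ids = NULL) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L)
    stop("'coords' must be an N x 3 numeric matrix", call. = FALSE)
  if (length(elements) != nrow(coords))
    stop("length(elements) must equal nrow(coords)", call. = FALSE)
  if (is.null(molecule_ids)) molecule_ids <- rep(1L, length(elements))
  if (length(molecule_ids) != length(elements))
    stop("'molecule_ids' must have one entry per atom", call. = FALSE)
  structure(
    list(elements = as.character(elements), coords = coords,
         time = as.numeric(time), molecule_ids = as.integer(molecule_ids)),
    class = "xyz_frame")
}

#' @export
print.xyz_frame <- function(x, ...) {
  cat(sprintf("<xyz_frame> %d atoms (%s) at t = %g fs, %d molecule(s)\n",
              length(x$elements),
              paste(names(sort(-table(x$elements))), collapse = ","),
              x$time, length(unique(x$molecule_ids))))
  invisible(x)
}

#' Read a multi-frame XYZ trajectory
#'
#' Parses standard multi-frame XYZ: per frame an atom-count line, a comment
#' line and N atom lines (`symbol x y z`). Frame times are taken from a
#' `t= <value>` token on the comment line (fs) when present; otherwise they
#' are synthesised as `frame index * frame_time_step`.
#'
#' Atoms are assigned molecule ids by connected components of the covalent
#' bond graph (see [guess_bonds()]).
#'
#' @param path path to the XYZ file.
#' @param frame_time_step time step in fs used when the comment line carries
#'   no time token.
#' @param assign_molecules logical; infer molecule ids from covalent
#'   connectivity (default TRUE).
#' @return A list of [xyz_frame()] objects (class `xyz_trajectory`).
#' @export
read_xyz_trajectory <- function(path, frame_time_step = 0.5,
                                assign_molecules = TRUE) {
  stopifnot_scalar_number(frame_time_step, "frame_time_step", positive = TRUE)
  lines <- readLines(path)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    warning("empty XYZ file: ", path, call. = FALSE)
    return(structure(list(), class = "xyz_trajectory"))
  }
  frames <- list()
  i <- 1L
  k <- 0L
  n_atoms_first <- NA_integer_
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    k <- k + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n <= 0L)
      stop(sprintf("malformed atom count line at frame %d: '%s'", k, lines[i]),
           call. = FALSE)
    if (is.na(n_atoms_first)) n_atoms_first <- n
    if (n != n_atoms_first)
      stop(sprintf("inconsistent atom count at frame %d: %d (expected %d)",
                   k, n, n_atoms_first), call. = FALSE)
    if (i + 1L + n > length(lines))
      stop(sprintf("truncated frame %d: expected %d atom lines", k, n),
           call. = FALSE)
    comment <- lines[i + 1L]
    atom_lines <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(atom_lines), "\\s+")
    if (any(vapply(toks, length, 1L) < 4L))
      stop(sprintf("malformed atom line in frame %d", k), call. = FALSE)
    elements <- vapply(toks, `[[`, "", 1L)
    xyz <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (anyNA(xyz))
      stop(sprintf("non-numeric coordinate in frame %d", k), call. = FALSE)
    tm <- .parse_time_token(comment)
    if (is.na(tm)) tm <- (k - 1L) * frame_time_step
    mol <- if (assign_molecules) molecule_ids_from_bonds(elements, xyz)
           else rep(1L, n)
    frames[[k]] <- xyz_frame(elements, xyz, time = tm, molecule_ids = mol)
    i <- i + 2L + n
  }
  times <- vapply(frames, `[[`, 0, "time")
  if (!is_sorted_strict(times))
    stop("frame times are not strictly increasing", call. = FALSE)
  structure(frames, class = "xyz_trajectory")
}

.parse_time_token <- function(comment) {
  m <- regmatches(comment, regexec("t=\\s*([-0-9.eE+]+)", comment))[[1]]
  if (length(m) == 2L) as.numeric(m[2]) else NA_real_
}

#' Write a multi-frame XYZ trajectory
#'
#' Writes frames in the dialect read by [read_xyz_trajectory()]: the comment
#' line carries `t= <fs>`.
#'
#' @param frames list of [xyz_frame()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(as.character(length(fr$elements)), con)
    writeLines(sprintf("t= %.6f", fr$time), con)
    writeLines(sprintf("%-2s %18.10f %18.10f %18.10f", fr$elements,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
  }
  invisible(path)
}

.TRANSITION_COLS <- c("time", "eps_core", "eps_vac",
                      "dip_x", "dip_y", "dip_z",
                      "traj_id", "ion_label", "system_label")

#' Construct a transition table
#'
#' One row per core-to-valence "stick": time stamp (fs), core and
#' valence-vacancy orbital energies (hartree), transition-dipole components
#' (atomic units) and metadata labels. This is the carrier of the inputs to
#' the absorption cross-section formula.
#'
#' @param time fs.
#' @param eps_core,eps_vac orbital energies in hartree; `eps_core < eps_vac`.
#' @param dip_x,dip_y,dip_z transition-dipole components, atomic units.
#' @param traj_id trajectory identifier.
#' @param ion_label one of `"HOMO"`, `"HOMO-3"`, `"other"` (ionised orbital).
#' @param system_label one of `"dimer"`, `"monomer_water"` (QM region type).
#' @return A `data.frame` of class `transition_table`.
#' @export
transition_table <- function(time, eps_core, eps_vac, dip_x, dip_y, dip_z,
                             traj_id = "traj1", ion_label = "HOMO",
                             system_label = "dimer") {
  df <- data.frame(time = time, eps_core = eps_core, eps_vac = eps_vac,
                   dip_x = dip_x, dip_y = dip_y, dip_z = dip_z,
                   traj_id = traj_id, ion_label = ion_label,
                   system_label = system_label,
                   stringsAsFactors = FALSE)
  validate_transition_table(df)
}

validate_transition_table <- function(df) {
  missing <- setdiff(.TRANSITION_COLS, names(df))
  if (length(missing))
    stop("missing column: ", paste(missing, collapse = ", "), call. = FALSE)
  num_cols <- .TRANSITION_COLS[1:6]
  for (cl in num_cols) {
    if (!is.numeric(df[[cl]]) || anyNA(df[[cl]]) || any(!is.finite(df[[cl]])))
      stop(sprintf("column '%s' must be finite numeric", cl), call. = FALSE)
  }
  if (any(df$eps_core >= df$eps_vac))
    stop("eps_core must be < eps_vac for every transition", call. = FALSE)
  bad_ion <- setdiff(unique(df$ion_label), c("HOMO", "HOMO-3", "other"))
  if (length(bad_ion))
    stop("invalid ion_label: ", paste(bad_ion, collapse = ", "), call. = FALSE)
  bad_sys <- setdiff(unique(df$system_label), c("dimer", "monomer_water"))
  if (length(bad_sys))
    stop("invalid system_label: ", paste(bad_sys, collapse = ", "),
         call. = FALSE)
  class(df) <- unique(c("transition_table", class(df)))
  df
}

#' Read / write transition tables
#'
#' Comma-separated text with `#`-prefixed metadata lines. Energies are stored
#' in hartree and dipoles in atomic units; times in fs (declared in the
#' metadata header).
#'
#' @param path file path.
#' @return `read_transition_table` returns a `transition_table` data.frame.
#' @export
read_transition_table <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(body) < 1L) stop("no header line found in ", path, call. = FALSE)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE, colClasses = NA)
  missing <- setdiff(.TRANSITION_COLS, names(df))
  if (length(missing))
    stop("missing column: ", paste(missing, collapse = ", "), call. = FALSE)
  for (cl in .TRANSITION_COLS[1:6]) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (anyNA(vn)) {
        row <- which(is.na(vn))[1]
        stop(sprintf("non-numeric value in column '%s' at data row %d", cl, row),
             call. = FALSE)
      }
      df[[cl]] <- vn
    }
  }
  validate_transition_table(df)
}

#' @rdname read_transition_table
#' @param table a `transition_table`.
#' @export
write_transition_table <- function(table, path) {
  table <- validate_transition_table(as.data.frame(table))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# transition table",
               "# units: time fs; eps_core, eps_vac hartree; dipoles a.u."),
             con)
  out <- table[.TRANSITION_COLS]
  for (cl in .TRANSITION_COLS[1:6]) out[[cl]] <- sprintf("%.17g", out[[cl]])
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
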