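#' Construct a transient map
#'
#' Delay-stacked spectra: a matrix of cross-section (atomic units) or
#' delta-OD values on a photon-energy grid (eV) versus pump--probe delay (fs).
#'
#' @param delays numeric vector of delays (fs), strictly increasing.
#' @param energies numeric vector of photon energies (eV), strictly
#'   increasing.
#' @param values numeric matrix, `length(delays)` rows by `length(energies)`
#'   columns.
#' @param kind `"sigma"` (cross-section) or `"dod"` (delta-OD).
#' @return An object of class `transient_map`.
#' @export
transient_map <- function(delays, energies, values,
                          kind = c("sigma", "dod")) {
  kind <- match.arg(kind)
  delays <- as.numeric(delays)
  energies <- as.numeric(energies)
  values <- as.matrix(values)
  if (!is_sorted_strict(delays))
    stop("'delays' must be strictly increasing", call. = FALSE)
  if (!is_sorted_strict(energies))
    stop("'energies' must be strictly increasing", call. = FALSE)
  if (nrow(values) != length(delays) || ncol(values) != length(energies))
    stop("'values' must be length(delays) x length(energies)", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("'values' must be finite", call. = FALSE)
  if (kind == "sigma" && any(values < -1e-12))
    stop("cross-section map must be non-negative", call. = FALSE)
  structure(list(delays = delays, energies = energies, values = values,
                 kind = kind),
            class = "transient_map")
}

#' @export
print.transient_map <- function(x, ...) {
  cat(sprintf(
    "<transient_map> %s: %d delays [%g, %g] fs x %d energies [%g, %g] eV\n",
    x$kind, length(x$delays), min(x$delays), max(x$delays),
    length(x$energies), min(x$energies), max(x$energies)))
  invisible(x)
}

#' Read / write a transient map as CSV
#'
#' Layout: `#`-prefixed metadata lines (including `# kind: sigma|dod`), then
#' a matrix whose first row holds the photon energies (eV, first cell is the
#' `delay_fs` column label) and whose first column holds the delays (fs).
#' Write followed by read reproduces axes and values to full stored
#' precision. Files with unsorted axes are rejected, never silently sorted.
#'
#' @param map a [transient_map()].
#' @param path file path.
#' @return `read_transient_map` returns a [transient_map()];
#'   `write_transient_map` returns `path` invisibly.
#' @export
write_transient_map <- function(map, path) {
  if (!inherits(map, "transient_map"))
    map <- transient_map(map$delays, map$energies, map$values,
                         kind = map$kind %||% "sigma")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# transient map: first row photon energies (eV), first column delays (fs)",
               paste0("# kind: ", map$kind)), con)
  header <- paste(c("delay_fs", sprintf("%.17g", map$energies)), collapse = ",")
  writeLines(header, con)
  for (i in seq_along(map$delays)) {
    writeLines(paste(c(sprintf("%.17g", map$delays[i]),
                       sprintf("%.17g", map$values[i, ])), collapse = ","), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_transient_map
#' @export
read_transient_map <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(trimws(lines), "#")]
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(body) < 2L)
    stop("transient map file needs a header row and at least one delay row",
         call. = FALSE)
  kind <- "sigma"
  km <- grep("^#\\s*kind:", meta, value = TRUE)
  if (length(km)) kind <- trimws(sub("^#\\s*kind:", "", km[1]))
  header <- strsplit(body[1], ",")[[1]]
  energies <- as.numeric(header[-1])
  rows <- strsplit(body[-1], ",")
  mat <- t(vapply(rows, as.numeric, numeric(length(header))))
  delays <- mat[, 1]
  values <- mat[, -1, drop = FALSE]
  if (anyNA(energies) || anyNA(delays) || anyNA(values))
    stop("non-numeric entry in transient map file", call. = FALSE)
  if (!is_sorted_strict(delays) || !is_sorted_strict(energies))
    stop("transient map file has unsorted axes; refusing to reorder",
         call. = FALSE)
  transient_map(delays, energies, values, kind = kind)
}
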