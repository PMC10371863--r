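#' Physical constants and unit conversions
#'
#' Central table of the constants used throughout the package. All energies
#' on disk for transition tables are atomic units (hartree); photon-energy
#' axes of spectra and maps are eV.
#'
#' @return Named list with elements
#'   \describe{
#'     \item{hartree_ev}{eV per hartree, 27.211386}
#'     \item{alpha}{fine-structure constant, 1/137.035999}
#'     \item{fwhm_to_sigma}{divide a Gaussian FWHM by this (2 sqrt(2 log 2))
#'       to get its standard deviation}
#'   }
#' @examples
#' xas_constants()$hartree_ev
#' @export
xas_constants <- function() {
  list(
    hartree_ev    = 27.211386,
    alpha         = 1 / 137.035999,
    fwhm_to_sigma = 2 * sqrt(2 * log(2))
  )
}

.HARTREE_EV <- 27.211386
.ALPHA <- 1 / 137.035999
.FWHM_SIGMA <- 2 * sqrt(2 * log(2))
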