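#' Unit conventions and conversion constants
#'
#' All internal quantities are kept in a single unit system: energies in
#' hartree, lengths in angstrom, charges in elementary charges. Coulomb
#' sums are evaluated in atomic units by converting angstrom to bohr at
#' the point of use, so there is exactly one conversion site.
#'
#' @name units
#' @keywords internal
NULL

# angstrom -> bohr
ANG_TO_BOHR <- 1.8897259886

# hartree -> wavenumber (cm^-1)
HARTREE_TO_WAVENUMBER <- 219474.6313632

# oscillator-strength to integrated molar absorptivity band area:
# integral of eps(nu) d nu = f / 4.319e-9  (eps in M^-1 cm^-1, nu in cm^-1)
OSC_TO_BAND_AREA <- 1 / 4.319e-9

#' Convert wavelength (nm) to wavenumber (cm^-1) and back
#'
#' The two maps are mutual inverses; \code{nm_to_wavenumber(wavenumber_to_nm(x))}
#' recovers \code{x} to machine precision.
#'
#' @param nm wavelength in nanometres
#' @param nu wavenumber in cm^-1
#' @return numeric vector in the target unit
#' @export
nm_to_wavenumber <- function(nm) 1e7 / nm

#' @rdname nm_to_wavenumber
#' @export
wavenumber_to_nm <- function(nu) 1e7 / nu

#' Convert an excitation energy in hartree to a wavelength in nm
#' @param e_hartree excitation energy, hartree
#' @return wavelength, nm
#' @export
hartree_to_nm <- function(e_hartree) {
  wavenumber_to_nm(e_hartree * HARTREE_TO_WAVENUMBER)
}
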