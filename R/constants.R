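#' Physical constants and package defaults
#'
#' Single registry for every unit-conversion constant and physical default
#' used by the package, so that each value is fixed in exactly one place.
#'
#' @return A named list with components:
#' \describe{
#'   \item{hartree_to_cm1}{219474.6313632, CODATA hartree-to-wavenumber
#'     conversion (cm^-1 per hartree).}
#'   \item{hartree_to_kcal}{627.5095, hartree to kcal/mol.}
#'   \item{dipolar_cm1_angstrom}{1.299, the scalar of the point-dipole
#'     coupling |D_AB| = 1.299 g^2 / r^3 when r is in Angstrom and D_AB in
#'     cm^-1 (the magnetic-dipole prefactor with Bohr magneton, vacuum
#'     permeability and unit bookkeeping folded in).}
#'   \item{g_free}{2.0023, free-electron Lande g-factor, default for
#'     nitroxide radicals.}
#'   \item{d_no_angstrom}{1.28, default N-O bond length of the nitroxide
#'     group (typical nitroxide value; configurable everywhere it is used).}
#'   \item{l_pi_n_angstrom, l_pi_o_angstrom}{0.574 and 0.461, fitted
#'     offsets of the pi-lobe barycentres from the N and O nuclei in the
#'     four-point spin model.}
#'   \item{pop_n, pop_o}{0.45 and 0.51, Mulliken spin populations of N and
#'     O in a nitroxide radical.}
#' }
#' @examples
#' spin_constants()$hartree_to_kcal
#' @export
spin_constants <- function() {
  list(
    hartree_to_cm1      = 219474.6313632,
    hartree_to_kcal     = 627.5095,
    dipolar_cm1_angstrom = 1.299,
    g_free              = 2.0023,
    d_no_angstrom       = 1.28,
    l_pi_n_angstrom     = 0.574,
    l_pi_o_angstrom     = 0.461,
    pop_n               = 0.45,
    pop_o               = 0.51
  )
}

# internal shorthand
.const <- function(name) spin_constants()[[name]]
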