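## Physical constants (CODATA 2018) shared by the DEER and PRE modules.
## Units are SI unless stated otherwise; distances elsewhere in the package
## are nm, times are microseconds (DEER) or seconds (PRE).

.const <- list(
  mu0      = 4 * pi * 1e-7,        # vacuum permeability, T m / A
  mu_B     = 9.2740100783e-24,     # Bohr magneton, J / T
  hbar     = 1.054571817e-34,      # reduced Planck constant, J s
  k_B      = 1.380649e-23,         # Boltzmann constant, J / K
  N_A      = 6.02214076e23,        # Avogadro constant, 1 / mol
  R_kJ     = 8.31446261815324e-3,  # gas constant, kJ / (mol K)
  g_e      = 2.0023,               # free-electron g-factor
  gamma_H  = 2.67522e8             # proton gyromagnetic ratio, rad / (s T)
)

#' Physical constants used by the package
#'
#' Returns the table of CODATA constants (and the electron g-factor and proton
#' gyromagnetic ratio) used throughout the DEER and PRE calculations.
#'
#' @return A named list of constants in SI units.
#' @export
spin_constants <- function() .const

#' Default Lennard-Jones parameters by element
#'
#' Element-class 6-12 Lennard-Jones parameters used for the steric (external)
#' energy of a placed rotamer against the protein. Values are representative
#' of CHARMM36 heavy-atom classes; a user-supplied table with the same columns
#' overrides them in all placement functions. Combination follows
#' Lorentz-Berthelot rules (arithmetic mean sigma, geometric mean epsilon).
#'
#' @return A data frame with columns \code{element}, \code{epsilon} (kJ/mol)
#'   and \code{sigma} (nm).
#' @export
#' @examples
#' lj_default_table()
lj_default_table <- function() {
  data.frame(
    element = c("C", "N", "O", "S"),
    epsilon = c(0.2343, 0.8368, 0.5021, 1.8828), # kJ/mol
    sigma   = c(0.3581, 0.3296, 0.3029, 0.3563), # nm
    stringsAsFactors = FALSE
  )
}

# Look up (epsilon, sigma) for a vector of element symbols; unknown elements
# are a parameterization error.
.lj_lookup <- function(elements, lj) {
  idx <- match(elements, lj$element)
  if (anyNA(idx)) {
    stop("no Lennard-Jones parameters for element(s): ",
         paste(unique(elements[is.na(idx)]), collapse = ", "))
  }
  list(epsilon = lj$epsilon[idx], sigma = lj$sigma[idx])
}
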