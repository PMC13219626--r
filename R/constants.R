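#' Physical constants used throughout the package
#'
#' Returns the pinned constants table (CODATA 2018 where applicable). All unit
#' conversions in the package go through this single table.
#'
#' @return A named list with elements:
#'   \describe{
#'     \item{kB_ev}{Boltzmann constant, eV K^-1.}
#'     \item{R_kcal}{Molar gas constant, kcal mol^-1 K^-1.}
#'     \item{R_kj}{Molar gas constant, kJ mol^-1 K^-1.}
#'     \item{nu0}{Default attempt (desorption) frequency, s^-1.}
#'     \item{A_richardson}{Richardson constant, A m^-2 K^-2.}
#'     \item{T_default}{Default temperature, K.}
#'     \item{hc}{Photon energy-wavelength product, eV nm.}
#'     \item{hartree_kcal}{kcal mol^-1 per hartree.}
#'     \item{hartree_ev}{eV per hartree.}
#'     \item{bohr_per_angstrom}{bohr per Angstrom.}
#'     \item{kcal_per_kj}{kcal per kJ.}
#'   }
#' @export
#' @examples
#' physical_constants()$hc
physical_constants <- function() {
  list(
    kB_ev             = 8.617333262e-5,
    R_kcal            = 1.987204259e-3,
    R_kj              = 8.314462618e-3,
    nu0               = 1e12,
    A_richardson      = 6e5,
    T_default         = 298,
    hc                = 1239.84193,
    hartree_kcal      = 627.5094740631,
    hartree_ev        = 27.211386245988,
    bohr_per_angstrom = 1.8897259886,
    kcal_per_kj       = 1 / 4.184
  )
}

#' Convert between photon energy (eV) and wavelength (nm)
#'
#' The conversion is an involution: `ev_nm(ev_nm(x)) == x`. The same function
#' maps eV to nm and nm to eV via `hc / value` with hc = 1239.84193 eV nm.
#'
#' @param value Positive numeric vector, in eV or nm.
#' @return Numeric vector in the complementary unit.
#' @export
#' @examples
#' ev_nm(1239.84193) # 1 eV
#' ev_nm(765)        # 1.62 eV
ev_nm <- function(value) {
  if (!is.numeric(value) || any(!is.finite(value)) || any(value <= 0)) {
    stop("ev_nm(): value must be finite and positive", call. = FALSE)
  }
  physical_constants()$hc / value
}
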