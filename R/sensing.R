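# Adsorption and sensing metrics: cohesive energy, adsorption energy,
# Arrhenius recovery time, Richardson-type conductivity, dipole magnitude,
# mean polarizability, and a desorption-regime classifier.

#' Cohesive energy per atom
#'
#' `(total - sum(atom_energies)) / n`; more negative means stronger overall
#' atomic bonding.
#'
#' @param total_energy Total energy of the bound structure, kcal/mol.
#' @param atom_energies Isolated-atom energies, kcal/mol (non-empty).
#' @return Cohesive energy in kcal/mol per atom.
#' @export
cohesive_energy <- function(total_energy, atom_energies) {
  if (length(atom_energies) == 0L) {
    stop("cohesive_energy(): atom_energies must be non-empty", call. = FALSE)
  }
  (total_energy - sum(atom_energies)) / length(atom_energies)
}

#' Adsorption energy of a sensor@analyte complex
#'
#' `E_complex - (E_sensor + E_drug)`; negative values indicate favorable
#' adsorption.
#'
#' @param e_complex,e_sensor,e_drug Total energies, kcal/mol.
#' @return Adsorption energy, kcal/mol.
#' @export
adsorption_energy <- function(e_complex, e_sensor, e_drug) {
  e_complex - (e_sensor + e_drug)
}

#' Arrhenius desorption recovery time
#'
#' `tau = nu0^-1 * exp(-E_ads / (R T))` with the molar gas constant in
#' kcal/(mol K) pairing with the molar adsorption energy. For favorable
#' adsorption (E_ads < 0) tau exceeds 1/nu0.
#'
#' @param e_ads Adsorption energy, kcal/mol.
#' @param temperature Temperature in K (default 298).
#' @param nu0 Attempt frequency, s^-1 (default 1e12).
#' @return Recovery time in seconds.
#' @export
#' @examples
#' recovery_time(-11.15) # ~1.5e-4 s
recovery_time <- function(e_ads, temperature = physical_constants()$T_default,
                          nu0 = physical_constants()$nu0) {
  if (temperature <= 0) stop("recovery_time(): temperature must be > 0", call. = FALSE)
  if (nu0 <= 0) stop("recovery_time(): nu0 must be > 0", call. = FALSE)
  kT <- physical_constants()$R_kcal * temperature
  (1 / nu0) * exp(-e_ads / kT)
}

#' Richardson-type electrical conductivity
#'
#' `sigma = A * T^{3/2} * exp(-HLG / (2k))`. Two thermal-energy conventions
#' are provided:
#' \describe{
#'   \item{`physical`}{k = kB * T in eV, dimensionally consistent with the
#'     gap in eV.}
#'   \item{`paper_compat`}{k = R * T in kJ/mol (2.4777 at 298 K) paired with
#'     the bare eV numeral of the gap. This mixed convention is the only one
#'     that reproduces the reference conductivity table; it is provided for
#'     reproducibility, not endorsed as physics.}
#' }
#'
#' @param hlg HOMO-LUMO gap, eV (>= 0).
#' @param temperature Temperature in K (default 298).
#' @param A Richardson constant, A m^-2 K^-2 (default 6e5).
#' @param mode `"physical"` or `"paper_compat"`.
#' @return Conductivity in S/m.
#' @export
#' @examples
#' conductivity(1.18, mode = "paper_compat") / 1e9 # ~2.43
conductivity <- function(hlg, temperature = physical_constants()$T_default,
                         A = physical_constants()$A_richardson,
                         mode = c("physical", "paper_compat")) {
  mode <- match.arg(mode)
  if (hlg < 0) stop("conductivity(): hlg must be >= 0", call. = FALSE)
  if (temperature <= 0) stop("conductivity(): temperature must be > 0", call. = FALSE)
  k <- physical_constants()
  kT <- switch(mode,
    physical     = k$kB_ev * temperature,
    paper_compat = k$R_kj * temperature
  )
  A * temperature^1.5 * exp(-hlg / (2 * kT))
}

#' Dipole moment magnitude
#'
#' Euclidean norm of the Cartesian dipole components.
#'
#' @param components Numeric length-3 vector (mu_x, mu_y, mu_z), Debye.
#' @return Magnitude in Debye.
#' @export
dipole_magnitude <- function(components) {
  components <- as.numeric(components)
  if (length(components) != 3L || any(!is.finite(components))) {
    stop("dipole_magnitude(): need 3 finite components", call. = FALSE)
  }
  sqrt(sum(components^2))
}

#' Mean (isotropic) polarizability
#'
#' One third of the trace of the polarizability tensor.
#'
#' @param tensor Symmetric 3x3 matrix, a.u. (asymmetry beyond 1e-8 rejected).
#' @return Mean polarizability, a.u.
#' @export
mean_polarizability <- function(tensor) {
  tensor <- matrix(as.numeric(tensor), 3, 3)
  if (max(abs(tensor - t(tensor))) > 1e-8) {
    stop("mean_polarizability(): tensor must be symmetric (tol 1e-8)",
         call. = FALSE)
  }
  sum(diag(tensor)) / 3
}

#' Classify the desorption regime of a sensor@analyte pair
#'
#' A pair with recovery time at or below `tau_fast` desorbs quickly enough for
#' repeated sensing; one at or above `tau_slow` is effectively an irreversible
#' adsorbent; anything between is intermediate.
#'
#' @param e_ads Adsorption energy, kcal/mol (carried through for reporting).
#' @param tau Recovery time, s.
#' @param tau_fast,tau_slow Regime thresholds in seconds (defaults 1 and 1e6).
#' @return One of `"reversible-sensor"`, `"adsorbent"`, `"intermediate"`.
#' @export
classify_regime <- function(e_ads, tau, tau_fast = 1, tau_slow = 1e6) {
  if (tau_fast >= tau_slow) {
    stop("classify_regime(): tau_fast must be < tau_slow", call. = FALSE)
  }
  if (tau <= tau_fast) "reversible-sensor"
  else if (tau >= tau_slow) "adsorbent"
  else "intermediate"
}

#' Sensing metrics for one sensor@analyte pair
#'
#' Bundles the adsorption energy, recovery time, conductivities of the free
#' sensor and of the complex, and the regime label into one record.
#'
#' @param sensor,complex,drug `result_bundle`s for the isolated sensor, the
#'   complex, and the isolated analyte.
#' @param temperature,nu0,A See [recovery_time()] and [conductivity()].
#' @param sigma_mode Conductivity convention (see [conductivity()]).
#' @param tau_fast,tau_slow Regime thresholds (see [classify_regime()]).
#' @return An object of class `sensing_metrics`: list with `e_ads`, `tau`,
#'   `sigma_free`, `sigma_complex`, `regime`.
#' @export
sensing_metrics <- function(sensor, complex, drug,
                            temperature = physical_constants()$T_default,
                            nu0 = physical_constants()$nu0,
                            A = physical_constants()$A_richardson,
                            sigma_mode = c("physical", "paper_compat"),
                            tau_fast = 1, tau_slow = 1e6) {
  sigma_mode <- match.arg(sigma_mode)
  e_ads <- adsorption_energy(complex$energies$total_energy,
                             sensor$energies$total_energy,
                             drug$energies$total_energy)
  tau <- recovery_time(e_ads, temperature, nu0)
  hlg_free <- reactivity_descriptors(sensor$orbitals)$hlg
  hlg_cpx <- reactivity_descriptors(complex$orbitals)$hlg
  structure(
    list(e_ads = e_ads, tau = tau,
         sigma_free = conductivity(hlg_free, temperature, A, sigma_mode),
         sigma_complex = conductivity(hlg_cpx, temperature, A, sigma_mode),
         regime = classify_regime(e_ads, tau, tau_fast, tau_slow)),
    class = "sensing_metrics"
  )
}

#' @export
print.sensing_metrics <- function(x, ...) {
  cat(sprintf("E_ads %.3f kcal/mol | tau %.3e s | sigma %.3e -> %.3e S/m | %s\n",
              x$e_ads, x$tau, x$sigma_free, x$sigma_complex, x$regime))
  invisible(x)
}
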