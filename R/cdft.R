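# Conceptual-DFT reactivity descriptors from frontier orbital energies.
# All values reported unrounded; 2-decimal display belongs to the report layer.

#' Conceptual-DFT reactivity descriptors
#'
#' From the frontier orbital energies: HOMO-LUMO gap
#' HLG = |E_HOMO - E_LUMO|, chemical hardness eta = HLG/2, chemical potential
#' mu = (E_HOMO + E_LUMO)/2, chemical softness S = 1/(2 eta), and the maximum
#' charge-transfer capacity dnmax = -mu/eta. For a degenerate frontier
#' (eta = 0) softness and dnmax are flagged undefined (NA), never infinite.
#'
#' @param orbitals An `orbital_spectrum`, or a numeric length-2 vector
#'   `c(homo, lumo)` in eV.
#' @return An object of class `reactivity_descriptors`: named list with
#'   `e_homo`, `e_lumo`, `hlg`, `eta`, `mu`, `softness`, `dnmax` (eV except
#'   softness eV^-1 and dnmax dimensionless).
#' @export
#' @examples
#' reactivity_descriptors(c(-5.25, -3.58))
reactivity_descriptors <- function(orbitals) {
  if (inherits(orbitals, "orbital_spectrum")) {
    fr <- frontier_orbitals(orbitals)
    homo <- fr[["homo"]]; lumo <- fr[["lumo"]]
  } else if (is.numeric(orbitals) && length(orbitals) == 2L) {
    homo <- orbitals[1]; lumo <- orbitals[2]
  } else {
    stop("reactivity_descriptors(): need an orbital_spectrum or c(homo, lumo)",
         call. = FALSE)
  }
  hlg <- abs(homo - lumo)
  eta <- (lumo - homo) / 2
  eta <- abs(eta)          # hardness reported as a positive quantity
  mu <- (homo + lumo) / 2
  if (eta > 0) {
    softness <- 1 / (2 * eta)
    dnmax <- -mu / eta
  } else {
    softness <- NA_real_
    dnmax <- NA_real_
  }
  structure(
    list(e_homo = homo, e_lumo = lumo, hlg = hlg, eta = eta, mu = mu,
         softness = softness, dnmax = dnmax),
    class = "reactivity_descriptors"
  )
}

#' @export
print.reactivity_descriptors <- function(x, ...) {
  cat(sprintf(
    "HOMO %.3f  LUMO %.3f  gap %.3f eV | eta %.3f  mu %.3f  S %s  dNmax %s\n",
    x$e_homo, x$e_lumo, x$hlg, x$eta, x$mu,
    if (is.na(x$softness)) "undef" else sprintf("%.3f", x$softness),
    if (is.na(x$dnmax)) "undef" else sprintf("%.3f", x$dnmax)))
  invisible(x)
}

#' Electrophilicity-based charge transfer between sensor and complex
#'
#' ECT = dnmax(isolated sensor) - dnmax(sensor@analyte complex). A negative
#' value is read as charge transferred from the analyte to the sensor. The
#' sign convention is applied literally; no auto-correction.
#'
#' @param sensor,complex `reactivity_descriptors` for the isolated sensor and
#'   the complex.
#' @return An object of class `charge_transfer_report`: list with
#'   `dnmax_sensor`, `dnmax_complex`, `ect`, and `direction`
#'   (`"analyte_to_sensor"`, `"sensor_to_analyte"`, or `"none"`); all NA when
#'   either dnmax is undefined.
#' @export
ect <- function(sensor, complex) {
  stopifnot(inherits(sensor, "reactivity_descriptors"),
            inherits(complex, "reactivity_descriptors"))
  a <- sensor$dnmax
  b <- complex$dnmax
  val <- if (is.na(a) || is.na(b)) NA_real_ else a - b
  direction <- if (is.na(val)) NA_character_
    else if (val < 0) "analyte_to_sensor"
    else if (val > 0) "sensor_to_analyte"
    else "none"
  structure(list(dnmax_sensor = a, dnmax_complex = b, ect = val,
                 direction = direction),
            class = "charge_transfer_report")
}

#' @export
print.charge_transfer_report <- function(x, ...) {
  cat(sprintf("ECT = %s (sensor dNmax %s, complex dNmax %s) [%s]\n",
              format(x$ect), format(x$dnmax_sensor), format(x$dnmax_complex),
              x$direction))
  invisible(x)
}

#' Reactivity descriptor table for a set of bundles
#'
#' Convenience wrapper producing one row per system in the reference-table
#' column order (LUMO, HOMO, HLG, eta, mu, S, dnmax), unrounded.
#'
#' @param bundles Named list of `result_bundle`s.
#' @return A data.frame with one row per bundle.
#' @export
reactivity_table <- function(bundles) {
  rows <- lapply(bundles, function(b) {
    d <- reactivity_descriptors(b$orbitals)
    data.frame(system = b$label, lumo = d$e_lumo, homo = d$e_homo,
               hlg = d$hlg, eta = d$eta, mu = d$mu, S = d$softness,
               dnmax = d$dnmax, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
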