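# Spectrum synthesis: Gaussian-broadened density of states from orbital
# energies and UV-Vis curves from excitation line lists, plus lambda_max and
# red-shift extraction. This is the standard post-processing convolution
# applied to electronic-structure outputs.

# unit-area Gaussian evaluated on grid x, centered at x0, full width at half
# maximum fwhm; peak height 2*sqrt(ln2/pi)/fwhm.
.gauss_unit <- function(x, x0, fwhm) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  exp(-(x - x0)^2 / (2 * s^2)) / (s * sqrt(2 * pi))
}

.spectrum_curve <- function(axis, intensity, fwhm, kind) {
  structure(list(axis = axis, intensity = intensity, fwhm = fwhm, kind = kind),
            class = "spectrum_curve")
}

#' @export
print.spectrum_curve <- function(x, ...) {
  cat(sprintf("<spectrum_curve %s: %d points, fwhm %.3g, max %.4g at %.4g>\n",
              x$kind, length(x$axis), x$fwhm,
              max(x$intensity), x$axis[which.max(x$intensity)]))
  invisible(x)
}

#' Density-of-states curve from orbital energies
#'
#' Sum of unit-area Gaussians centered at each orbital energy; the integral
#' over a window spanning the orbitals by several FWHM approximates the number
#' of broadened orbitals.
#'
#' @param orbitals An `orbital_spectrum`.
#' @param fwhm Broadening full width at half maximum, eV (default 0.3).
#' @param from,to,by Energy grid specification in eV (defaults -15..0 step 0.01).
#' @return A `spectrum_curve` of kind `"dos"` (axis in eV).
#' @export
dos_curve <- function(orbitals, fwhm = 0.3, from = -15, to = 0, by = 0.01) {
  stopifnot(inherits(orbitals, "orbital_spectrum"))
  if (length(orbitals$energies) == 0L) {
    stop("dos_curve(): empty orbital list", call. = FALSE)
  }
  if (fwhm <= 0) stop("dos_curve(): fwhm must be > 0", call. = FALSE)
  axis <- seq(from, to, by = by)
  intensity <- rowSums(vapply(orbitals$energies,
                              function(e0) .gauss_unit(axis, e0, fwhm),
                              numeric(length(axis))))
  .spectrum_curve(axis, intensity, fwhm, "dos")
}

#' UV-Vis absorption curve from an excitation set
#'
#' Each excitation line contributes an oscillator-strength-weighted unit-area
#' Gaussian on the energy axis. A wavelength-axis view is available via
#' [as_wavelength()].
#'
#' @param excitations An `excitation_set` with at least one line of f > 0.
#' @param fwhm Broadening FWHM, eV (default 0.333).
#' @param from,to,by Energy grid in eV (defaults 0.5..6.5 step 0.005).
#' @return A `spectrum_curve` of kind `"uvvis"` (axis in eV).
#' @export
uvvis_curve <- function(excitations, fwhm = 0.333, from = 0.5, to = 6.5,
                        by = 0.005) {
  stopifnot(inherits(excitations, "excitation_set"))
  if (fwhm <= 0) stop("uvvis_curve(): fwhm must be > 0", call. = FALSE)
  if (nrow(excitations) == 0L || all(excitations$f == 0)) {
    stop("uvvis_curve(): no excitation with positive oscillator strength",
         call. = FALSE)
  }
  axis <- seq(from, to, by = by)
  intensity <- rowSums(mapply(
    function(e0, fk) fk * .gauss_unit(axis, e0, fwhm),
    excitations$ev, excitations$f))
  .spectrum_curve(axis, intensity, fwhm, "uvvis")
}

#' Wavelength-axis view of an energy-domain curve
#'
#' Maps each grid energy E to lambda = hc/E by direct resampling (no dE/dlambda
#' Jacobian by default, matching common spectrum-plotting practice); set
#' `jacobian = TRUE` to weight intensities by dE/dlambda = hc/lambda^2.
#'
#' @param curve A `spectrum_curve` on an eV axis.
#' @param jacobian Apply the Jacobian weighting (default FALSE).
#' @return A `spectrum_curve` with axis in nm, ascending.
#' @export
as_wavelength <- function(curve, jacobian = FALSE) {
  stopifnot(inherits(curve, "spectrum_curve"))
  hc <- physical_constants()$hc
  lambda <- hc / curve$axis
  intensity <- curve$intensity
  if (jacobian) intensity <- intensity * hc / lambda^2
  ord <- order(lambda)
  .spectrum_curve(lambda[ord], intensity[ord], curve$fwhm, curve$kind)
}

#' Wavelength of maximum absorption
#'
#' Global intensity maximum of a UV-Vis curve, reported in nm. Exact ties are
#' broken toward the longer wavelength (lower energy).
#'
#' @param curve A `spectrum_curve` of kind `"uvvis"` (eV or nm axis).
#' @return lambda_max in nm.
#' @export
lambda_max <- function(curve) {
  stopifnot(inherits(curve, "spectrum_curve"))
  if (curve$kind != "uvvis") {
    stop("lambda_max(): curve must be of kind 'uvvis'", call. = FALSE)
  }
  if (all(curve$intensity == 0)) {
    stop("lambda_max(): flat zero curve has no defined maximum", call. = FALSE)
  }
  peak <- max(curve$intensity)
  at <- which(curve$intensity == peak)
  # eV axis ascending: lower energy = longer wavelength = first index;
  # nm axis ascending: longer wavelength = last index
  ax <- curve$axis[at]
  if (max(curve$axis) <= 50) {           # energy axis (eV)
    ev_nm(min(ax))
  } else {                               # wavelength axis (nm)
    max(ax)
  }
}

#' Red/blue shift report on complexation
#'
#' @param lambda_free lambda_max of the free sensor, nm.
#' @param lambda_complex lambda_max of the sensor@analyte complex, nm.
#' @return A list with `lambda_free`, `lambda_complex`, `delta_lambda`
#'   (complex minus free, nm) and `direction` (`"red"`, `"blue"`, `"none"`).
#' @export
#' @examples
#' shift_report(521, 765) # 244 nm red shift
shift_report <- function(lambda_free, lambda_complex) {
  if (lambda_free <= 0 || lambda_complex <= 0) {
    stop("shift_report(): wavelengths must be positive", call. = FALSE)
  }
  delta <- lambda_complex - lambda_free
  structure(
    list(lambda_free = lambda_free, lambda_complex = lambda_complex,
         delta_lambda = delta,
         direction = if (delta > 0) "red" else if (delta < 0) "blue" else "none"),
    class = "shift_report"
  )
}

#' @export
print.shift_report <- function(x, ...) {
  cat(sprintf("lambda %.1f -> %.1f nm (delta %+.1f nm, %s shift)\n",
              x$lambda_free, x$lambda_complex, x$delta_lambda, x$direction))
  invisible(x)
}

#' Gap reading from broadened DOS curves
#'
#' Measures the HOMO-LUMO gap the way one reads it off a plotted DOS: the
#' occupied and virtual manifolds are broadened separately and the distance
#' between the highest occupied peak center and the lowest unoccupied peak
#' center is returned. For levels separated by more than the broadening width
#' the peak centers coincide with the underlying orbital energies, so the
#' reading matches the frontier-orbital gap to within one grid step.
#'
#' @param orbitals The `orbital_spectrum` the DOS is built from.
#' @param fwhm Broadening FWHM in eV (default 0.3).
#' @param by Grid step in eV (default 0.01).
#' @return Gap in eV as read from the curves.
#' @export
dos_gap <- function(orbitals, fwhm = 0.3, by = 0.01) {
  stopifnot(inherits(orbitals, "orbital_spectrum"))
  occ <- orbitals$occupations > 0.5
  if (!any(occ) || all(occ)) {
    stop("dos_gap(): need both occupied and virtual orbitals", call. = FALSE)
  }
  lo <- min(orbitals$energies) - 5 * fwhm
  hi <- max(orbitals$energies) + 5 * fwhm
  curve_occ <- dos_curve(orbital_spectrum(orbitals$energies[occ],
                                          orbitals$occupations[occ]),
                         fwhm = fwhm, from = lo, to = hi, by = by)
  curve_vir <- dos_curve(orbital_spectrum(orbitals$energies[!occ],
                                          rep(2, sum(!occ))),
                         fwhm = fwhm, from = lo, to = hi, by = by)
  # highest occupied peak center: local maxima of the occupied curve
  peak_centers <- function(curve) {
    y <- curve$intensity
    idx <- which(diff(sign(diff(y))) < 0) + 1L
    if (length(idx) == 0L) idx <- which.max(y)
    curve$axis[idx]
  }
  homo_peak <- max(peak_centers(curve_occ))
  lumo_peak <- min(peak_centers(curve_vir))
  lumo_peak - homo_peak
}
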