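# Data model for quantum-chemistry result bundles: constructors and validators.
# Canonical units: eV (orbitals, excitations), kcal/mol (thermochemistry),
# nm (wavelengths), Debye (dipoles), a.u. (polarizability, densities).

.supported_elements <- c("H", "C", "N", "O", "Al", "Zn")

#' Molecular geometry
#'
#' @param elements Character vector of element symbols (supported set: H, C,
#'   N, O, Al, Zn).
#' @param coords Numeric matrix, one row per atom, columns x, y, z in Angstrom.
#' @param charge Integer total charge.
#' @param label Free-text label (for XYZ files this is the comment line).
#' @return An object of class `geometry`.
#' @export
geometry <- function(elements, coords, charge = 0L, label = "") {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (length(elements) < 1L) {
    stop("geometry(): at least one atom required", call. = FALSE)
  }
  if (nrow(coords) != length(elements)) {
    stop("geometry(): coords must have one row per element", call. = FALSE)
  }
  bad <- setdiff(unique(elements), .supported_elements)
  if (length(bad) > 0L) {
    stop("geometry(): unsupported element(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(coords))) {
    stop("geometry(): coordinates must be finite", call. = FALSE)
  }
  structure(
    list(elements = as.character(elements), coords = coords,
         charge = as.integer(charge), label = as.character(label)),
    class = "geometry"
  )
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry: %d atoms (%s), charge %d> %s\n",
              length(x$elements),
              paste(unique(x$elements), collapse = ","),
              x$charge, x$label))
  invisible(x)
}

#' Orbital energy spectrum
#'
#' Energies are stored sorted ascending with occupations aligned. The frontier
#' orbitals are defined by an occupancy threshold of 0.5: the HOMO is the
#' highest-energy orbital with occupation > 0.5, the LUMO the lowest-energy
#' orbital with occupation <= 0.5 (degenerate ties broken by index).
#'
#' @param energies Numeric vector of orbital energies in eV.
#' @param occupations Numeric vector in \[0, 2\] aligned with `energies`.
#' @return An object of class `orbital_spectrum`.
#' @export
orbital_spectrum <- function(energies, occupations) {
  if (length(energies) != length(occupations)) {
    stop("orbital_spectrum(): energies and occupations lengths differ",
         call. = FALSE)
  }
  if (any(!is.finite(energies)) || any(!is.finite(occupations))) {
    stop("orbital_spectrum(): non-finite entries", call. = FALSE)
  }
  if (any(occupations < 0 | occupations > 2)) {
    stop("orbital_spectrum(): occupations must lie in [0, 2]", call. = FALSE)
  }
  ord <- order(energies)
  structure(
    list(energies = as.numeric(energies[ord]),
         occupations = as.numeric(occupations[ord])),
    class = "orbital_spectrum"
  )
}

#' Frontier orbital energies (HOMO, LUMO)
#'
#' @param orbitals An `orbital_spectrum`.
#' @return Named numeric vector `c(homo = ..., lumo = ...)` in eV.
#' @export
frontier_orbitals <- function(orbitals) {
  stopifnot(inherits(orbitals, "orbital_spectrum"))
  occ <- which(orbitals$occupations > 0.5)
  vir <- which(orbitals$occupations <= 0.5)
  if (length(occ) == 0L || length(vir) == 0L) {
    stop("frontier_orbitals(): need at least one occupied and one virtual orbital",
         call. = FALSE)
  }
  c(homo = max(orbitals$energies[occ]), lumo = min(orbitals$energies[vir]))
}

#' Total / atomic energy record
#'
#' @param total_energy Total energy, kcal/mol.
#' @param atom_energies Optional numeric vector of isolated-atom energies,
#'   kcal/mol.
#' @param label Free-text label.
#' @return An object of class `energy_record`.
#' @export
energy_record <- function(total_energy, atom_energies = NULL, label = "") {
  if (!is.numeric(total_energy) || length(total_energy) != 1L ||
      !is.finite(total_energy)) {
    stop("energy_record(): total_energy must be a single finite number",
         call. = FALSE)
  }
  if (!is.null(atom_energies) && any(!is.finite(atom_energies))) {
    stop("energy_record(): atom_energies must be finite", call. = FALSE)
  }
  structure(
    list(total_energy = total_energy,
         atom_energies = if (is.null(atom_energies)) NULL else as.numeric(atom_energies),
         label = label),
    class = "energy_record"
  )
}

#' Dipole vector and polarizability tensor
#'
#' @param dipole Numeric length-3 vector (mu_x, mu_y, mu_z) in Debye.
#' @param polarizability Symmetric 3x3 matrix in a.u., or NULL.
#' @return An object of class `electric_tensors`.
#' @export
electric_tensors <- function(dipole, polarizability = NULL) {
  dipole <- as.numeric(dipole)
  if (length(dipole) != 3L || any(!is.finite(dipole))) {
    stop("electric_tensors(): dipole must be 3 finite numbers", call. = FALSE)
  }
  if (!is.null(polarizability)) {
    polarizability <- matrix(as.numeric(polarizability), 3, 3)
    if (any(!is.finite(polarizability))) {
      stop("electric_tensors(): polarizability entries must be finite",
           call. = FALSE)
    }
    if (max(abs(polarizability - t(polarizability))) > 1e-8) {
      stop("electric_tensors(): polarizability must be symmetric (tol 1e-8)",
           call. = FALSE)
    }
  }
  structure(list(dipole = dipole, polarizability = polarizability),
            class = "electric_tensors")
}

#' Electronic excitation set
#'
#' Each excitation may be specified by energy (eV) or wavelength (nm); the
#' other is derived via E * lambda = 1239.84193 eV nm.
#'
#' @param ev Numeric vector of excitation energies in eV (NA where `nm` given).
#' @param nm Numeric vector of wavelengths in nm (NA where `ev` given).
#' @param f Oscillator strengths, >= 0.
#' @return An object of class `excitation_set`: data.frame with columns
#'   `ev`, `nm`, `f`.
#' @export
excitation_set <- function(ev = NULL, nm = NULL, f) {
  n <- length(f)
  if (is.null(ev)) ev <- rep(NA_real_, n)
  if (is.null(nm)) nm <- rep(NA_real_, n)
  if (length(ev) != n || length(nm) != n) {
    stop("excitation_set(): ev, nm, f lengths differ", call. = FALSE)
  }
  if (any(!is.finite(f)) || any(f < 0)) {
    stop("excitation_set(): oscillator strengths must be finite and >= 0",
         call. = FALSE)
  }
  hc <- physical_constants()$hc
  for (i in seq_len(n)) {
    if (is.na(ev[i]) && is.na(nm[i])) {
      stop("excitation_set(): entry ", i, " has neither ev nor nm",
           call. = FALSE)
    }
    if (is.na(ev[i])) ev[i] <- hc / nm[i]
    if (is.na(nm[i])) nm[i] <- hc / ev[i]
    if (abs(ev[i] * nm[i] - hc) > 1e-6 * hc) {
      stop("excitation_set(): entry ", i, " violates E*lambda = hc",
           call. = FALSE)
    }
  }
  structure(data.frame(ev = ev, nm = nm, f = f),
            class = c("excitation_set", "data.frame"))
}

#' Result bundle: one system's quantum-chemistry summary
#'
#' @param label System label, unique within a study set.
#' @param orbitals An `orbital_spectrum`.
#' @param energies An `energy_record`.
#' @param geom Optional `geometry`.
#' @param electric Optional `electric_tensors`.
#' @param excitations Optional `excitation_set`.
#' @param atomic_charges Optional per-atom charges in e (fixture use only).
#' @return An object of class `result_bundle`.
#' @export
result_bundle <- function(label, orbitals, energies, geom = NULL,
                          electric = NULL, excitations = NULL,
                          atomic_charges = NULL) {
  stopifnot(inherits(orbitals, "orbital_spectrum"),
            inherits(energies, "energy_record"))
  if (!is.null(geom)) stopifnot(inherits(geom, "geometry"))
  if (!is.null(electric)) stopifnot(inherits(electric, "electric_tensors"))
  if (!is.null(excitations)) stopifnot(inherits(excitations, "excitation_set"))
  if (!is.null(geom) && !is.null(energies$atom_energies) &&
      length(energies$atom_energies) != length(geom$elements)) {
    stop("result_bundle(): atom_energies length must equal atom count",
         call. = FALSE)
  }
  structure(
    list(label = as.character(label), orbitals = orbitals,
         energies = energies, geometry = geom, electric = electric,
         excitations = excitations, atomic_charges = atomic_charges),
    class = "result_bundle"
  )
}

#' @export
print.result_bundle <- function(x, ...) {
  fr <- tryCatch(frontier_orbitals(x$orbitals), error = function(e) NULL)
  cat(sprintf("<result_bundle '%s'>\n", x$label))
  if (!is.null(fr)) {
    cat(sprintf("  HOMO %.3f eV, LUMO %.3f eV\n", fr["homo"], fr["lumo"]))
  }
  cat(sprintf("  total energy %.4f kcal/mol\n", x$energies$total_energy))
  invisible(x)
}
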