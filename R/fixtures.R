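# Printed reference tables for the six fullerene/analyte systems, shipped as
# fixtures. All numeric cells are stored verbatim as printed (2-decimal
# rounding and all); no silent re-derivation. Absolute total energies are not
# printed anywhere, so the energy records below use synthetic anchor values
# chosen such that adsorption_energy() and cohesive_energy() reproduce the
# printed adsorption and cohesive energies exactly.

.fx_systems <- c("C60", "AlC59", "ZnC59", "C60@PCE", "AlC59@PCE", "ZnC59@PCE")

.fx_reactivity <- function() {
  data.frame(
    system = .fx_systems,
    lumo  = c(-3.58, -3.48, -4.09, -3.62, -3.04, -3.92),
    homo  = c(-5.25, -4.66, -4.45, -4.80, -4.12, -4.24),
    hlg   = c(1.67, 1.18, 0.36, 1.18, 1.08, 0.32),
    eta   = c(0.83, 0.59, 0.18, 0.59, 0.54, 0.16),
    mu    = c(-4.41, -4.07, -4.27, -4.21, -3.58, -4.08),
    S     = c(0.59, 0.84, 2.77, 0.84, 0.92, 3.12),
    dnmax = c(5.28, 6.89, 23.72, 7.13, 6.62, 25.5),
    ect   = c(NA, NA, NA, -1.84, -0.26, -1.77),
    stringsAsFactors = FALSE
  )
}

.fx_sensing <- function() {
  data.frame(
    system    = .fx_systems,
    eads      = c(NA, NA, NA, -11.15, -54.08, -32.78),
    tau       = c(NA, NA, NA, 1.54e-4, 4.57e27, 1.09e12),
    sigma_1e9 = c(2.20, 2.43, 2.87, 2.43, 2.48, 2.89),
    stringsAsFactors = FALSE
  )
}

.fx_electric <- function() {
  data.frame(
    system         = .fx_systems,
    dipole         = c(0.00, 11.43, 8.20, 2.26, 13.34, 8.74),
    polarizability = c(163.96, 289.93, 303.11, 685.88, 693.67, 705.40),
    stringsAsFactors = FALSE
  )
}

# The isolated-C60 row pairs 360 nm with 2.78 eV as printed, which is not
# internally consistent with E = hc/lambda (hc/2.78 = 446 nm); the row is kept
# verbatim and excluded from any conversion check.
.fx_uvvis <- function() {
  data.frame(
    system    = .fx_systems,
    lambda_nm = c(360, 521, 427, 530, 765, 764),
    eex_ev    = c(2.78, 2.37, 2.89, 2.33, 1.61, 1.62),
    lambda_experimental_nm = c(345, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

.fx_qtaim <- function() {
  data.frame(
    system    = c("C60@PCE", "AlC59@PCE", "ZnC59@PCE"),
    rho       = c(0.016, 0.080, 0.056),
    laplacian = c(-0.011, -0.060, -0.071),
    g         = c(0.010, 0.092, 0.073),
    v         = c(-0.001, 0.032, 0.001),
    vir       = c(0.009, 0.124, 0.074),
    stringsAsFactors = FALSE
  )
}

.fx_geometry <- function() {
  bonds <- rbind(
    data.frame(structure = "C60",
      bond = c("C11-C1", "C11-C2", "C11-C3", "C2-C6", "C6-C7", "C2-C5",
               "C5-C4", "C6-C8", "C8-C10", "C10-C9", "C9-C5"),
      length_angstrom = c(1.45, 1.40, 1.45, 1.40, 1.45, 1.45, 1.45, 1.45,
                          1.40, 1.45, 1.40)),
    data.frame(structure = "AlC59",
      bond = c("Al-C1", "Al-C2", "Al-C3", "C2-C6", "C6-C7", "C2-C5",
               "C5-C4", "C6-C8", "C8-C10", "C10-C9", "C9-C5"),
      length_angstrom = c(1.92, 1.92, 1.90, 1.40, 1.51, 1.46, 1.51, 1.44,
                          1.40, 1.45, 1.41)),
    data.frame(structure = "ZnC59",
      bond = c("Zn-C1", "Zn-C2", "Zn-C3", "C2-C6", "C6-C7", "C2-C5",
               "C5-C4", "C6-C8", "C8-C10", "C10-C9", "C9-C5"),
      length_angstrom = c(2.03, 2.02, 1.97, 1.39, 1.51, 1.44, 1.49, 1.45,
                          1.39, 1.45, 1.41))
  )
  angles <- rbind(
    data.frame(structure = "C60",
      angle = c("C1-C11-C2", "C1-C11-C3", "C2-C11-C3", "C3-C4-C5",
                "C4-C5-C2", "C5-C2-C6", "C2-C6-C7", "C2-C6-C8",
                "C6-C8-C10", "C8-C10-C9", "C10-C9-C5"),
      degrees = c(120, 108, 119, 108, 108, 120, 120, 120, 120, 120, 120)),
    data.frame(structure = "AlC59",
      angle = c("C1-Al-C2", "C1-Al-C3", "C2-Al-C3", "C3-C4-C5",
                "C4-C5-C2", "C5-C2-C6", "C2-C6-C7", "C2-C6-C8",
                "C6-C8-C10", "C8-C10-C9", "C10-C9-C5"),
      degrees = c(92, 104, 104, 115, 115, 118, 125, 119, 120, 119, 120)),
    data.frame(structure = "ZnC59",
      angle = c("C1-Zn-C2", "C1-Zn-C3", "C2-Zn-C4", "C3-C4-C5",
                "C4-C5-C2", "C5-C2-C6", "C2-C6-C7", "C2-C6-C8",
                "C6-C8-C10", "C8-C10-C9", "C10-C9-C5"),
      degrees = c(82, 91, 99, 113, 113, 119, 124, 121, 120, 118, 119))
  )
  list(bonds = bonds, angles = angles)
}

.fx_charges <- function() {
  list(
    C60   = c(C1 = 0, C2 = 0, C3 = 0, C4 = 0, C5 = 0, C6 = 0, C7 = 0,
              C8 = 0, C9 = 0, C10 = 0, C11 = 0),
    AlC59 = c(C1 = -0.139, C2 = -0.164, C3 = -0.164, C4 = 0.015, C5 = 0.015,
              C6 = 0.014, C7 = 0.008, C8 = 0.011, C9 = 0.002, C10 = -0.011,
              Al = 0.410),
    ZnC59 = c(C1 = -0.292, C2 = -0.260, C3 = -0.214, C4 = 0.077, C5 = 0.039,
              C6 = 0.031, C7 = 0.013, C8 = 0.013, C9 = 0.003, C10 = -0.018,
              Zn = 0.545)
  )
}

# Synthetic anchor energies (kcal/mol). Per-atom isolated energies and drug
# total are arbitrary round numbers; sensor totals are fixed so that
# (total - sum(atoms))/n equals the printed cohesive energy, and complex
# totals are sensor + drug + printed Eads so adsorption_energy() reproduces
# the printed values exactly.
.fx_energies <- function() {
  coh <- c(C60 = -197.3, AlC59 = -193.5, ZnC59 = -199.6)
  natoms <- c(C60 = 60, AlC59 = 60, ZnC59 = 60)
  atom_e <- c(C60 = -170, AlC59 = -170, ZnC59 = -170)
  drug_total <- -5000
  eads <- c("C60@PCE" = -11.15, "AlC59@PCE" = -54.08, "ZnC59@PCE" = -32.78)
  sensors <- lapply(names(coh), function(s) {
    atoms <- rep(atom_e[[s]], natoms[[s]])
    energy_record(sum(atoms) + natoms[[s]] * coh[[s]], atoms, label = s)
  })
  names(sensors) <- names(coh)
  complexes <- lapply(names(eads), function(cx) {
    s <- sub("@PCE", "", cx)
    energy_record(sensors[[s]]$total_energy + drug_total + eads[[cx]],
                  label = cx)
  })
  names(complexes) <- names(eads)
  c(sensors, complexes, list(PCE = energy_record(drug_total, label = "PCE")))
}

#' Reference study fixtures from the printed tables
#'
#' Returns the six fullerene/analyte system bundles (C60, AlC59, ZnC59 and
#' their PCE complexes) carrying every printed number from the reference
#' tables, a PCE drug bundle (energy only), and the geometry/charge tables
#' keyed separately. The full cage coordinates are not distributed with the
#' source study and are therefore not included; bundles carry no geometry.
#'
#' Orbital spectra are minimal four-level spectra whose frontier pair equals
#' the printed (HOMO, LUMO) exactly; excitation sets carry the printed
#' excitation energy as a single dominant line (f = 0.2) with the wavelength
#' derived from it. Energy records use synthetic anchors (see source comments)
#' that reproduce the printed adsorption and cohesive energies exactly.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{systems}{Named list of six `result_bundle`s.}
#'     \item{drug}{A `result_bundle` for the analyte (energy record only).}
#'     \item{geometry_table}{Bond-length/angle tables (list of two data.frames).}
#'     \item{charges}{Atomic charge distributions (named list).}
#'     \item{reactivity_table}{Printed reactivity descriptors (data.frame).}
#'     \item{sensing_table}{Printed Eads/tau/sigma values (data.frame).}
#'     \item{electric_table}{Printed dipole/polarizability values (data.frame).}
#'     \item{uvvis_table}{Printed lambda_max/Eex values (data.frame).}
#'     \item{qtaim_table}{Printed BCP rho, Laplacian, G, V, VIR (data.frame).}
#'     \item{cohesive}{Printed cohesive energies, kcal/mol (named vector).}
#'     \item{contact_lengths}{Printed sensor-analyte contact distances, Angstrom.}
#'   }
#' @export
paper_fixtures <- function() {
  t3 <- .fx_reactivity()
  t5 <- .fx_electric()
  t6 <- .fx_uvvis()
  en <- .fx_energies()
  chg <- .fx_charges()

  make_orbitals <- function(homo, lumo) {
    # two filler levels keep the spectrum non-trivial without moving the frontier
    orbital_spectrum(c(homo - 2, homo, lumo, lumo + 2), c(2, 2, 0, 0))
  }

  systems <- lapply(seq_along(.fx_systems), function(i) {
    s <- .fx_systems[i]
    dip <- t5$dipole[i]
    # component split is arbitrary; only the printed magnitude is meaningful
    electric <- electric_tensors(c(dip, 0, 0),
                                 diag(rep(t5$polarizability[i], 3)))
    exc <- excitation_set(ev = t6$eex_ev[i], f = 0.2)
    result_bundle(
      label = s,
      orbitals = make_orbitals(t3$homo[i], t3$lumo[i]),
      energies = en[[s]],
      electric = electric,
      excitations = exc,
      atomic_charges = if (s %in% names(chg)) chg[[s]] else NULL
    )
  })
  names(systems) <- .fx_systems

  list(
    systems = systems,
    drug = result_bundle("PCE", orbital_spectrum(c(-9, -1), c(2, 0)),
                         en$PCE),
    geometry_table = .fx_geometry(),
    charges = chg,
    reactivity_table = t3,
    sensing_table = .fx_sensing(),
    electric_table = t5,
    uvvis_table = t6,
    qtaim_table = .fx_qtaim(),
    cohesive = c(C60 = -197.3, AlC59 = -193.5, ZnC59 = -199.6),
    contact_lengths = c("C60@PCE" = 2.80, "AlC59@PCE" = 1.22,
                        "ZnC59@PCE" = 1.49)
  )
}
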