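# File formats: XYZ (read/write), JSON result bundles (read/write),
# Gaussian cube volumetric files (write/read-back).

#' Read an XYZ geometry file
#'
#' Standard XYZ dialect: first line atom count, second line free comment
#' (kept verbatim as the geometry label), then one `element x y z` record per
#' atom, whitespace-separated, coordinates in Angstrom.
#'
#' @param path Path to the file.
#' @return A `geometry`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("read_xyz(): file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("read_xyz(): empty file", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) {
    stop("read_xyz(): line 1 does not parse as a positive atom count",
         call. = FALSE)
  }
  if (length(lines) < n + 2L) {
    stop("read_xyz(): header declares ", n, " atoms but record ends at line ",
         length(lines) + 1L, call. = FALSE)
  }
  label <- if (length(lines) >= 2L) lines[2] else ""
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4L) {
      stop("read_xyz(): malformed atom record at line ", ln, call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(xyz))) {
      stop("read_xyz(): non-numeric coordinate at line ", ln, call. = FALSE)
    }
    if (!tok[1] %in% .supported_elements) {
      stop("read_xyz(): unknown element '", tok[1], "' at line ", ln,
           call. = FALSE)
    }
    elements[i] <- tok[1]
    coords[i, ] <- xyz
  }
  geometry(elements, coords, label = label)
}

#' Write a geometry to an XYZ file
#'
#' @param geom A `geometry`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(geom, path) {
  stopifnot(inherits(geom, "geometry"))
  lines <- c(
    as.character(length(geom$elements)),
    geom$label,
    sprintf("%-2s %14.6f %14.6f %14.6f", geom$elements,
            geom$coords[, 1], geom$coords[, 2], geom$coords[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

# Energy unit tags accepted in bundle JSON, as factors to kcal/mol.
.energy_unit_factor <- function(tag) {
  k <- physical_constants()
  switch(tolower(tag),
    "kcal/mol" = 1,
    "kcal.mol-1" = 1,
    "hartree" = k$hartree_kcal,
    "kj/mol" = k$kcal_per_kj,
    "ev" = k$hartree_kcal / k$hartree_ev,
    stop("unknown energy unit tag '", tag, "' at key path energies/units",
         call. = FALSE)
  )
}

#' Read a result bundle from JSON
#'
#' Schema keys: `label`, optional `geometry {elements, coords, charge}`,
#' `orbitals {energies_ev, occupations}`, `energies {total, units, atoms}`,
#' optional `dipole_debye`, `polarizability_au` (3x3, row-major),
#' `excitations` (array of objects with `ev` or `nm`, and `f`),
#' `atomic_charges`. Energies are converted to the canonical kcal/mol using
#' the `units` tag (`kcal/mol`, `hartree`, `kJ/mol`, `eV`); orbital energies
#' are always eV. Missing optional sections stay absent.
#'
#' @param path Path to the JSON file.
#' @return A `result_bundle`.
#' @export
read_bundle <- function(path) {
  if (!file.exists(path)) {
    stop("read_bundle(): file not found: ", path, call. = FALSE)
  }
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (key in c("label", "orbitals", "energies")) {
    if (is.null(x[[key]])) {
      stop("read_bundle(): missing required key '", key, "'", call. = FALSE)
    }
  }
  if (is.null(x$orbitals$energies_ev) || is.null(x$orbitals$occupations)) {
    stop("read_bundle(): missing key orbitals/energies_ev or orbitals/occupations",
         call. = FALSE)
  }
  if (!is.numeric(x$orbitals$energies_ev)) {
    stop("read_bundle(): non-numeric entry at orbitals/energies_ev",
         call. = FALSE)
  }
  orbitals <- orbital_spectrum(x$orbitals$energies_ev, x$orbitals$occupations)

  if (is.null(x$energies$total)) {
    stop("read_bundle(): missing key energies/total", call. = FALSE)
  }
  if (!is.numeric(x$energies$total)) {
    stop("read_bundle(): non-numeric entry at energies/total", call. = FALSE)
  }
  fac <- .energy_unit_factor(if (is.null(x$energies$units)) "kcal/mol" else x$energies$units)
  atoms <- if (is.null(x$energies$atoms)) NULL else x$energies$atoms * fac
  energies <- energy_record(x$energies$total * fac, atoms)

  geom <- NULL
  if (!is.null(x$geometry)) {
    g <- x$geometry
    geom <- geometry(g$elements, matrix(as.numeric(g$coords), ncol = 3),
                     charge = if (is.null(g$charge)) 0L else g$charge,
                     label = if (is.null(g$label)) "" else g$label)
  }

  electric <- NULL
  if (!is.null(x$dipole_debye) || !is.null(x$polarizability_au)) {
    pol <- if (is.null(x$polarizability_au)) NULL else
      matrix(as.numeric(x$polarizability_au), 3, 3, byrow = TRUE)
    dip <- if (is.null(x$dipole_debye)) c(0, 0, 0) else x$dipole_debye
    electric <- electric_tensors(dip, pol)
  }

  exc <- NULL
  if (!is.null(x$excitations) && NROW(x$excitations) > 0) {
    e <- as.data.frame(x$excitations)
    exc <- excitation_set(
      ev = if ("ev" %in% names(e)) e$ev else NULL,
      nm = if ("nm" %in% names(e)) e$nm else NULL,
      f  = e$f
    )
  }

  result_bundle(x$label, orbitals, energies, geom = geom, electric = electric,
                excitations = exc, atomic_charges = x$atomic_charges)
}

#' Write a result bundle to JSON
#'
#' Inverse of [read_bundle()]; always writes canonical units (eV orbitals,
#' kcal/mol energies), so a write/read round trip is the identity.
#'
#' @param bundle A `result_bundle`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "result_bundle"))
  out <- list(
    label = bundle$label,
    orbitals = list(energies_ev = bundle$orbitals$energies,
                    occupations = bundle$orbitals$occupations),
    energies = list(total = bundle$energies$total_energy, units = "kcal/mol")
  )
  if (!is.null(bundle$energies$atom_energies)) {
    out$energies$atoms <- bundle$energies$atom_energies
  }
  if (!is.null(bundle$geometry)) {
    out$geometry <- list(elements = bundle$geometry$elements,
                         coords = bundle$geometry$coords,
                         charge = bundle$geometry$charge,
                         label = bundle$geometry$label)
  }
  if (!is.null(bundle$electric)) {
    out$dipole_debye <- bundle$electric$dipole
    if (!is.null(bundle$electric$polarizability)) {
      out$polarizability_au <- bundle$electric$polarizability
    }
  }
  if (!is.null(bundle$excitations)) {
    out$excitations <- as.data.frame(unclass(bundle$excitations))
  }
  if (!is.null(bundle$atomic_charges)) {
    out$atomic_charges <- bundle$atomic_charges
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

# Atomic numbers for the supported element set (cube atom block).
.atomic_numbers <- c(H = 1, C = 6, N = 7, O = 8, Al = 13, Zn = 30)

#' Write a Gaussian cube volumetric file
#'
#' Conventional sign convention (positive atom count); origin and axes in
#' bohr (input grid spec in Angstrom is converted with 1.8897259886 bohr/A);
#' values in z-fastest order, six per line.
#'
#' @param values Numeric array with dim `c(nx, ny, nz)` matching `grid`.
#' @param grid A list with `origin` (length-3, Angstrom), `step` (length-3,
#'   Angstrom), and `n` (length-3 integer counts).
#' @param geom A `geometry`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(values, grid, geom, path) {
  stopifnot(inherits(geom, "geometry"))
  n <- as.integer(grid$n)
  if (!identical(dim(values), n)) {
    stop("write_cube(): values dim ", paste(dim(values), collapse = "x"),
         " does not match grid ", paste(n, collapse = "x"), call. = FALSE)
  }
  b <- physical_constants()$bohr_per_angstrom
  origin <- grid$origin * b
  step <- grid$step * b
  natom <- length(geom$elements)
  lines <- c(
    "fullersense cube file",
    "scalar field on regular grid",
    sprintf("%5d %11.6f %11.6f %11.6f", natom, origin[1], origin[2], origin[3]),
    sprintf("%5d %11.6f %11.6f %11.6f", n[1], step[1], 0, 0),
    sprintf("%5d %11.6f %11.6f %11.6f", n[2], 0, step[2], 0),
    sprintf("%5d %11.6f %11.6f %11.6f", n[3], 0, 0, step[3])
  )
  z <- .atomic_numbers[geom$elements]
  xyz_b <- geom$coords * b
  lines <- c(lines, sprintf("%5d %11.6f %11.6f %11.6f %11.6f",
                            z, z, xyz_b[, 1], xyz_b[, 2], xyz_b[, 3]))
  # z-fastest: for each (ix, iy), all iz in order
  flat <- aperm(values, c(3, 2, 1))  # now [iz, iy, ix]; loop ix slow
  v <- as.vector(flat[, , , drop = FALSE])
  # reorder: as.vector of [z,y,x] runs z fastest then y then x -> matches cube
  chunks <- split(v, ceiling(seq_along(v) / 6))
  lines <- c(lines, vapply(chunks, function(ch)
    paste(sprintf("%13.6e", ch), collapse = " "), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read back a Gaussian cube file written by [write_cube()]
#'
#' @param path Path to a cube file.
#' @return A list with `values` (array nx x ny x nz), `grid` (origin/step in
#'   Angstrom, counts), and `geom` (a `geometry`).
#' @export
read_cube <- function(path) {
  lines <- readLines(path, warn = FALSE)
  b <- physical_constants()$bohr_per_angstrom
  parse_row <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  hdr <- parse_row(lines[3])
  natom <- as.integer(hdr[1])
  origin <- hdr[2:4] / b
  ax <- lapply(4:6, function(i) parse_row(lines[i]))
  n <- vapply(ax, function(a) as.integer(a[1]), integer(1))
  step <- c(ax[[1]][2], ax[[2]][3], ax[[3]][4]) / b
  atom_rows <- lapply(7:(6 + natom), function(i) parse_row(lines[i]))
  zs <- vapply(atom_rows, function(a) a[1], numeric(1))
  el <- names(.atomic_numbers)[match(zs, .atomic_numbers)]
  coords <- t(vapply(atom_rows, function(a) a[3:5], numeric(3))) / b
  geom <- geometry(el, coords)
  vals <- unlist(lapply(lines[(7 + natom):length(lines)], parse_row),
                 use.names = FALSE)
  if (length(vals) != prod(n)) {
    stop("read_cube(): value count ", length(vals), " != grid size ", prod(n),
         call. = FALSE)
  }
  arr <- aperm(array(vals, dim = rev(n)), c(3, 2, 1))
  list(values = arr,
       grid = list(origin = origin, step = step, n = n),
       geom = geom)
}
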