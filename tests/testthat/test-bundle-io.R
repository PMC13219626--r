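# Data model and file formats: XYZ, JSON bundles, cube files, fixtures.

test_that("XYZ read/write round-trips and validates", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "hydrogen molecule",
               "H 0.0 0.0 0.0",
               "H 0.0 0.0 0.74"), path)
  g <- read_xyz(path)
  expect_s3_class(g, "geometry")
  expect_length(g$elements, 2)
  expect_equal(g$label, "hydrogen molecule")
  expect_equal(sqrt(sum((g$coords[1, ] - g$coords[2, ])^2)), 0.74)

  out <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(g, out)
  g2 <- read_xyz(out)
  expect_equal(g2$coords, g$coords, tolerance = 1e-6)
  expect_equal(g2$elements, g$elements)
  expect_equal(g2$label, g$label)
})

test_that("malformed XYZ files raise format errors naming the line", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "short file", "H 0 0 0", "H 0 0 0.74"), path)
  expect_error(read_xyz(path), "line 5")

  writeLines(c("2", "bad element", "H 0 0 0", "Xx 0 0 1"), path)
  expect_error(read_xyz(path), "unknown element.*line 4")

  writeLines(c("not-a-count", "x", "H 0 0 0"), path)
  expect_error(read_xyz(path), "line 1")
})

test_that("bundle JSON round-trips and canonicalizes units", {
  # minimal bundle: frontier pair only
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    label = "C60",
    orbitals = list(energies_ev = c(-5.25, -3.58), occupations = c(2, 0)),
    energies = list(total = -100, units = "kcal/mol")
  ), path, auto_unbox = TRUE)
  b <- read_bundle(path)
  fr <- frontier_orbitals(b$orbitals)
  expect_equal(unname(fr["homo"]), -5.25)
  expect_equal(unname(fr["lumo"]), -3.58)

  # hartree-tagged energies convert with the CODATA factor
  jsonlite::write_json(list(
    label = "x",
    orbitals = list(energies_ev = c(-5, -3), occupations = c(2, 0)),
    energies = list(total = -1, units = "hartree", atoms = c(-0.5, -0.25))
  ), path, auto_unbox = TRUE)
  b2 <- read_bundle(path)
  expect_equal(b2$energies$total_energy, -627.5094740631)
  expect_equal(b2$energies$atom_energies, c(-0.5, -0.25) * 627.5094740631)

  # full round trip; canonicalization is idempotent
  spec <- scenario_spec(seed = 7, noise_sd = 0.05)
  b3 <- make_pair(spec)$complex
  out <- withr::local_tempfile(fileext = ".json")
  write_bundle(b3, out)
  b4 <- read_bundle(out)
  expect_equal(b4$orbitals$energies, b3$orbitals$energies)
  expect_equal(b4$energies$total_energy, b3$energies$total_energy)
  expect_equal(b4$geometry$coords, b3$geometry$coords)
  expect_equal(b4$excitations$ev, b3$excitations$ev)
  out2 <- withr::local_tempfile(fileext = ".json")
  write_bundle(b4, out2)
  expect_identical(readLines(out), readLines(out2))
})

test_that("bundle schema errors name the offending key", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(label = "x",
                            energies = list(total = 1)), path,
                       auto_unbox = TRUE)
  expect_error(read_bundle(path), "orbitals")

  jsonlite::write_json(list(
    label = "x",
    orbitals = list(energies_ev = c(-5, -3), occupations = c(2, 0)),
    energies = list(total = 1, units = "furlongs")
  ), path, auto_unbox = TRUE)
  expect_error(read_bundle(path), "unknown energy unit.*furlongs")
})

test_that("cube files round-trip values, grid, and geometry", {
  g <- geometry(c("C", "N"), rbind(c(0, 0, 0), c(0, 0, 1.5)))
  grid <- list(origin = c(-1, -1, -1), step = c(0.5, 0.5, 0.5),
               n = c(3L, 4L, 5L))
  vals <- array(seq_len(60) / 7, dim = grid$n)
  path <- withr::local_tempfile(fileext = ".cube")
  write_cube(vals, grid, g, path)
  back <- read_cube(path)
  expect_equal(back$values, vals, tolerance = 1e-6)
  expect_equal(back$grid$origin, grid$origin, tolerance = 1e-6)
  expect_equal(back$grid$step, grid$step, tolerance = 1e-6)
  expect_equal(back$geom$elements, g$elements)
  expect_equal(back$geom$coords, g$coords, tolerance = 1e-5)

  # header axes are in bohr: third line origin = -1 Angstrom * 1.8897259886
  hdr <- strsplit(trimws(readLines(path)[3]), "\\s+")[[1]]
  expect_equal(as.numeric(hdr[2]), -1.8897259886, tolerance = 1e-6)

  expect_error(write_cube(array(0, c(2, 2, 2)), grid, g, path),
               "does not match grid")
})

test_that("excitation sets enforce the energy-wavelength identity", {
  e <- excitation_set(ev = 2.33, f = 0.1)
  expect_equal(e$nm, 1239.84193 / 2.33)
  e2 <- excitation_set(nm = 765, f = 0.1)
  expect_equal(e2$ev, 1239.84193 / 765)
  expect_error(excitation_set(ev = 2.0, nm = 700, f = 0.1), "E\\*lambda")
  expect_error(excitation_set(ev = 2.0, f = -0.1), "oscillator")
})

test_that("fixtures expose every printed table cell", {
  fx <- paper_fixtures()
  expect_named(fx$systems, c("C60", "AlC59", "ZnC59",
                             "C60@PCE", "AlC59@PCE", "ZnC59@PCE"))

  # reactivity table: 6 systems x 8 descriptor columns (ECT absent for sensors)
  expect_equal(dim(fx$reactivity_table), c(6, 9))
  expect_equal(sum(!is.na(fx$reactivity_table$ect)), 3)

  # sensing table: 3 pairs x 3 metrics, sigma for all six systems
  expect_equal(sum(!is.na(fx$sensing_table$eads)), 3)
  expect_equal(sum(!is.na(fx$sensing_table$tau)), 3)
  expect_equal(sum(!is.na(fx$sensing_table$sigma_1e9)), 6)

  # QTAIM table: 3 pairs x 5 quantities
  expect_equal(dim(fx$qtaim_table), c(3, 6))

  # spot values straight from the printed tables
  fr <- frontier_orbitals(fx$systems$ZnC59$orbitals)
  expect_equal(unname(fr), c(-4.45, -4.09))
  expect_equal(fx$sensing_table$eads[fx$sensing_table$system == "AlC59@PCE"],
               -54.08)
  t1 <- fx$geometry_table$bonds
  expect_equal(t1$length_angstrom[t1$structure == "C60" & t1$bond == "C11-C2"],
               1.40)
  expect_equal(unname(fx$charges$ZnC59["Zn"]), 0.545)
  expect_equal(nrow(fx$geometry_table$bonds), 33)
  expect_equal(nrow(fx$geometry_table$angles), 33)

  # energy anchors reproduce printed adsorption + cohesive energies
  eads <- adsorption_energy(fx$systems$`C60@PCE`$energies$total_energy,
                            fx$systems$C60$energies$total_energy,
                            fx$drug$energies$total_energy)
  expect_equal(eads, -11.15)
  coh <- cohesive_energy(fx$systems$C60$energies$total_energy,
                         fx$systems$C60$energies$atom_energies)
  expect_equal(coh, -197.3)
})
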