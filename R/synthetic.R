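# Reproducible synthetic sensor/analyte study sets. Every random draw flows
# from one explicit integer seed through a locally scoped Mersenne-Twister
# stream; the caller's global random state is saved and restored.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(expr)
}

#' Synthetic study scenario specification
#'
#' Defines the controllable knobs of one sensor/complex pair: frontier gaps
#' and chemical potentials (eV), adsorption energy (kcal/mol), excitation
#' lines, dimer separation (Angstrom), and orbital jitter (eV).
#'
#' @param seed Integer seed; identical seed gives identical output.
#' @param gap_sensor,gap_complex HOMO-LUMO gaps, eV (>= 0).
#' @param mu_sensor,mu_complex Chemical potentials, eV.
#' @param eads Adsorption energy, kcal/mol.
#' @param excitations_free,excitations_complex Data frames (or lists) with
#'   columns/elements `ev` and `f`.
#' @param separation Dimer separation, Angstrom.
#' @param noise_sd Gaussian jitter applied to filler orbitals, eV (>= 0).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(seed = 1L, gap_sensor = 1.67, gap_complex = 1.18,
                          mu_sensor = -4.415, mu_complex = -4.21,
                          eads = -11.15,
                          excitations_free = data.frame(ev = 2.37, f = 0.2),
                          excitations_complex = data.frame(ev = 1.61, f = 0.2),
                          separation = 2.8, noise_sd = 0) {
  if (gap_sensor < 0 || gap_complex < 0) {
    stop("scenario_spec(): gaps must be >= 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("scenario_spec(): noise_sd must be >= 0", call. = FALSE)
  if (separation <= 0) stop("scenario_spec(): separation must be > 0", call. = FALSE)
  structure(
    list(seed = as.integer(seed), gap_sensor = gap_sensor,
         gap_complex = gap_complex, mu_sensor = mu_sensor,
         mu_complex = mu_complex, eads = eads,
         excitations_free = as.data.frame(excitations_free),
         excitations_complex = as.data.frame(excitations_complex),
         separation = separation, noise_sd = noise_sd),
    class = "scenario_spec"
  )
}

#' Generate a synthetic sensor / complex / analyte bundle set
#'
#' Orbital spectra are constructed so the frontier pair reproduces
#' `mu +/- gap/2` exactly; eight filler orbitals are placed below the HOMO and
#' above the LUMO and jittered by `noise_sd`. Energy records are consistent
#' with the requested adsorption energy by construction
#' (`E_complex = E_sensor + E_drug + eads`). The complex geometry is a C-N
#' dimer at the stated separation.
#'
#' @param spec A `scenario_spec`.
#' @return A named list of `result_bundle`s: `sensor`, `complex`, `drug`.
#' @export
make_pair <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  .with_seed(spec$seed, {
    build_orbitals <- function(mu, gap, noise_sd) {
      homo <- mu - gap / 2
      lumo <- mu + gap / 2
      fill_occ <- homo - seq(1, 4)
      fill_vir <- lumo + seq(1, 4)
      if (noise_sd > 0) {
        fill_occ <- fill_occ - abs(rnorm(4, 0, noise_sd))
        fill_vir <- fill_vir + abs(rnorm(4, 0, noise_sd))
      }
      orbital_spectrum(c(fill_occ, homo, lumo, fill_vir),
                       c(rep(2, 5), rep(0, 5)))
    }
    e_sensor <- -12000
    e_drug <- -5000
    sensor <- result_bundle(
      "synthetic-sensor",
      build_orbitals(spec$mu_sensor, spec$gap_sensor, spec$noise_sd),
      energy_record(e_sensor),
      geom = geometry("C", matrix(0, 1, 3), label = "sensor site"),
      excitations = excitation_set(ev = spec$excitations_free$ev,
                                   f = spec$excitations_free$f)
    )
    complex <- result_bundle(
      "synthetic-complex",
      build_orbitals(spec$mu_complex, spec$gap_complex, spec$noise_sd),
      energy_record(e_sensor + e_drug + spec$eads),
      geom = geometry(c("C", "N"),
                      rbind(c(0, 0, 0), c(0, 0, spec$separation)),
                      label = "sensor@analyte contact dimer"),
      excitations = excitation_set(ev = spec$excitations_complex$ev,
                                   f = spec$excitations_complex$f)
    )
    drug <- result_bundle(
      "synthetic-drug",
      orbital_spectrum(c(-9, -1), c(2, 0)),
      energy_record(e_drug)
    )
    list(sensor = sensor, complex = complex, drug = drug)
  })
}

#' Deterministic grid of study scenarios
#'
#' `n` scenario specs spanning physisorption (eads in \[-15, -5\] kcal/mol)
#' and chemisorption (eads in \[-60, -30\]) regimes with gaps in 0.3-2.0 eV,
#' fully determined by the seed. Scenarios alternate between the two
#' adsorption regimes so any grid of n >= 2 contains both.
#'
#' @param n Number of scenarios (>= 1).
#' @param seed Integer seed.
#' @return A list of `scenario_spec`s.
#' @export
scenario_grid <- function(n, seed = 1L) {
  if (n < 1L) stop("scenario_grid(): n must be >= 1", call. = FALSE)
  .with_seed(seed, {
    lapply(seq_len(n), function(i) {
      physis <- i %% 2L == 1L
      eads <- if (physis) runif(1, -15, -5) else runif(1, -60, -30)
      gap_s <- runif(1, 0.3, 2.0)
      gap_c <- runif(1, 0.3, 2.0)
      scenario_spec(
        seed = seed + i,
        gap_sensor = gap_s, gap_complex = gap_c,
        mu_sensor = runif(1, -5, -3.5), mu_complex = runif(1, -5, -3.5),
        eads = eads,
        excitations_free = data.frame(ev = runif(1, 2.0, 3.0), f = 0.2),
        excitations_complex = data.frame(ev = runif(1, 1.2, 2.4), f = 0.2),
        separation = if (physis) runif(1, 2.4, 3.2) else runif(1, 1.2, 2.0),
        noise_sd = 0
      )
    })
  })
}
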