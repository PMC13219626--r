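# Study report assembly: orchestrates descriptors -> sensing -> spectra into
# per-study CSV tables mirroring the reference-table layouts, plus a JSON
# summary with unrounded values. Every number in the report is produced by one
# module operation; this layer only formats.

#' Study configuration
#'
#' @param temperature Temperature, K (> 0).
#' @param nu0 Attempt frequency, s^-1 (> 0).
#' @param sigma_mode Conductivity convention, `"physical"` or `"paper_compat"`.
#' @param fwhm_dos,fwhm_uv Broadening widths, eV (> 0).
#' @param tau_fast,tau_slow Regime thresholds, s (fast < slow).
#' @param out_dir Output directory for report files.
#' @return An object of class `study_config`.
#' @export
study_config <- function(temperature = 298, nu0 = 1e12,
                         sigma_mode = c("paper_compat", "physical"),
                         fwhm_dos = 0.3, fwhm_uv = 0.333,
                         tau_fast = 1, tau_slow = 1e6,
                         out_dir = tempfile("report")) {
  sigma_mode <- match.arg(sigma_mode)
  if (temperature <= 0) stop("study_config(): temperature must be > 0", call. = FALSE)
  if (nu0 <= 0) stop("study_config(): nu0 must be > 0", call. = FALSE)
  if (fwhm_dos <= 0 || fwhm_uv <= 0) {
    stop("study_config(): broadening widths must be > 0", call. = FALSE)
  }
  if (tau_fast >= tau_slow) {
    stop("study_config(): tau_fast must be < tau_slow", call. = FALSE)
  }
  structure(list(temperature = temperature, nu0 = nu0,
                 sigma_mode = sigma_mode, fwhm_dos = fwhm_dos,
                 fwhm_uv = fwhm_uv, tau_fast = tau_fast,
                 tau_slow = tau_slow, out_dir = out_dir),
            class = "study_config")
}

#' Assemble a full sensor/complex study report
#'
#' Runs the descriptor, sensing, and spectrum pipelines on one
#' sensor/complex/analyte bundle triple and writes: `reactivity.csv`
#' (descriptor-table layout, 2-decimal display), `sensing.csv` (Eads, tau,
#' sigma with the conductivity-mode note), `electric.csv` (dipole magnitude
#' and mean polarizability), `spectra.csv` (lambda_max, Eex, shift), and
#' `summary.json` with all unrounded values, the regime label, and the shift
#' report. Outputs are deterministic: identical inputs and config give
#' byte-identical CSV bodies.
#'
#' @param sensor,complex,drug `result_bundle`s.
#' @param config A `study_config`.
#' @return Invisibly, a list with the unrounded `summary` and the output
#'   `paths`. Partial outputs are removed on error.
#' @export
run_report <- function(sensor, complex, drug, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  for (b in list(sensor, complex, drug)) {
    if (!inherits(b, "result_bundle")) {
      stop("run_report(): all inputs must be result_bundles", call. = FALSE)
    }
  }
  if (is.null(sensor$excitations) || is.null(complex$excitations)) {
    stop("run_report(): sensor and complex bundles must carry excitations",
         call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir,
                     c("reactivity.csv", "sensing.csv", "electric.csv",
                       "spectra.csv", "summary.json"))
  names(paths) <- c("reactivity", "sensing", "electric", "spectra", "summary")
  on_fail <- function() unlink(paths[file.exists(paths)])

  tryCatch({
    ds <- reactivity_descriptors(sensor$orbitals)
    dc <- reactivity_descriptors(complex$orbitals)
    ct <- ect(ds, dc)
    react <- data.frame(
      system = c(sensor$label, complex$label),
      lumo = round(c(ds$e_lumo, dc$e_lumo), 2),
      homo = round(c(ds$e_homo, dc$e_homo), 2),
      hlg = round(c(ds$hlg, dc$hlg), 2),
      eta = round(c(ds$eta, dc$eta), 2),
      mu = round(c(ds$mu, dc$mu), 2),
      S = round(c(ds$softness, dc$softness), 2),
      dnmax = round(c(ds$dnmax, dc$dnmax), 2),
      ect = c(NA, round(ct$ect, 2))
    )
    utils::write.csv(react, paths["reactivity"], row.names = FALSE)

    sm <- sensing_metrics(sensor, complex, drug,
                          temperature = config$temperature, nu0 = config$nu0,
                          sigma_mode = config$sigma_mode,
                          tau_fast = config$tau_fast,
                          tau_slow = config$tau_slow)
    sens <- data.frame(
      system = c(sensor$label, complex$label),
      eads_kcal_mol = c(NA, round(sm$e_ads, 2)),
      tau_s = c(NA, sprintf("%.2e", sm$tau)),
      sigma_1e9_S_m = round(c(sm$sigma_free, sm$sigma_complex) / 1e9, 2),
      sigma_mode = config$sigma_mode
    )
    utils::write.csv(sens, paths["sensing"], row.names = FALSE)

    elec_row <- function(b) {
      if (is.null(b$electric)) return(c(NA_real_, NA_real_))
      c(dipole_magnitude(b$electric$dipole),
        if (is.null(b$electric$polarizability)) NA_real_
        else mean_polarizability(b$electric$polarizability))
    }
    es <- elec_row(sensor); ec <- elec_row(complex)
    elec <- data.frame(system = c(sensor$label, complex$label),
                       dipole_debye = round(c(es[1], ec[1]), 2),
                       polarizability_au = round(c(es[2], ec[2]), 2))
    utils::write.csv(elec, paths["electric"], row.names = FALSE)

    lam_free <- lambda_max(uvvis_curve(sensor$excitations, fwhm = config$fwhm_uv))
    lam_cpx <- lambda_max(uvvis_curve(complex$excitations, fwhm = config$fwhm_uv))
    sh <- shift_report(lam_free, lam_cpx)
    spct <- data.frame(system = c(sensor$label, complex$label),
                       lambda_max_nm = round(c(lam_free, lam_cpx), 1),
                       eex_ev = round(ev_nm(c(lam_free, lam_cpx)), 2),
                       delta_lambda_nm = c(NA, round(sh$delta_lambda, 1)),
                       direction = c(NA, sh$direction))
    utils::write.csv(spct, paths["spectra"], row.names = FALSE)

    summary <- list(
      sensor = sensor$label, complex = complex$label,
      descriptors_sensor = unclass(ds), descriptors_complex = unclass(dc),
      ect = unclass(ct),
      sensing = unclass(sm),
      dos_gap_sensor = dos_gap(sensor$orbitals, fwhm = config$fwhm_dos),
      dos_gap_complex = dos_gap(complex$orbitals, fwhm = config$fwhm_dos),
      shift = unclass(sh),
      config = unclass(config)
    )
    jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                         digits = NA)
    invisible(list(summary = summary, paths = paths))
  }, error = function(e) {
    on_fail()
    stop("run_report(): ", conditionMessage(e), call. = FALSE)
  })
}
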