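#!/usr/bin/env Rscript
# DOS gap readings and UV-Vis absorption maxima / complexation shifts for the
# six reference systems.
# Outputs: results/dos_gaps.csv, results/uvvis.csv

suppressPackageStartupMessages(library(fullersense))

fx <- paper_fixtures()

gaps <- do.call(rbind, lapply(names(fx$systems), function(sys) {
  orb <- fx$systems[[sys]]$orbitals
  fr <- frontier_orbitals(orb)
  data.frame(system = sys,
             frontier_gap = unname(fr["lumo"] - fr["homo"]),
             dos_gap = dos_gap(orb, fwhm = 0.3))
}))

uv <- do.call(rbind, lapply(names(fx$systems), function(sys) {
  b <- fx$systems[[sys]]
  lam <- lambda_max(uvvis_curve(b$excitations))
  data.frame(system = sys, lambda_max_nm = lam, eex_ev = ev_nm(lam),
             lambda_ref_nm = fx$uvvis_table$lambda_nm[
               fx$uvvis_table$system == sys])
}))
shifts <- do.call(rbind, lapply(c("C60", "AlC59", "ZnC59"), function(s) {
  lam_f <- uv$lambda_max_nm[uv$system == s]
  lam_c <- uv$lambda_max_nm[uv$system == paste0(s, "@PCE")]
  sh <- shift_report(lam_f, lam_c)
  data.frame(pair = paste0(s, "@PCE"), delta_lambda_nm = sh$delta_lambda,
             direction = sh$direction)
}))

dir.create("results", showWarnings = FALSE)
write.csv(gaps, "results/dos_gaps.csv", row.names = FALSE)
write.csv(merge(uv, shifts, by.x = "system", by.y = "pair", all.x = TRUE),
          "results/uvvis.csv", row.names = FALSE)
print(gaps, digits = 4)
print(shifts, digits = 4)
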