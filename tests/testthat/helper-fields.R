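# Shared helpers for topology tests: symmetric single-shell dimers with
# closed-form critical-point properties, and a finite-difference oracle.

# two identical single-shell atoms; c and zeta in a.u./bohr, separation in
# Angstrom. Single-shell model so the midpoint density has the closed form
# rho = 2 c exp(-d/(2 zeta)).
symmetric_dimer <- function(separation_ang = 2.0, c0 = 1.0, zeta = 0.6) {
  geom <- geometry(c("H", "H"),
                   rbind(c(0, 0, 0), c(0, 0, separation_ang)))
  model <- promolecular_model(list(H = list(c = c0, zeta = zeta)))
  list(geom = geom, model = model,
       field = promolecular_field(geom, model),
       c0 = c0, zeta = zeta,
       d_bohr = separation_ang * physical_constants()$bohr_per_angstrom)
}

# central-difference gradient and Hessian of the density at a point (bohr)
fd_derivatives <- function(field, point, h = 1e-4) {
  grad <- vapply(1:3, function(i) {
    e <- numeric(3); e[i] <- h
    (field(point + e)$rho - field(point - e)$rho) / (2 * h)
  }, numeric(1))
  hess <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      ei <- numeric(3); ei[i] <- h
      ej <- numeric(3); ej[j] <- h
      hess[i, j] <- (field(point + ei + ej)$rho - field(point + ei - ej)$rho -
                     field(point - ei + ej)$rho + field(point - ei - ej)$rho) /
                    (4 * h^2)
    }
  }
  list(grad = grad, hessian = hess)
}
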