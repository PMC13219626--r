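# Density topology: analytic derivatives, RDG/NCI, ELF/LOL, energy
# densities, bond critical point search, grid evaluation.

test_that("analytic gradient and Hessian match finite differences", {
  geom <- geometry(c("C", "N", "H"),
                   rbind(c(0, 0, 0), c(0, 0, 1.4), c(0.9, 0, -0.4)))
  field <- promolecular_field(geom)
  set.seed(17)
  for (rep in 1:8) {
    pt <- rnorm(3, sd = 1.5) + c(0, 0, 1.3)   # bohr, away from nuclei
    s <- field(pt)
    fd <- fd_derivatives(field, pt)
    expect_lt(max(abs(s$grad - fd$grad)), 1e-6)
    expect_lt(max(abs((s$hessian + t(s$hessian)) / 2 - fd$hessian)), 1e-5)
    expect_equal(s$laplacian, sum(diag(s$hessian)))
    expect_equal(sort(s$lambda), s$lambda)    # ascending
  }
})

test_that("single-shell fields obey the exponential closed forms", {
  dm <- symmetric_dimer(separation_ang = 2.0, c0 = 1.0, zeta = 0.6)
  # on the axis away from both nuclei: rho = sum of two exponentials and
  # |grad rho| of a single shell is rho_shell / zeta
  z <- 5.0  # bohr, beyond the second nucleus at d_bohr
  s <- dm$field(c(0, 0, z))
  r1 <- z; r2 <- z - dm$d_bohr
  rho_exact <- dm$c0 * (exp(-r1 / dm$zeta) + exp(-r2 / dm$zeta))
  expect_equal(s$rho, rho_exact, tolerance = 1e-12)
  expect_equal(sqrt(sum(s$grad^2)), rho_exact / dm$zeta, tolerance = 1e-12)

  # at a nucleus the density is the sum of shell coefficients plus the
  # partner tail
  s0 <- dm$field(c(0, 0, 0))
  expect_equal(s0$rho, dm$c0 * (1 + exp(-dm$d_bohr / dm$zeta)),
               tolerance = 1e-12)
})

test_that("reduced density gradient has the closed form and zeros", {
  # s = |grad| / (2 (3 pi^2)^{1/3} rho^{4/3})
  expect_equal(rdg(0.1, 0.2), 0.2 / (2 * (3 * pi^2)^(1 / 3) * 0.1^(4 / 3)))
  expect_equal(rdg(0.1, 0.2), 0.6964, tolerance = 1e-4)
  expect_equal(rdg(0.37, 0), 0)
  # RDG vanishes at the dimer midpoint (a stationary point by symmetry)
  dm <- symmetric_dimer()
  mid <- dm$field(c(0, 0, dm$d_bohr / 2))
  expect_lt(rdg(mid$rho, sqrt(sum(mid$grad^2))), 1e-10)
  expect_error(rdg(0, 1), "rho")
})

test_that("signed density classifies interaction character", {
  dm <- symmetric_dimer(separation_ang = 3.5)
  # weakly overlapping midpoint: low density, vdw bin
  mid <- dm$field(c(0, 0, dm$d_bohr / 2))
  sd_mid <- signed_density(mid)
  expect_equal(sd_mid$class, "vdw")
  expect_lt(abs(sd_mid$signed_rho), 0.01)

  # close to a nucleus off-axis: lambda2 < 0, dense -> attractive
  near <- dm$field(c(0.3, 0, 0))
  sd_near <- signed_density(near)
  expect_lt(near$lambda[2], 0)
  expect_equal(sd_near$class, "attractive")
  expect_equal(sd_near$signed_rho, -near$rho)

  # synthetic boundary: lambda2 exactly 0 -> signed rho 0 -> vdw
  fake <- list(rho = 0.5, grad = c(0, 0, 0), lambda = c(-1, 0, 1))
  expect_equal(signed_density(fake)$class, "vdw")
  expect_equal(signed_density(fake)$signed_rho, 0)
})

test_that("kinetic energy densities: TF value, Weizsaecker bound", {
  expect_equal(kinetic_density(1, mode = "tf"), 0.3 * (3 * pi^2)^(2 / 3))
  expect_equal(kinetic_density(1, mode = "tf"), 2.8712, tolerance = 1e-4)
  set.seed(23)
  for (rep in 1:10) {
    rho <- runif(1, 1e-3, 2); gn <- runif(1, 0, 1)
    expect_gte(kinetic_density(rho, gn, "tfw"), kinetic_density(rho, 0, "tf"))
  }
  expect_equal(kinetic_density(0.4, 0, "tfw"), kinetic_density(0.4, 0, "tf"))
  expect_error(kinetic_density(-1), "rho")
})

test_that("ELF hits its reference points and clamps negative D", {
  # homogeneous gas: tau = tau_TF, grad = 0 -> ELF = 1/2
  rho <- 0.8
  tau_tf <- kinetic_density(rho, mode = "tf")
  expect_equal(elf(rho, 0, tau_tf), 0.5)
  # pure Weizsaecker regime: D = 0 -> perfect localization, ELF = 1
  gn <- 0.3
  expect_equal(elf(rho, gn, gn^2 / (8 * rho)), 1)
  # D = 2 D_h -> 1/(1+4) = 0.2
  expect_equal(elf(rho, 0, 2 * tau_tf), 0.2)
  # negative Pauli term clamps to the localized limit with a warning
  expect_warning(v <- elf(rho, 1.0, 0.01), "clamped")
  expect_equal(v, 1)
})

test_that("LOL is bounded, 1/2 at the gas reference, monotone in tau", {
  rho <- 0.8
  tau_tf <- kinetic_density(rho, mode = "tf")
  expect_equal(lol(rho, tau_tf), 0.5)
  expect_equal(lol(rho, 3 * tau_tf), 0.25)
  taus <- tau_tf * c(0.25, 0.5, 1, 2, 4)
  vals <- vapply(taus, function(t) lol(rho, t), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0 & vals < 1))
  expect_error(lol(rho, 0), "tau")
})

test_that("energy densities satisfy the virial bookkeeping", {
  # uniform-gas point: g = tau_TF, v = -2 g, h = -g
  ed <- energy_densities(1, 0, 0)
  expect_equal(unname(ed["g"]), 2.871234, tolerance = 1e-5)
  expect_equal(unname(ed["v"]), -2 * ed[["g"]])
  expect_equal(unname(ed["h"]), -ed[["g"]])

  # weak-interaction point representative of a BCP
  ed2 <- energy_densities(0.016, 0, -0.011)
  expect_equal(unname(ed2["g"]), 0.0010837, tolerance = 1e-4)
  expect_equal(unname(ed2["v"]), -0.0049173, tolerance = 1e-4)
  expect_equal(unname(ed2["h"]), ed2[["g"]] + ed2[["v"]])

  # h = g + v is an identity for any admissible input
  set.seed(29)
  for (rep in 1:10) {
    rho <- runif(1, 1e-3, 1); gn <- runif(1, 0, 0.5); lap <- rnorm(1)
    ed3 <- energy_densities(rho, gn, lap)
    expect_equal(ed3[["h"]], ed3[["g"]] + ed3[["v"]])
    expect_equal(total_energy_density(ed3[["g"]], ed3[["v"]]), ed3[["h"]])
  }
})

test_that("BCP search finds the symmetric-dimer midpoint exactly", {
  dm <- symmetric_dimer(separation_ang = 2.0, c0 = 1.0, zeta = 0.6)
  bcps <- find_bcps(dm$field, dm$geom)
  expect_equal(nrow(bcps), 1)
  expect_lt(max(abs(c(bcps$x, bcps$y) - 0)), 1e-8)
  expect_equal(bcps$z, dm$d_bohr / 2, tolerance = 1e-8)
  # closed-form midpoint density 2 c exp(-d / (2 zeta))
  expect_equal(bcps$rho, 2 * dm$c0 * exp(-dm$d_bohr / (2 * dm$zeta)),
               tolerance = 1e-10)
  expect_equal(bcps$signature, -1L)
  expect_equal(bcps$rank, 3L)
  # axial symmetry: lambda1 = lambda2 < 0 < lambda3
  expect_equal(bcps$lambda1, bcps$lambda2, tolerance = 1e-8)
  expect_lt(bcps$lambda2, 0)
  expect_gt(bcps$lambda3, 0)
  expect_equal(bcps$h, bcps$g + bcps$v)
})

test_that("BCP search is translation invariant and empty for one atom", {
  dm <- symmetric_dimer()
  shift <- c(1.3, -0.7, 2.1)   # Angstrom
  geom2 <- geometry(dm$geom$elements, sweep(dm$geom$coords, 2, -shift))
  field2 <- promolecular_field(geom2, dm$model)
  b1 <- find_bcps(dm$field, dm$geom)
  b2 <- find_bcps(field2, geom2)
  bohr <- physical_constants()$bohr_per_angstrom
  expect_equal(c(b2$x, b2$y, b2$z),
               c(b1$x, b1$y, b1$z) + shift * bohr, tolerance = 1e-8)
  expect_equal(b2$rho, b1$rho, tolerance = 1e-10)

  single <- geometry("H", matrix(c(0, 0, 0), 1))
  fs <- promolecular_field(single, dm$model)
  expect_equal(nrow(find_bcps(fs, single)), 0)
})

test_that("BCP energy densities reproduce the printed contact rows", {
  fx <- paper_fixtures()
  q <- fx$qtaim_table
  # VIR (total energy density) is the exact sum of the printed G and V
  expect_equal(q$vir, q$g + q$v, tolerance = 1e-9)
  expect_equal(q$vir, c(0.009, 0.124, 0.074), tolerance = 1e-9)
  # density at the contact orders Al > Zn > C60
  ord <- q$rho[match(c("AlC59@PCE", "ZnC59@PCE", "C60@PCE"), q$system)]
  expect_equal(ord, c(0.080, 0.056, 0.016))
  expect_true(all(diff(ord) < 0))
})

test_that("grid evaluation agrees with pointwise field calls", {
  dm <- symmetric_dimer(separation_ang = 2.0)
  grid <- list(origin = c(-0.4, -0.4, 0.2), step = c(0.4, 0.4, 0.4),
               n = c(3L, 3L, 5L))
  out <- evaluate_grid(dm$field, dm$geom,
                       c("rho", "rdg", "elf", "lol", "laplacian"),
                       grid = grid)
  expect_true(all(out$rho > 0))
  expect_true(all(out$elf >= 0 & out$elf <= 1))
  expect_true(all(out$lol > 0 & out$lol < 1))
  bohr <- physical_constants()$bohr_per_angstrom
  # spot check one voxel against a direct field call
  pt_ang <- grid$origin + grid$step * (c(2, 3, 4) - 1)
  s <- dm$field(pt_ang * bohr)
  expect_equal(out$rho[2, 3, 4], s$rho)
  expect_equal(out$laplacian[2, 3, 4], s$laplacian)
  gn <- sqrt(sum(s$grad^2))
  expect_equal(out$rdg[2, 3, 4], rdg(s$rho, gn))

  expect_error(evaluate_grid(dm$field, dm$geom, character(0)), "empty")
  expect_error(evaluate_grid(dm$field, dm$geom, "banana"), "unknown")
  bad <- grid; bad$step <- c(0, 0.1, 0.1)
  expect_error(evaluate_grid(dm$field, dm$geom, "rho", grid = bad),
               "positive")
})
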