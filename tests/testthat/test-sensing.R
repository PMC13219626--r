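# Adsorption/sensing metrics: cohesive and adsorption energies, recovery
# time, conductivity, electric moments, regime classification.

test_that("cohesive energy is the per-atom binding residual", {
  expect_equal(cohesive_energy(-10, c(-2, -1, -1)), -2.0)
  expect_equal(cohesive_energy(-4, c(-2, -1, -1)), 0)
  # inversion: constructing a 60-atom total from a target per-atom value
  atoms <- rep(-170, 60)
  total <- sum(atoms) + 60 * (-197.3)
  expect_equal(cohesive_energy(total, atoms), -197.3)
  expect_error(cohesive_energy(-10, numeric(0)), "non-empty")
})

test_that("adsorption energy is the complex-minus-fragments difference", {
  expect_equal(adsorption_energy(-500, -480, -8.85), -11.15)
  expect_equal(adsorption_energy(-488.85, -480, -8.85), 0)
  # metamorphic: shifting all inputs by c changes the result by -c
  set.seed(3)
  for (rep in 1:10) {
    e <- runif(3, -1000, 0); cc <- runif(1, -50, 50)
    expect_equal(adsorption_energy(e[1] + cc, e[2] + cc, e[3] + cc),
                 adsorption_energy(e[1], e[2], e[3]) - cc)
  }
})

test_that("recovery times reproduce the printed table values", {
  expect_equal(recovery_time(0, 298, 1e12), 1e-12)
  expect_equal(recovery_time(-54.08), 4.57e27, tolerance = 0.02)
  expect_equal(recovery_time(-32.78), 1.09e12, tolerance = 0.02)
  expect_equal(recovery_time(-11.15), 1.54e-4, tolerance = 0.05)
  expect_error(recovery_time(-10, temperature = -1), "temperature")
  expect_error(recovery_time(-10, nu0 = 0), "nu0")
})

test_that("recovery time is monotone in binding strength and temperature", {
  eads <- seq(-60, -5, by = 5)
  taus <- vapply(eads, recovery_time, numeric(1))
  expect_true(all(diff(taus) < 0))  # weaker binding -> shorter tau
  temps <- seq(250, 400, by = 25)
  taus_t <- vapply(temps, function(t) recovery_time(-30, t), numeric(1))
  expect_true(all(diff(taus_t) < 0))
})

test_that("conductivity reproduces the printed table only in compat mode", {
  sigma_ref <- c(2.20, 2.43, 2.87, 2.43, 2.48, 2.89)
  gaps <- c(1.67, 1.18, 0.36, 1.18, 1.08, 0.32)
  got <- vapply(gaps, function(g)
    conductivity(g, mode = "paper_compat"), numeric(1)) / 1e9
  expect_equal(got, sigma_ref, tolerance = 0.01)

  # the dimensionally consistent reading is orders of magnitude away
  phys <- conductivity(1.67, mode = "physical")
  expect_lt(phys, 1)           # ~2e-5 S/m, nowhere near 2.2e9
  expect_gt(sigma_ref[1] * 1e9 / phys, 1e10)

  # zero gap: A T^{3/2} in both modes
  expect_equal(conductivity(0), 6e5 * 298^1.5)
  expect_equal(conductivity(0, mode = "paper_compat"), 6e5 * 298^1.5)

  # monotone decreasing in the gap in both modes
  for (m in c("physical", "paper_compat")) {
    s <- vapply(seq(0, 2, 0.25), function(g)
      conductivity(g, mode = m), numeric(1))
    expect_true(all(diff(s) < 0))
  }
  expect_error(conductivity(-1), "hlg")
})

test_that("dipole magnitude is the rotation-invariant Euclidean norm", {
  expect_equal(dipole_magnitude(c(0, 0, 0)), 0)
  expect_equal(dipole_magnitude(c(3, 4, 0)), 5)
  set.seed(11)
  for (rep in 1:10) {
    v <- rnorm(3)
    q <- qr.Q(qr(matrix(rnorm(9), 3)))   # random orthogonal matrix
    expect_equal(dipole_magnitude(q %*% v), dipole_magnitude(v))
  }
})

test_that("mean polarizability is trace/3 and rotation invariant", {
  expect_equal(mean_polarizability(diag(c(3, 3, 3))), 3)
  expect_equal(mean_polarizability(diag(c(1, 2, 3))), 2)
  set.seed(13)
  a <- crossprod(matrix(rnorm(9), 3))
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(mean_polarizability(q %*% a %*% t(q)), mean_polarizability(a))
  asym <- diag(3); asym[1, 2] <- 1e-3
  expect_error(mean_polarizability(asym), "symmetric")
})

test_that("regime classification separates sensor from adsorbent behavior", {
  expect_equal(classify_regime(-11.15, 1.5e-4), "reversible-sensor")
  expect_equal(classify_regime(-54.08, 4.57e27), "adsorbent")
  expect_equal(classify_regime(-20, 10), "intermediate")
  expect_error(classify_regime(-20, 10, tau_fast = 10, tau_slow = 1),
               "tau_fast")
})

test_that("fixture pairs rank and classify as the study concludes", {
  fx <- paper_fixtures()
  pairs <- c("C60@PCE", "ZnC59@PCE", "AlC59@PCE")
  eads <- fx$sensing_table$eads[match(pairs, fx$sensing_table$system)]
  taus <- vapply(eads, recovery_time, numeric(1))
  # |Eads| and tau both increase C60@PCE < ZnC59@PCE < AlC59@PCE
  expect_true(all(diff(abs(eads)) > 0))
  expect_true(all(diff(taus) > 0))
  regimes <- mapply(classify_regime, eads, taus)
  names(regimes) <- pairs
  expect_equal(unname(regimes[c("C60@PCE", "AlC59@PCE")]),
               c("reversible-sensor", "adsorbent"))
  expect_true(regimes[["ZnC59@PCE"]] %in% c("intermediate", "adsorbent"))
})

test_that("sensing_metrics aggregates the pair-level pipeline", {
  fx <- paper_fixtures()
  m <- sensing_metrics(fx$systems$C60, fx$systems$`C60@PCE`, fx$drug,
                       sigma_mode = "paper_compat")
  expect_equal(m$e_ads, -11.15)
  expect_equal(m$tau, 1.54e-4, tolerance = 0.05)
  expect_equal(m$sigma_free / 1e9, 2.20, tolerance = 0.01)
  expect_equal(m$sigma_complex / 1e9, 2.43, tolerance = 0.01)
  expect_equal(m$regime, "reversible-sensor")
})
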