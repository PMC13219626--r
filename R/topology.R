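# Real-space electron-density analysis on analytic promolecular model
# densities: field evaluation with closed-form derivatives, reduced density
# gradient / NCI classification, ELF and LOL localization indicators, Newton
# search for bond critical points, and Abramov/local-virial energy densities.
# All internal coordinates are bohr; all field quantities atomic units.

# Per-element shell parameters (coefficient in a.u., decay length in bohr)
# for rho_elem(r) = sum_i c_i * exp(-r / zeta_i). The hydrogen shell is the
# standard single-exponential promolecular H density; heavier elements use
# two-exponential core+valence fits of the implementer's choosing. Topology
# results asserted in the tests depend only on the functional form, not on
# these specific parameter values.
.promolecular_shells <- list(
  H  = list(c = 0.2815,            zeta = 0.5288),
  C  = list(c = c(35.0, 1.00),     zeta = c(0.20, 0.60)),
  N  = list(c = c(50.0, 1.40),     zeta = c(0.18, 0.55)),
  O  = list(c = c(70.0, 1.80),     zeta = c(0.16, 0.50)),
  Al = list(c = c(150.0, 0.80),    zeta = c(0.14, 0.90)),
  Zn = list(c = c(400.0, 1.20),    zeta = c(0.10, 0.75))
)

#' Promolecular shell model
#'
#' @param shells Optional named list of per-element `list(c =, zeta =)` shell
#'   parameters replacing or extending the built-in table (coefficients in
#'   a.u., decay lengths in bohr; all positive).
#' @return An object of class `promolecular_model`.
#' @export
promolecular_model <- function(shells = NULL) {
  tab <- .promolecular_shells
  if (!is.null(shells)) tab[names(shells)] <- shells
  for (el in names(tab)) {
    if (any(tab[[el]]$c <= 0) || any(tab[[el]]$zeta <= 0)) {
      stop("promolecular_model(): coefficients and decay lengths must be > 0 (",
           el, ")", call. = FALSE)
    }
  }
  structure(list(shells = tab), class = "promolecular_model")
}

#' Promolecular density field evaluator
#'
#' Builds an evaluator for the promolecular electron density of a geometry:
#' the sum of spherical per-atom shell densities. The evaluator returns the
#' density, its analytic gradient and Hessian (no numerical differentiation),
#' the Laplacian, and the ordered Hessian eigenvalues at any point.
#'
#' @param geom A `geometry` (coordinates in Angstrom; converted to bohr
#'   internally).
#' @param model A `promolecular_model` (default: built-in table).
#' @return A function `f(point_bohr)` returning a `field_sample`: list with
#'   `position` (bohr), `rho`, `grad` (length 3), `hessian` (3x3),
#'   `laplacian`, `lambda` (eigenvalues ascending), all in a.u.
#' @export
promolecular_field <- function(geom, model = promolecular_model()) {
  stopifnot(inherits(geom, "geometry"), inherits(model, "promolecular_model"))
  bad <- setdiff(unique(geom$elements), names(model$shells))
  if (length(bad) > 0L) {
    stop("promolecular_field(): element(s) not in model: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  centers <- geom$coords * physical_constants()$bohr_per_angstrom
  shells <- model$shells[geom$elements]

  function(point) {
    point <- as.numeric(point)
    rho <- 0
    grad <- c(0, 0, 0)
    hess <- matrix(0, 3, 3)
    for (a in seq_len(nrow(centers))) {
      d <- point - centers[a, ]
      r <- sqrt(sum(d^2))
      cs <- shells[[a]]$c
      zs <- shells[[a]]$zeta
      f <- cs * exp(-r / zs)          # shell values
      fp <- -f / zs                   # d rho / d r
      fpp <- f / zs^2                 # d2 rho / d r2
      rho <- rho + sum(f)
      if (r > 1e-12) {
        u <- d / r
        grad <- grad + sum(fp) * u
        # H = f'' u u^T + (f'/r) (I - u u^T)
        uu <- tcrossprod(u)
        hess <- hess + sum(fpp) * uu + (sum(fp) / r) * (diag(3) - uu)
      }
      # at the nucleus the spherical density has a cusp; gradient/Hessian of
      # the exponential are not defined there and the zero contribution is the
      # symmetric limit
    }
    lam <- sort(eigen((hess + t(hess)) / 2, symmetric = TRUE,
                      only.values = TRUE)$values)
    list(position = point, rho = rho, grad = grad, hessian = hess,
         laplacian = sum(diag(hess)), lambda = lam)
  }
}

#' Reduced density gradient
#'
#' `s = |grad rho| / (2 (3 pi^2)^{1/3} rho^{4/3})`, the dimensionless gradient
#' used in NCI analysis; low s at low rho marks noncovalent interactions.
#'
#' @param rho Electron density, a.u. (> 0).
#' @param grad_norm Gradient magnitude, a.u. (>= 0).
#' @return s, dimensionless.
#' @export
rdg <- function(rho, grad_norm) {
  if (any(rho <= 0)) stop("rdg(): rho must be > 0", call. = FALSE)
  grad_norm / (2 * (3 * pi^2)^(1 / 3) * rho^(4 / 3))
}

#' Density signed by the middle Hessian eigenvalue
#'
#' NCI sign convention: `sign(lambda_2) * rho` with lambda_2 the middle of the
#' ordered Hessian eigenvalues. Classification: `attractive` when the signed
#' density is below `-rho_cut`, `repulsive` above `+rho_cut`, `vdw` otherwise.
#'
#' @param sample A `field_sample` from a [promolecular_field()] evaluator.
#' @param rho_cut Classification threshold in a.u. (default 0.01).
#' @return A list with `rho`, `s` (reduced density gradient), `signed_rho`,
#'   and `class`.
#' @export
signed_density <- function(sample, rho_cut = 0.01) {
  lam2 <- sample$lambda[2]
  signed <- sign(lam2) * sample$rho
  cls <- if (signed < -rho_cut) "attractive"
    else if (signed > rho_cut) "repulsive"
    else "vdw"
  list(rho = sample$rho, s = rdg(sample$rho, sqrt(sum(sample$grad^2))),
       signed_rho = signed, class = cls)
}

# Thomas-Fermi kinetic energy density prefactor (3/10)(3 pi^2)^{2/3}
.c_tf <- function() 0.3 * (3 * pi^2)^(2 / 3)

#' Approximate kinetic energy density
#'
#' Thomas-Fermi estimate `tau_TF = (3/10)(3 pi^2)^{2/3} rho^{5/3}`, optionally
#' plus the Weizsaecker gradient correction `|grad rho|^2 / (8 rho)` (`tfw`).
#'
#' @param rho Density, a.u. (> 0).
#' @param grad_norm Gradient magnitude, a.u. (used by `tfw`).
#' @param mode `"tf"` or `"tfw"`.
#' @return Kinetic energy density, a.u. (positive).
#' @export
kinetic_density <- function(rho, grad_norm = 0, mode = c("tf", "tfw")) {
  mode <- match.arg(mode)
  if (any(rho <= 0)) stop("kinetic_density(): rho must be > 0", call. = FALSE)
  tf <- .c_tf() * rho^(5 / 3)
  if (mode == "tf") tf else tf + grad_norm^2 / (8 * rho)
}

#' Electron localization function (ELF)
#'
#' Becke-Edgecombe form `ELF = 1 / (1 + (D/D_h)^2)` with the Pauli kinetic
#' energy density `D = tau - |grad rho|^2/(8 rho)` and the homogeneous-gas
#' reference `D_h = tau_TF`. Negative D (possible with approximate tau) is
#' clamped to 0 with a warning, giving the perfect-localization limit 1.
#'
#' @param rho Density, a.u. (> 0).
#' @param grad_norm Gradient magnitude, a.u.
#' @param tau Kinetic energy density, a.u.
#' @return ELF in \[0, 1\]; 0.5 at the homogeneous-gas reference.
#' @export
elf <- function(rho, grad_norm, tau) {
  if (any(rho <= 0)) stop("elf(): rho must be > 0", call. = FALSE)
  d <- tau - grad_norm^2 / (8 * rho)
  if (any(d < 0)) {
    warning("elf(): negative Pauli kinetic energy clamped to 0")
    d <- pmax(d, 0)
  }
  dh <- .c_tf() * rho^(5 / 3)
  1 / (1 + (d / dh)^2)
}

#' Localized orbital locator (LOL)
#'
#' Schmider-Becke form `nu = t / (1 + t)` with `t = tau_TF / tau`; bounded in
#' (0, 1), 0.5 at the homogeneous-gas reference, monotone decreasing in tau.
#'
#' @param rho Density, a.u. (> 0).
#' @param tau Kinetic energy density, a.u. (> 0).
#' @return LOL in (0, 1).
#' @export
lol <- function(rho, tau) {
  if (any(rho <= 0)) stop("lol(): rho must be > 0", call. = FALSE)
  if (any(tau <= 0)) stop("lol(): tau must be > 0", call. = FALSE)
  t <- (.c_tf() * rho^(5 / 3)) / tau
  t / (1 + t)
}

#' Abramov kinetic, potential, and total energy densities
#'
#' Kinetic energy density from the Abramov estimate
#' `g = (3/10)(3 pi^2)^{2/3} rho^{5/3} + |grad rho|^2/(72 rho) + lap/6`,
#' potential energy density from the local virial relation
#' `v = lap/4 - 2 g`, and total `h = g + v` (exact identity).
#'
#' @param rho Density, a.u. (> 0).
#' @param grad_norm Gradient magnitude, a.u.
#' @param laplacian Laplacian of the density, a.u.
#' @return Named numeric vector `c(g = , v = , h = )` in a.u.
#' @export
energy_densities <- function(rho, grad_norm, laplacian) {
  if (any(rho <= 0)) stop("energy_densities(): rho must be > 0", call. = FALSE)
  g <- .c_tf() * rho^(5 / 3) + grad_norm^2 / (72 * rho) + laplacian / 6
  v <- laplacian / 4 - 2 * g
  c(g = g, v = v, h = g + v)
}

#' Total electronic energy density
#'
#' `H = G + V`, the sum of kinetic and potential energy densities at a point
#' (the quantity tabulated as "VIR" in the reference table).
#'
#' @param g Kinetic energy density, a.u.
#' @param v Potential energy density, a.u.
#' @return H in a.u.
#' @export
total_energy_density <- function(g, v) g + v

#' Find bond critical points of a promolecular field
#'
#' Newton iterations on `grad rho = 0`, seeded at the midpoint of every atom
#' pair closer than `seed_cutoff` Angstrom. Steps are damped by 0.5 when the
#' step norm exceeds 0.5 bohr; convergence at `|grad rho| < 1e-8` a.u. within
#' 100 iterations (non-converging or singular-Hessian seeds are skipped).
#' Converged points are deduplicated at 1e-3 bohr and only saddle points of
#' signature (3, -1) are returned, with the Abramov/virial energy densities
#' attached.
#'
#' @param field A field evaluator from [promolecular_field()].
#' @param geom The `geometry` the field was built from (>= 2 atoms).
#' @param seed_cutoff Atom-pair distance cutoff in Angstrom (default 4.0).
#' @return A data.frame with one row per BCP: `x`, `y`, `z` (bohr), `rho`,
#'   `laplacian`, `lambda1..3`, `g`, `v`, `h`, `rank`, `signature`.
#' @export
find_bcps <- function(field, geom, seed_cutoff = 4.0) {
  stopifnot(inherits(geom, "geometry"))
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      rho = numeric(0), laplacian = numeric(0),
                      lambda1 = numeric(0), lambda2 = numeric(0),
                      lambda3 = numeric(0), g = numeric(0), v = numeric(0),
                      h = numeric(0), rank = integer(0),
                      signature = integer(0))
  n <- nrow(geom$coords)
  if (n < 2L) return(empty)
  b <- physical_constants()$bohr_per_angstrom
  centers <- geom$coords * b
  seeds <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((geom$coords[i, ] - geom$coords[j, ])^2)) <= seed_cutoff) {
        seeds[[length(seeds) + 1L]] <- (centers[i, ] + centers[j, ]) / 2
      }
    }
  }
  found <- list()
  for (seed in seeds) {
    x <- seed
    converged <- FALSE
    for (it in seq_len(100)) {
      s <- field(x)
      gn <- sqrt(sum(s$grad^2))
      if (gn < 1e-8) { converged <- TRUE; break }
      H <- (s$hessian + t(s$hessian)) / 2
      step <- tryCatch(-solve(H, s$grad), error = function(e) NULL)
      if (is.null(step)) break                 # singular Hessian: skip seed
      if (sqrt(sum(step^2)) > 0.5) step <- step * 0.5
      x <- x + step
    }
    if (!converged) next
    dup <- any(vapply(found, function(p)
      sqrt(sum((p$position - x)^2)) < 1e-3, logical(1)))
    if (dup) next
    s <- field(x)
    sig <- sum(sign(s$lambda))
    rank <- sum(abs(s$lambda) > 1e-10)
    if (rank == 3L && sig == -1) {
      ed <- energy_densities(s$rho, sqrt(sum(s$grad^2)), s$laplacian)
      found[[length(found) + 1L]] <- list(position = x, sample = s, ed = ed,
                                          rank = rank, sig = sig)
    }
  }
  if (length(found) == 0L) return(empty)
  do.call(rbind, lapply(found, function(p) {
    data.frame(x = p$position[1], y = p$position[2], z = p$position[3],
               rho = p$sample$rho, laplacian = p$sample$laplacian,
               lambda1 = p$sample$lambda[1], lambda2 = p$sample$lambda[2],
               lambda3 = p$sample$lambda[3],
               g = p$ed[["g"]], v = p$ed[["v"]], h = p$ed[["h"]],
               rank = p$rank, signature = p$sig)
  }))
}

#' Evaluate field quantities on a regular grid
#'
#' @param field A field evaluator from [promolecular_field()].
#' @param geom The `geometry` (used for the default grid box).
#' @param quantities Subset of `c("rho", "rdg", "signed_rho", "elf", "lol",
#'   "laplacian")`.
#' @param grid Optional list `(origin, step, n)` in Angstrom; default is the
#'   geometry bounding box padded 2.5 Angstrom at step 0.1 Angstrom.
#' @param tau_mode Kinetic-energy mode for ELF/LOL (`"tfw"` default: Thomas-
#'   Fermi plus Weizsaecker; the resulting ELF/LOL are approximate, as exact
#'   orbital kinetic energy is not available for a promolecular field).
#' @return A list with `grid` (the spec used) and one numeric array per
#'   requested quantity.
#' @export
evaluate_grid <- function(field, geom, quantities, grid = NULL,
                          tau_mode = c("tfw", "tf")) {
  tau_mode <- match.arg(tau_mode)
  allowed <- c("rho", "rdg", "signed_rho", "elf", "lol", "laplacian")
  if (length(quantities) == 0L) {
    stop("evaluate_grid(): empty quantity set", call. = FALSE)
  }
  bad <- setdiff(quantities, allowed)
  if (length(bad) > 0L) {
    stop("evaluate_grid(): unknown quantities: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(grid)) {
    lo <- apply(geom$coords, 2, min) - 2.5
    hi <- apply(geom$coords, 2, max) + 2.5
    step <- rep(0.1, 3)
    n <- as.integer(floor((hi - lo) / step)) + 1L
    grid <- list(origin = lo, step = step, n = n)
  }
  if (any(grid$step <= 0)) {
    stop("evaluate_grid(): grid steps must be positive", call. = FALSE)
  }
  b <- physical_constants()$bohr_per_angstrom
  n <- as.integer(grid$n)
  arrays <- lapply(quantities, function(q) array(NA_real_, dim = n))
  names(arrays) <- quantities
  for (ix in seq_len(n[1])) {
    for (iy in seq_len(n[2])) {
      for (iz in seq_len(n[3])) {
        pt_ang <- grid$origin + grid$step * (c(ix, iy, iz) - 1)
        s <- field(pt_ang * b)
        gn <- sqrt(sum(s$grad^2))
        for (q in quantities) {
          arrays[[q]][ix, iy, iz] <- switch(q,
            rho = s$rho,
            rdg = rdg(s$rho, gn),
            signed_rho = signed_density(s)$signed_rho,
            laplacian = s$laplacian,
            elf = suppressWarnings(
              elf(s$rho, gn, kinetic_density(s$rho, gn, tau_mode))),
            lol = lol(s$rho, kinetic_density(s$rho, gn, tau_mode))
          )
        }
      }
    }
  }
  c(list(grid = grid), arrays)
}
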