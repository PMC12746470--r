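# the built-in RHF engine behind the adapter contract

test_that("external potential matrix: analytic single-Gaussian oracle", {
  # one H-like center, one normalized s primitive with exponent zeta:
  # <s|-Z/r|s> = -Z * 2 sqrt(2 zeta / pi); cross-checked by radial quadrature
  zeta <- 1.3; Z <- 2
  sh <- list(list(l = 0L, exps = zeta, coefs = 1, center = c(0, 0, 0),
                  atom = 1L))
  attr(sh, "M") <- 1L
  V <- rdmlearn:::cpp_potential(sh, Z, matrix(0, 1, 3))
  expect_equal(V[1, 1], -Z * 2 * sqrt(2 * zeta / pi), tolerance = 1e-12)
  quad <- stats::integrate(function(r)
    (2 * zeta / pi)^1.5 * exp(-2 * zeta * r^2) * 4 * pi * r, 0, Inf)$value
  expect_equal(V[1, 1], -Z * quad, tolerance = 1e-9)
})

test_that("external potential is linear in the nuclear charges", {
  g <- builtin_molecule("water"); m <- m_sto3g()
  sh <- basis_shells(g, m$basis)
  bohr <- g$positions / 0.529177210903
  V1 <- rdmlearn:::cpp_potential(sh, as.numeric(g$Z), bohr)
  V2 <- rdmlearn:::cpp_potential(sh, as.numeric(2 * g$Z), bohr)
  expect_equal(V2, 2 * V1, tolerance = 1e-13)
  expect_true(all(diag(V1) < 0))
})

test_that("well-separated fragments decouple in the potential matrix", {
  m <- m_sto3g()
  h2 <- geometry(c("H", "H"), rbind(c(0, 0, 0), c(0.74, 0, 0)))
  far <- geometry(c("H", "H", "H", "H"),
                  rbind(c(0, 0, 0), c(0.74, 0, 0),
                        c(1000, 0, 0), c(1000.74, 0, 0)))
  Viso <- external_potential_matrix(h2, m)$values
  Vfar <- external_potential_matrix(far, m)$values
  Siso <- overlap_matrix(h2, m)$values
  blk <- Vfar[1:2, 1:2]
  # monopole tail of the distant fragment, expanded about the exact charge
  # centroid of each orbital product (from the dipole integrals); the
  # remaining quadrupole error is O(1/d^3) ~ 1e-12
  b <- 1 / 0.529177210903
  sh <- basis_shells(h2, m$basis)
  DX <- rdmlearn:::cpp_dipole(sh)$x                  # bohr
  tail <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    centroid <- DX[i, j] / Siso[i, j]                # bohr, on the x axis
    for (xc in c(1000, 1000.74))
      tail[i, j] <- tail[i, j] - Siso[i, j] / (xc * b - centroid)
  }
  expect_lt(max(abs(blk - Viso - tail)), 1e-8)
  expect_lt(max(abs(Vfar[1:2, 3:4])), 1e-10)
})

test_that("SCF reproduces frozen reference energies and invariants", {
  m <- m_sto3g()
  # H2 at R = 1.4 bohr: the classic closed-form-checkable case
  h2 <- geometry(c("H", "H"),
                 rbind(c(0, 0, 0), c(0, 0, 1.4 * 0.529177210903)))
  s <- run_scf(h2, m)
  expect_true(s$converged)
  expect_equal(s$energy, -1.116714, tolerance = 2e-6)   # frozen oracle value
  g <- builtin_molecule("water")
  sw <- run_scf(g, m)
  expect_equal(sw$energy, -74.96302, tolerance = 2e-5)  # frozen oracle value
  expect_equal(sum(sw$gamma$values * sw$overlap$values), 10, tolerance = 1e-8)
  P <- sw$gamma$values; S <- sw$overlap$values
  expect_lt(norm(P %*% S %*% P - 2 * P, "F"), 1e-7)     # idempotency
  Fm <- sw$fock$values
  expect_lt(norm(Fm %*% P %*% S - S %*% P %*% Fm, "F"), 1e-6)  # stationarity
  expect_equal(energy_from_dm(sw$gamma, g, m), sw$energy, tolerance = 1e-9)
  s631 <- run_scf(g, m_631g())
  expect_equal(s631$energy, -75.98397, tolerance = 5e-5) # frozen oracle value
})

test_that("fock_build matches SCF orbital energies and responds to perturbations", {
  m <- m_sto3g(); g <- water_eq()
  s <- run_scf(g, m)
  f <- fock_build(s$gamma, g, m)
  eps <- rdmlearn:::generalized_eigvals(f$values, s$overlap$values)
  expect_equal(eps, s$orbital_energies, tolerance = 1e-7)
  # monotone growth of ||f - f_conv|| under growing density perturbation
  dev <- vapply(c(0.001, 0.004, 0.016), function(eta) {
    P <- s$gamma$values
    D <- random_symmetric(nrow(P), 7) * eta
    Ppert <- purify(P + D, s$overlap, 10)
    norm(fock_build(Ppert, g, m)$values - f$values, "F")
  }, 0)
  expect_true(all(diff(dev) > 0))
  expect_error(fock_build(ao_matrix(2 * s$gamma$values), g, m), "electron count")
})

test_that("energy_from_dm is variational above the SCF minimum", {
  m <- m_sto3g(); g <- water_eq()
  s <- run_scf(g, m)
  set.seed(12)
  above <- vapply(1:20, function(i) {
    D <- random_symmetric(7, i) * 0.02
    P <- purify(s$gamma$values + D, s$overlap, 10)
    energy_from_dm(P, g, m) >= s$energy - 1e-10
  }, TRUE)
  expect_gte(mean(above), 0.95)
  expect_error(energy_from_dm(ao_matrix(s$gamma$values * 1.2), g, m),
               "electron count")
})

test_that("analytic forces: engine self-consistency, sum rule, stationarity", {
  m <- m_sto3g()
  g <- builtin_molecule("water")   # displaced from the HF minimum
  s <- run_scf(g, m)
  Fa <- scf_forces(s)
  expect_lt(max(abs(colSums(Fa))), 1e-6)
  # central-difference oracle on one O and one H component
  h <- 1e-4
  for (idx in list(c(1, 3), c(2, 2))) {
    pp <- g$positions; pp[idx[1], idx[2]] <- pp[idx[1], idx[2]] + h
    pm <- g$positions; pm[idx[1], idx[2]] <- pm[idx[1], idx[2]] - h
    fd <- -(run_scf(geometry(Z = g$Z, positions = pp), m)$energy -
              run_scf(geometry(Z = g$Z, positions = pm), m)$energy) / (2 * h)
    expect_equal(Fa[idx[1], idx[2]], fd, tolerance = 1e-6)
  }
  expect_lt(max(abs(scf_forces(run_scf(water_eq(), m)))), 1e-4)
})

test_that("nuclear attraction derivatives agree with finite differences", {
  m <- m_sto3g(); g <- builtin_molecule("water")
  dv <- nuclear_attraction_derivatives(g, m)
  h <- 1e-4
  dims <- c("x", "y", "z")
  for (i in c(1, 3)) for (d in c(1, 3)) {
    pp <- g$positions; pp[i, d] <- pp[i, d] + h
    pm <- g$positions; pm[i, d] <- pm[i, d] - h
    fd <- (external_potential_matrix(geometry(Z = g$Z, positions = pp), m)$values -
             external_potential_matrix(geometry(Z = g$Z, positions = pm), m)$values) /
      (2 * h)
    expect_lt(max(abs(fd - dv[[i]][[dims[d]]])), 1e-6)
  }
  # rigid translation: total derivative of v-hat vanishes
  tot <- dv[[1]]$x + dv[[2]]$x + dv[[3]]$x
  gshift <- g; gshift$positions <- g$positions + matrix(rep(c(h, 0, 0), each = 3), 3)
  fd_tot <- (external_potential_matrix(gshift, m)$values -
               external_potential_matrix(g, m)$values) / h
  expect_lt(max(abs(tot - fd_tot)), 1e-5)
})

test_that("one-electron properties: dipole symmetry, kinetic positivity and spectral form", {
  m <- m_sto3g()
  h2 <- geometry(c("H", "H"), rbind(c(0, 0, -0.37), c(0, 0, 0.37)))
  s <- run_scf(h2, m)
  expect_equal(one_electron_property(s$gamma, "dipole", h2, m),
               c(0, 0, 0), tolerance = 1e-10)
  g <- water_eq(); sw <- run_scf(g, m)
  ke <- one_electron_property(sw$gamma, "kinetic", g, m)
  expect_gt(ke, 0)
  # spectral cross-check: Tr[gamma T] = sum_i n_i <phi_i|T|phi_i>
  no <- natural_orbitals(sw$gamma, sw$overlap)
  ctx <- rdmlearn:::engine_context(g, m)
  spect <- sum(vapply(seq_along(no$occupations), function(i)
    no$occupations[i] * drop(t(no$orbitals[, i]) %*% ctx$T %*% no$orbitals[, i]),
    0))
  expect_equal(ke, spect, tolerance = 1e-9)
  expect_error(one_electron_property(sw$gamma, "overlap", g, m))
})

test_that("normal modes: counts, orthonormality, minimum verification", {
  modes <- water_modes()
  expect_equal(modes$n_vib, 3)
  Gm <- t(modes$modes) %*% modes$modes
  expect_lt(max(abs(Gm - diag(3))), 1e-8)
  expect_true(all(modes$frequencies_cm1 > 0))
  # linear molecule: 3N - 5
  m <- m_sto3g()
  co2 <- optimize_geometry(builtin_molecule("co2"), m)$geometry
  mco2 <- hessian_normal_modes(co2, m)
  expect_equal(mco2$n_vib, 4)
  # refuses an unrelaxed geometry
  expect_error(hessian_normal_modes(builtin_molecule("water"), m),
               "not a relaxed minimum")
})

test_that("method_spec enforces the configuration contract", {
  expect_error(method_spec("B3LYP", "STO-3G"), "configuration error")
  expect_error(method_spec("HF", "STO-3G", scf_convergence = 1e-5), "1e-6")
  expect_error(basis_shells(builtin_molecule("water"), "cc-pVTZ"),
               "configuration error")
  expect_equal(basis_dimension(builtin_molecule("water"), "STO-3G"), 7L)
  expect_equal(basis_dimension(builtin_molecule("water"), "6-31G"), 13L)
})

test_that("engine determinism: identical inputs give bit-identical results", {
  m <- m_sto3g(); g <- builtin_molecule("water")
  s1 <- run_scf(g, m); s2 <- run_scf(g, m)
  expect_identical(s1$energy, s2$energy)
  expect_identical(s1$gamma$values, s2$gamma$values)
  expect_identical(scf_forces(s1), scf_forces(s2))
})
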