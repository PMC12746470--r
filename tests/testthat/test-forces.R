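# HOMO-LUMO gaps, the co-diagonal Fock operator, gradients of the predicted
# 1-RDM, and the force correction for nonvariational densities

test_that("HOMO-LUMO gap matches the engine at a converged density", {
  m <- m_sto3g(); g <- water_eq()
  s <- run_scf(g, m)
  gap_engine <- s$orbital_energies[6] - s$orbital_energies[5]
  expect_equal(homo_lumo_gap(s$gamma, g, m), gap_engine, tolerance = 1e-7)
  expect_equal(homo_lumo_gap(s$gamma, g, m, units = "eV"),
               gap_engine * 27.211386245988, tolerance = 1e-5)
  # rotational invariance through the full frame machinery
  R <- rot_z(54)
  grot <- g; grot$positions <- g$positions %*% t(R)
  tr <- structure(list(rotation = R, translation = c(0, 0, 0),
                       center = c(0, 0, 0)), class = "frame_transform")
  gam_rot <- rotate_ao_matrix(s$gamma, tr, basis_shells(g, m$basis))
  expect_equal(homo_lumo_gap(gam_rot, grot, m), gap_engine, tolerance = 1e-6)
})

test_that("ML gap tracks the reference along an O-H stretch and degrades outward", {
  gm <- water_model(); m <- m_sto3g()
  eq <- water_eq()
  stack <- model_stack(gm)
  deltas <- c(-0.05, 0, 0.05, 0.15, 0.3, 0.5)   # angstrom along one O-H
  bond <- eq$positions[2, ] - eq$positions[1, ]
  u <- bond / sqrt(sum(bond^2))
  errs <- numeric(length(deltas)); gaps_ref <- errs; gaps_ml <- errs
  for (i in seq_along(deltas)) {
    gi <- eq
    gi$positions[2, ] <- eq$positions[2, ] + deltas[i] * u
    sref <- run_scf(gi, m)
    gaps_ref[i] <- sref$orbital_energies[6] - sref$orbital_energies[5]
    pf <- predict_full(stack, gi)
    gaps_ml[i] <- homo_lumo_gap(pf$gamma, gi, m)
    errs[i] <- abs(gaps_ml[i] - gaps_ref[i])
  }
  # inside the thermally sampled span the gap is recovered well
  expect_lt(max(errs[1:3]), 5e-3)
  # graceful degradation: error grows with distance from the training span
  expect_gt(suppressWarnings(stats::cor(errs, abs(deltas),
                                        method = "spearman")), 0)
})

test_that("fock_prime: 2x2 hand case, construction property, variational limit", {
  # orthonormal 2-level toy: natural orbitals = coordinate axes
  f <- rbind(c(-1, 0.2), c(0.2, 1))
  gamma <- diag(c(2, 0))
  fp <- fock_prime(f, gamma, diag(2))
  expect_equal(fp$values, diag(c(-1, 1)), tolerance = 1e-12)
  df <- f - fp$values
  expect_equal(df, rbind(c(0, 0.2), c(0.2, 0)), tolerance = 1e-12)
  # delta f vanishes in the occupied and virtual blocks of gamma's NOs
  m <- m_sto3g(); g <- water_eq()
  s <- run_scf(g, m)
  noisy <- purify(s$gamma$values + random_symmetric(7, 5) * 0.04,
                  s$overlap, 10)
  Fm <- fock_build(noisy, g, m)
  fpn <- fock_prime(Fm, noisy, s$overlap)
  no <- natural_orbitals(noisy, s$overlap)
  dmo <- t(no$orbitals) %*% (Fm$values - fpn$values) %*% no$orbitals
  expect_lt(max(abs(dmo[1:5, 1:5])), 1e-9)
  expect_lt(max(abs(dmo[6:7, 6:7])), 1e-9)
  expect_lt(max(abs(diag(dmo))), 1e-10)
  # converged gamma: f' = f
  fpc <- fock_prime(s$fock, s$gamma, s$overlap)
  expect_lt(norm(s$fock$values - fpc$values, "F"), 1e-6)
})

test_that("grad_gamma_ml: analytic and FD modes agree on the raw prediction", {
  gm <- water_model()
  gd <- sample_normal_mode_geometries(water_eq(), water_modes(),
                                      sampler_config(300, 1, seed = 55))[[1]]
  gan <- grad_gamma_ml(gm, gd, mode = "analytic", what = "raw")
  gfd <- grad_gamma_ml(gm, gd, mode = "fd", what = "raw", step = 1e-3)
  dev <- 0
  for (i in 1:3) for (d in c("x", "y", "z"))
    dev <- max(dev, max(abs(gan[[i]][[d]] - gfd[[i]][[d]])))
  expect_lt(dev, 1e-5)
  expect_error(grad_gamma_ml(gm, gd, mode = "analytic", what = "purified"),
               "raw")
})

test_that("grad_gamma_ml passes the secant test between nearby geometries", {
  gm <- water_model()
  eq <- water_eq()
  g1 <- eq
  set.seed(9)
  dirn <- matrix(rnorm(9), 3); dirn <- dirn / sqrt(sum(dirn^2))
  h <- 0.02
  g2 <- eq; g2$positions <- eq$positions + h * dirn
  pred <- function(g) {
    al <- align_to_reference(g, gm$ref)
    v <- pack_symmetric(external_potential_matrix(al$geometry, gm$method))
    raw <- predict_gamma(gm, v)
    pur <- purify(raw, overlap_matrix(al$geometry, gm$method), 10)
    rotate_ao_matrix(pur, invert_transform(al$transform),
                     basis_shells(g, gm$method$basis))$values
  }
  secant <- pred(g2) - pred(g1)
  gg <- grad_gamma_ml(gm, g1, mode = "fd", what = "purified")
  lin <- matrix(0, 7, 7)
  dims <- c("x", "y", "z")
  for (i in 1:3) for (d in 1:3)
    lin <- lin + gg[[i]][[dims[d]]] * h * dirn[i, d]
  expect_lt(max(abs(secant - lin)), 0.1 * max(abs(secant)))
})

test_that("force modes: variational limit and engine agreement at training points", {
  gm <- water_model(); m <- m_sto3g()
  stack <- model_stack(gm)
  ts <- water_ts()
  gtr <- ts$geometries[[5]]
  F_ref <- scf_forces(run_scf(gtr, m))
  F_cor <- compute_forces("corrected", stack, gtr)
  F_hf <- compute_forces("hellmann_feynman", stack, gtr)
  # at an interpolated (converged) prediction both modes reduce to the
  # engine's analytic forces
  expect_lt(max(abs(F_cor - F_ref)), 1e-6)
  expect_lt(max(abs(F_hf - F_ref)), 1e-5)
  # translational sum rule for the Hellmann-Feynman mode
  expect_lt(max(abs(colSums(F_hf))), 1e-6)
})

test_that("corrected forces are energy-consistent; uncorrected are not", {
  # sparse model so the nonvariational error is visible
  eq <- water_eq(); modes <- water_modes(); m <- m_sto3g()
  ts <- make_training_set(eq, modes, sampler_config(300, 6, seed = 3), m)
  stack <- model_stack(fit_gamma(ts, kernel_spec("RBF", alpha = 0)))
  gd <- sample_normal_mode_geometries(eq, modes,
                                      sampler_config(500, 3, seed = 77))[[2]]
  F_cor <- compute_forces("corrected", stack, gd)
  F_hf <- compute_forces("hellmann_feynman", stack, gd)
  h <- 1e-3
  dev_c <- 0; dev_h <- 0
  for (i in 1:3) for (d in 1:3) {
    pp <- gd$positions; pp[i, d] <- pp[i, d] + h
    pm <- gd$positions; pm[i, d] <- pm[i, d] - h
    gp <- gd; gp$positions <- pp
    gmm <- gd; gmm$positions <- pm
    f_fd <- -(predict_full(stack, gp)$energy -
                predict_full(stack, gmm)$energy) / (2 * h)
    dev_c <- max(dev_c, abs(F_cor[i, d] - f_fd))
    dev_h <- max(dev_h, abs(F_hf[i, d] - f_fd))
  }
  expect_lt(dev_c, 1e-4)
  expect_lt(dev_c, dev_h / 10)
})

test_that("the nonvariational residual delta-f vanishes as gamma converges", {
  # scan gamma = purify((1 - t) gamma_pred + t gamma_scf): the occupied-
  # virtual Fock coupling (the correction's driver) goes to zero at t = 1,
  # monotonically within tolerance, and so does its force contribution
  # Tr[delta f  dgamma/dR]
  eq <- water_eq(); modes <- water_modes(); m <- m_sto3g()
  ts <- make_training_set(eq, modes, sampler_config(300, 6, seed = 3), m)
  stack <- model_stack(fit_gamma(ts, kernel_spec("RBF", alpha = 0)))
  gd <- sample_normal_mode_geometries(eq, modes,
                                      sampler_config(400, 2, seed = 13))[[1]]
  s <- run_scf(gd, m)
  al <- align_to_reference(gd, stack$gamma$ref)
  v <- pack_symmetric(external_potential_matrix(al$geometry, m))
  raw <- predict_gamma(stack$gamma, v)
  pur_pred <- rotate_ao_matrix(
    purify(raw, overlap_matrix(al$geometry, m), 10),
    invert_transform(al$transform), basis_shells(gd, m$basis))
  gg <- grad_gamma_ml(stack$gamma, gd, mode = "fd", what = "purified")
  res <- vapply(c(0, 0.5, 1), function(t) {
    mix <- purify((1 - t) * pur_pred$values + t * s$gamma$values,
                  s$overlap, 10)
    Fm <- fock_build(mix, gd, m)
    df <- Fm$values - fock_prime(Fm, mix, s$overlap)$values
    corr <- max(vapply(1:3, function(i) max(vapply(c("x", "y", "z"),
      function(d) abs(sum(df * gg[[i]][[d]])), 0)), 0))
    c(norm(df, "F"), corr)
  }, numeric(2))
  expect_lt(res[1, 3], 1e-7)              # delta f -> 0 at convergence
  expect_lt(res[2, 3], 1e-7)              # its force contribution too
  expect_true(all(diff(res[1, ]) < 1e-12))  # monotone decay along the scan
  # and at a converged *prediction* (training point) the corrected forces
  # coincide with the engine's analytic forces
  gtr <- ts$geometries[[2]]
  F_ref2 <- scf_forces(run_scf(gtr, m))
  F_cor2 <- compute_forces("corrected", stack, gtr)
  expect_lt(max(abs(F_cor2 - F_ref2)), 1e-6)
})
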