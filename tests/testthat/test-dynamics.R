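# velocity-Verlet NVE machinery and diagnostics

test_that("Maxwell-Boltzmann initialization: zero-T, momentum, equipartition", {
  g <- builtin_molecule("water")
  expect_equal(maxwell_boltzmann_velocities(g, 0, 1), matrix(0, 3, 3))
  v <- maxwell_boltzmann_velocities(g, 300, 3)
  expect_lt(max(abs(colSums(v * g$masses))), 1e-12)
  # Monte-Carlo equipartition: mean KE = (3N - 3)/2 k_B T after momentum removal
  kes <- vapply(1:10000, function(s)
    rdmlearn:::kinetic_energy(maxwell_boltzmann_velocities(g, 300, s),
                              g$masses), 0)
  target <- (3 * 3 - 3) / 2 * 3.166811563e-6 * 300
  expect_equal(mean(kes), target, tolerance = 0.02)
})

test_that("velocity Verlet: harmonic oscillator energy envelope and order", {
  # 1-D oscillator: one particle, unit-ish parameters in MD units
  g1 <- geometry("He", matrix(c(1, 0, 0), 1))
  prov <- harmonic_provider(k = 1)
  run_err <- function(dt, n) {
    traj <- run_nve(g1, matrix(0, 1, 3), prov, dt, n)
    e <- rdmlearn:::total_energies(traj)
    max(abs(e - e[1]))
  }
  # omega = sqrt(k MD_ACC / m); period ~ 2 pi / omega
  omega <- sqrt(1 * rdmlearn:::MD_ACC / 4.002603254)
  period <- 2 * pi / omega
  dt <- period / 100
  err1 <- run_err(dt, 10000)
  # bounded oscillatory error, no secular drift over 10^4 steps
  e_tot0 <- 0.5 * 1 * 1^2  # (Ha-consistent within provider units)
  expect_lt(err1, 5e-3 * e_tot0)
  # halving dt shrinks the energy-error amplitude ~4x (second order)
  err2 <- run_err(dt / 2, 20000)
  expect_equal(err1 / err2, 4, tolerance = 0.25)
})

test_that("zero forces give uniform linear motion", {
  g1 <- geometry("He", matrix(0, 1, 3))
  prov <- structure(function(g) list(energy = 0, forces = matrix(0, 1, 3)),
                    label = "free")
  v0 <- matrix(c(0.01, -0.02, 0.005), 1)
  traj <- run_nve(g1, v0, prov, 1, 50)
  fin <- traj$states[[51]]
  expect_equal(fin$positions, v0 * 50, tolerance = 1e-12)
  expect_equal(fin$velocities, v0, tolerance = 1e-14)
})

test_that("integrator is exactly time-reversible for exact forces", {
  g1 <- geometry("He", matrix(c(0.7, 0, 0), 1))
  prov <- harmonic_provider(1)
  fw <- run_nve(g1, matrix(c(0, 0.01, 0), 1), prov, 0.5, 10)
  last <- fw$states[[11]]
  bk <- run_nve(geometry("He", last$positions), -last$velocities, prov, 0.5, 10)
  fin <- bk$states[[11]]
  expect_lt(max(abs(fin$positions - g1$positions)), 1e-10)
  # engine-driven water round trip (SCF noise limits this to ~1e-6)
  m <- m_sto3g(); eq <- water_eq()
  v0 <- maxwell_boltzmann_velocities(eq, 300, 7)
  fw2 <- run_nve(eq, v0, engine_force_provider(m), 0.5, 10)
  l2 <- fw2$states[[11]]
  bk2 <- run_nve(rdmlearn:::with_positions(eq, l2$positions), -l2$velocities,
                 engine_force_provider(m), 0.5, 10)
  expect_lt(max(abs(bk2$states[[11]]$positions - eq$positions)), 1e-6)
})

test_that("engine NVE on water conserves energy over 0.1 ps", {
  m <- m_sto3g(); eq <- water_eq()
  v0 <- maxwell_boltzmann_velocities(eq, 300, 11)
  traj <- run_nve(eq, v0, engine_force_provider(m), 0.5, 200)
  dr <- energy_drift(traj)
  expect_lt(dr$max_dev_ha, 1e-4)
  expect_lt(abs(dr$slope_ha_per_ps), 1e-4)
})

test_that("trajectory determinism and error truncation", {
  m <- m_sto3g(); eq <- water_eq()
  v0 <- maxwell_boltzmann_velocities(eq, 300, 4)
  t1 <- run_nve(eq, v0, engine_force_provider(m), 0.5, 5)
  t2 <- run_nve(eq, v0, engine_force_provider(m), 0.5, 5)
  expect_identical(t1$states[[6]]$positions, t2$states[[6]]$positions)
  # provider failure -> truncated trajectory with diagnostic
  flaky <- local({
    count <- 0
    structure(function(g) {
      count <<- count + 1
      if (count > 3) stop("boom")
      list(energy = 0, forces = matrix(0, 3, 3))
    }, label = "flaky")
  })
  tr <- run_nve(eq, v0 * 0, flaky, 0.5, 10)
  expect_lt(length(tr$states), 11)
  expect_match(attr(tr, "error"), "frame 3")
})

test_that("decoherence RMSD: zero cases and threshold crossing", {
  m <- m_sto3g(); eq <- water_eq()
  v0 <- maxwell_boltzmann_velocities(eq, 300, 4)
  a <- run_nve(eq, v0, engine_force_provider(m), 0.5, 5)
  expect_equal(decoherence_rmsd(a, a), rep(0, 6), tolerance = 1e-12)
  # frame-by-frame rigid rotation is invisible after superposition
  b <- a
  R <- rot_z(25)
  b$states <- lapply(a$states, function(s) {
    s$positions <- s$positions %*% t(R); s
  })
  expect_lt(max(decoherence_rmsd(a, b)), 1e-10)
  expect_equal(first_passage(c(0, 0.05, 0.2, 0.4), 0.1), 3)
  expect_identical(first_passage(c(0, 0.01), 0.1), Inf)
  bad <- a; bad$states <- bad$states[1:3]
  bad$states[[2]]$time <- 99
  expect_error(decoherence_rmsd(a, bad), "time-grid")
})

test_that("energy_drift on constructed trajectories", {
  mk <- function(e_series) {
    structure(list(states = lapply(seq_along(e_series), function(i)
      list(time = (i - 1) * 500, epot = e_series[i], ekin = 0,
           positions = matrix(0, 1, 3))),
      dt_fs = 500, provider = "synthetic"), class = "trajectory")
  }
  flat <- mk(rep(-5, 4))
  expect_equal(energy_drift(flat)$slope_ha_per_ps, 0)
  expect_equal(energy_drift(flat)$max_dev_ha, 0)
  # linear ramp of 1e-3 Ha over 1 ps -> slope exactly 1e-3 Ha/ps
  ramp <- mk(-5 + 5e-4 * (0:2))  # frames at 0, 0.5, 1.0 ps
  expect_equal(energy_drift(ramp)$slope_ha_per_ps, 1e-3, tolerance = 1e-9)
  expect_error(energy_drift(mk(-5)), "2 frames")
})
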