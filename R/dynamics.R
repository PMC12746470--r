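# NVE molecular dynamics: velocity-Verlet integration driven by any force
# provider (reference engine or surrogate model stack), Maxwell-Boltzmann
# initialization, and stability/decoherence diagnostics.
# Units: positions angstrom, velocities angstrom/fs, masses amu, energies Ha.

#' Maxwell-Boltzmann initial velocities
#'
#' Per-component normal draws with variance `k_B T / m_I`, followed by removal
#' of the net linear momentum. Seeded and reproducible.
#'
#' @param g a [geometry()].
#' @param temperature target temperature (K).
#' @param seed RNG seed.
#' @return n x 3 velocity matrix (angstrom/fs).
#' @export
maxwell_boltzmann_velocities <- function(g, temperature, seed = 1L) {
  if (temperature < 0) stop("temperature must be >= 0")
  n <- length(g$Z)
  set.seed(seed)
  if (temperature == 0) return(matrix(0, n, 3))
  # sigma_v^2 = k_B T / m  in (angstrom/fs)^2: k_B T [Ha] * MD_ACC / m [amu]
  sig <- sqrt(KB_HARTREE * temperature * MD_ACC / g$masses)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sig
  ptot <- colSums(v * g$masses)
  sweep(v, 2, ptot / sum(g$masses))
}

kinetic_energy <- function(v, masses) {
  0.5 * sum(masses * rowSums(v^2)) / MD_ACC
}

md_state <- function(positions, velocities, masses, time, epot, forces) {
  list(positions = positions, velocities = velocities, masses = masses,
       time = time, epot = epot, ekin = kinetic_energy(velocities, masses),
       forces = forces)
}

#' Engine-driven force provider
#'
#' Wraps the SCF engine as a `function(geometry) -> list(energy, forces)` for
#' [run_nve()]; reuses the previous density as the SCF guess along a
#' trajectory.
#'
#' @param method a [method_spec()].
#' @return force-provider closure with attribute `label = "engine"`.
#' @export
engine_force_provider <- function(method) {
  last_gamma <- NULL
  f <- function(g) {
    s <- run_scf(g, method, guess = last_gamma)
    if (!s$converged) stop("SCF failure in force provider")
    last_gamma <<- s$gamma
    list(energy = s$energy, forces = scf_forces(s))
  }
  attr(f, "label") <- "engine"
  f
}

#' Surrogate-model force provider
#'
#' @param stack a [model_stack()].
#' @param force_mode `"corrected"`, `"hellmann_feynman"` or `"delta_learned"`.
#' @return force-provider closure with a descriptive label attribute.
#' @export
ml_force_provider <- function(stack,
                              force_mode = c("corrected", "hellmann_feynman",
                                             "delta_learned")) {
  force_mode <- match.arg(force_mode)
  f <- function(g) {
    if (force_mode == "delta_learned") {
      pf <- predict_full(stack, g, want_forces = TRUE)
      list(energy = pf$energy, forces = pf$forces)
    } else {
      pf <- predict_full(stack, g, want_forces = TRUE,
                         force_mode = force_mode)
      list(energy = pf$energy, forces = pf$forces)
    }
  }
  attr(f, "label") <- paste0("ml_", force_mode)
  f
}

#' One velocity-Verlet step
#'
#' Standard two-half-kick update; exactly time-reversible for deterministic
#' forces.
#'
#' @param state an MD state (see [run_nve()]).
#' @param force_provider `function(geometry) -> list(energy, forces)`.
#' @param dt_fs time step (fs).
#' @param template geometry carrying Z/masses for rebuilding geometries.
#' @return updated state.
#' @export
velocity_verlet_step <- function(state, force_provider, dt_fs, template) {
  if (dt_fs <= 0) stop("dt must be positive")
  m <- state$masses
  a0 <- state$forces / m * MD_ACC                     # angstrom/fs^2
  newpos <- state$positions + state$velocities * dt_fs + 0.5 * a0 * dt_fs^2
  ev <- force_provider(with_positions(template, newpos))
  a1 <- ev$forces / m * MD_ACC
  newvel <- state$velocities + 0.5 * (a0 + a1) * dt_fs
  md_state(newpos, newvel, m, state$time + dt_fs, ev$energy, ev$forces)
}

#' Run NVE molecular dynamics
#'
#' @param g initial [geometry()].
#' @param velocities initial n x 3 velocities (angstrom/fs), e.g. from
#'   [maxwell_boltzmann_velocities()].
#' @param force_provider force provider closure.
#' @param dt_fs time step (fs; 0.5 fs is the standard protocol).
#' @param n_steps number of steps.
#' @return a `trajectory`: `states` (list of MD states incl. the initial
#'   frame), `dt_fs`, `provider` label. On provider failure the truncated
#'   trajectory is returned with attribute `error`.
#' @export
run_nve <- function(g, velocities, force_provider, dt_fs, n_steps) {
  ev <- force_provider(g)
  st <- md_state(g$positions, velocities, g$masses, 0, ev$energy, ev$forces)
  states <- vector("list", n_steps + 1L)
  states[[1]] <- st
  err <- NULL
  for (k in seq_len(n_steps)) {
    st <- tryCatch(velocity_verlet_step(st, force_provider, dt_fs, g),
                   error = function(e) e)
    if (inherits(st, "error")) {
      err <- paste0("provider failure at frame ", k, ": ",
                    conditionMessage(st))
      states <- states[seq_len(k)]
      break
    }
    states[[k + 1L]] <- st
  }
  structure(list(states = states[!vapply(states, is.null, TRUE)],
                 dt_fs = dt_fs,
                 provider = attr(force_provider, "label") %||% "custom",
                 geometry = g),
            class = "trajectory", error = err)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trajectory <- function(x, ...) {
  et <- total_energies(x)
  cat("<trajectory> ", length(x$states), " frames, dt = ", x$dt_fs,
      " fs, provider = ", x$provider,
      ", max |dE| = ", format(max(abs(et - et[1])), digits = 3), " Ha\n",
      sep = "")
  invisible(x)
}

total_energies <- function(traj) {
  vapply(traj$states, function(s) s$epot + s$ekin, 0)
}

traj_times <- function(traj) vapply(traj$states, function(s) s$time, 0)

#' Total-energy drift diagnostics
#'
#' Least-squares slope of the total energy versus time plus the maximum
#' absolute deviation from the initial energy.
#'
#' @param traj a `trajectory`.
#' @return list `slope_ha_per_ps`, `max_dev_ha`.
#' @export
energy_drift <- function(traj) {
  if (length(traj$states) < 2) stop("need at least 2 frames")
  e <- total_energies(traj)
  t_ps <- traj_times(traj) / 1000
  fit <- stats::lm.fit(cbind(1, t_ps), e)
  list(slope_ha_per_ps = unname(fit$coefficients[2]),
       max_dev_ha = max(abs(e - e[1])))
}

#' Trajectory decoherence (per-frame RMSD)
#'
#' Mass-unweighted RMSD of each frame of `b` against the same-time frame of
#' `a`, after optimal rigid superposition (Kabsch with unit weights).
#'
#' @param a,b trajectories on identical time grids.
#' @return numeric vector of RMSD values (angstrom) per frame.
#' @export
decoherence_rmsd <- function(a, b) {
  ta <- traj_times(a); tb <- traj_times(b)
  nn <- min(length(ta), length(tb))
  if (max(abs(ta[seq_len(nn)] - tb[seq_len(nn)])) > 1e-9)
    stop("time-grid mismatch between trajectories")
  vapply(seq_len(nn), function(i) {
    superposed_rmsd(a$states[[i]]$positions, b$states[[i]]$positions)
  }, 0)
}

superposed_rmsd <- function(X, Y) {
  if (!all(dim(X) == dim(Y))) stop("atom-count mismatch")
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  H <- t(Yc) %*% Xc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sqrt(mean(rowSums((Yc %*% t(R) - Xc)^2)))
}

#' First-passage frame of a decoherence series over a threshold
#' @param rmsd_series output of [decoherence_rmsd()].
#' @param threshold RMSD threshold (angstrom).
#' @return frame index (or `Inf` if never crossed).
#' @export
first_passage <- function(rmsd_series, threshold) {
  idx <- which(rmsd_series > threshold)
  if (length(idx) == 0) Inf else idx[1]
}
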