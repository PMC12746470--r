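# Training-set generation: temperature-targeted normal-mode sampling around a
# relaxed geometry, SCF labelling, and a short reference-MD test-set protocol.

#' Normal-mode sampler configuration
#'
#' Displacements along each vibrational mode are drawn from a zero-mean normal
#' distribution with the classical harmonic-oscillator variance
#' \eqn{k_B T / \omega_i^2} per mass-weighted mode coordinate (proportionality
#' constant 1, reproducing classical equipartition at the target temperature).
#' Modes softer than `mode_frequency_floor` (torsions and other large-
#' amplitude motions, for which the harmonic sigma diverges) are instead drawn
#' uniformly within the amplitude the floor frequency would give, which keeps
#' conformational modes broadly covered without unphysical displacements.
#'
#' @param temperature target temperature in kelvin (default 300 K).
#' @param n_samples number of geometries to draw.
#' @param seed integer RNG seed; every sampler draw is reproducible.
#' @param mode_frequency_floor frequency floor in cm^-1 (default 50).
#' @param displacement_cap optional cap on |q_i| in multiples of sigma
#'   (default `Inf`, i.e. none).
#' @return a `sampler_config`.
#' @export
sampler_config <- function(temperature = 300, n_samples = 1L, seed = 1L,
                           mode_frequency_floor = 50,
                           displacement_cap = Inf) {
  if (temperature < 0) stop("temperature must be >= 0")
  if (n_samples < 1) stop("n_samples must be >= 1")
  structure(list(temperature = temperature, n_samples = as.integer(n_samples),
                 seed = as.integer(seed),
                 mode_frequency_floor = mode_frequency_floor,
                 displacement_cap = displacement_cap),
            class = "sampler_config")
}

#' Sample geometries along normal modes
#'
#' Draws `cfg$n_samples` geometries `eq + sum_i q_i d_i`, where `d_i` is the
#' mass-unweighted displacement of mode i and the mass-weighted coordinate
#' `q_i ~ N(0, k_B T / omega_i^2)` (atomic units). Modes carry no net
#' translation or rotation, so the center of mass is preserved.
#'
#' @param eq the relaxed [geometry()] used for the normal-mode analysis.
#' @param modes a `normal_modes` object from [hessian_normal_modes()].
#' @param cfg a [sampler_config()].
#' @return list of geometries (length `n_samples`).
#' @export
sample_normal_mode_geometries <- function(eq, modes, cfg) {
  if (!identical(dim(modes$modes)[1], 3L * length(eq$Z)) &&
      nrow(modes$modes) != 3 * length(eq$Z))
    stop("modes do not match the geometry")
  kT <- KB_HARTREE * cfg$temperature
  sm <- sqrt(rep(eq$masses * ME_PER_AMU, each = 3))
  set.seed(cfg$seed)
  out <- vector("list", cfg$n_samples)
  omega <- modes$frequencies_au
  floor_au <- cfg$mode_frequency_floor / AU_FREQ_TO_CM1
  for (k in seq_len(cfg$n_samples)) {
    disp <- numeric(3 * length(eq$Z))
    for (i in seq_len(modes$n_vib)) {
      if (omega[i] >= floor_au) {
        sigma <- sqrt(kT) / omega[i]
        q <- stats::rnorm(1, 0, sigma)
        if (is.finite(cfg$displacement_cap))
          q <- max(-cfg$displacement_cap * sigma,
                   min(cfg$displacement_cap * sigma, q))
      } else {
        # soft/torsional mode: uniform over the amplitude at the floor
        amp <- sqrt(kT) / floor_au
        q <- stats::runif(1, -amp, amp)
      }
      disp <- disp + q * modes$modes[, i]
    }
    # mass-weighted displacement (bohr sqrt(m_e)) -> cartesian angstrom
    dx <- disp / sm * ANGSTROM_PER_BOHR
    out[[k]] <- with_positions(eq, eq$positions +
                                 matrix(dx, ncol = 3, byrow = TRUE))
  }
  out
}

#' Build a labelled training set
#'
#' For each geometry: Kabsch-align to the reference, run the SCF engine in the
#' aligned frame, and store the packed external-potential and 1-RDM features
#' together with energy and forces. Non-converged records are dropped with a
#' warning; more than 5\% failures aborts.
#'
#' @param geometries list of geometries (same atom ordering as `ref`).
#' @param ref reference [geometry()] defining the common learning frame.
#' @param method a [method_spec()].
#' @param provenance optional list stored with the set (temperature, seed...).
#' @param with_forces also store analytic forces per record (needed for
#'   force delta-learning; the dominant labelling cost for larger molecules,
#'   so energy-only protocols can switch it off).
#' @return a `training_set`: features `X` (n x M(M+1)/2 potentials), targets
#'   `Y` (n x M(M+1)/2 densities), `energies`, `forces` (list, aligned frame),
#'   `transforms`, `geometries` (aligned), `ref`, `method`, `M`.
#' @export
build_training_set <- function(geometries, ref, method, provenance = list(),
                               with_forces = TRUE) {
  n <- length(geometries)
  M <- basis_dimension(ref, method$basis)
  nf <- M * (M + 1) / 2
  X <- matrix(0, n, nf); Y <- matrix(0, n, nf)
  energies <- numeric(n)
  forces <- vector("list", n)
  transforms <- vector("list", n)
  aligned <- vector("list", n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    al <- align_to_reference(geometries[[i]], ref)
    s <- run_scf(al$geometry, method)
    if (!s$converged) {
      warning("SCF failed to converge for record ", i, "; dropped")
      next
    }
    X[i, ] <- pack_symmetric(external_potential_matrix(al$geometry, method))
    Y[i, ] <- pack_symmetric(s$gamma)
    energies[i] <- s$energy
    if (with_forces) forces[[i]] <- scf_forces(s)
    transforms[[i]] <- al$transform
    aligned[[i]] <- al$geometry
    ok[i] <- TRUE
  }
  if (sum(!ok) > 0.05 * n)
    stop("training-set generation aborted: ", sum(!ok), " of ", n,
         " SCF calculations failed to converge")
  structure(list(X = X[ok, , drop = FALSE], Y = Y[ok, , drop = FALSE],
                 energies = energies[ok], forces = forces[ok],
                 transforms = transforms[ok], geometries = aligned[ok],
                 ref = ref, method = method, M = M,
                 provenance = provenance),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat("<training_set> n =", nrow(x$X), "records, M =", x$M,
      paste0("(", x$method$functional, "/", x$method$basis, ")"), "\n")
  invisible(x)
}

n_records <- function(ts) nrow(ts$X)

#' Grow a training set by freshly sampled records
#'
#' Appends `increment` new normal-mode-sampled, SCF-labelled records using a
#' seed derived deterministically from the stored provenance, so growing
#' 50 -> 100 -> 150 equals growing 50 -> 150 in one step.
#'
#' @param existing a `training_set` whose provenance carries `eq`, `modes`,
#'   `cfg` (as stored by [make_training_set()]).
#' @param increment number of records to append (0 returns the set unchanged).
#' @return the enlarged `training_set`.
#' @export
grow_training_set <- function(existing, increment) {
  if (increment == 0) return(existing)
  pv <- existing$provenance
  if (is.null(pv$eq) || is.null(pv$modes) || is.null(pv$cfg))
    stop("training set lacks sampler provenance; cannot grow")
  n0 <- pv$n_drawn
  # deterministic schedule: draw n0 + increment samples from the base seed and
  # keep the tail, so the chain is independent of the growth increments
  cfg_all <- pv$cfg
  cfg_all$n_samples <- n0 + increment
  geoms <- sample_normal_mode_geometries(pv$eq, pv$modes, cfg_all)
  new_geoms <- geoms[(n0 + 1):(n0 + increment)]
  wf <- length(existing$forces) > 0 && !is.null(existing$forces[[1]])
  add <- build_training_set(new_geoms, existing$ref, existing$method,
                            provenance = pv, with_forces = wf)
  out <- existing
  out$X <- rbind(existing$X, add$X)
  out$Y <- rbind(existing$Y, add$Y)
  out$energies <- c(existing$energies, add$energies)
  out$forces <- c(existing$forces, add$forces)
  out$transforms <- c(existing$transforms, add$transforms)
  out$geometries <- c(existing$geometries, add$geometries)
  out$provenance$n_drawn <- n0 + increment
  out
}

#' One-call training-set construction with provenance for growth
#'
#' Convenience wrapper: normal-mode sampling at the configured temperature
#' followed by [build_training_set()], recording everything
#' [grow_training_set()] needs.
#'
#' @param eq relaxed [geometry()].
#' @param modes `normal_modes` at `eq`.
#' @param cfg a [sampler_config()].
#' @param method a [method_spec()].
#' @param with_forces see [build_training_set()].
#' @return a `training_set`.
#' @export
make_training_set <- function(eq, modes, cfg, method, with_forces = TRUE) {
  geoms <- sample_normal_mode_geometries(eq, modes, cfg)
  ts <- build_training_set(geoms, eq, method,
                           provenance = list(eq = eq, modes = modes, cfg = cfg,
                                             n_drawn = cfg$n_samples,
                                             temperature = cfg$temperature,
                                             seed = cfg$seed),
                           with_forces = with_forces)
  ts
}

#' Reference-MD test-set protocol
#'
#' Runs engine-driven NVE dynamics (velocity Verlet) from the relaxed
#' geometry with Maxwell-Boltzmann initial velocities and selects equally
#' spaced frames from the tail of the trajectory. The defaults are the
#' standard protocol (0.5 fs steps, 2 ps at 300 K, 100 frames from the last
#' 1 ps); every parameter can be scaled down.
#'
#' @param eq relaxed [geometry()].
#' @param method a [method_spec()].
#' @param temperature initialization temperature (K).
#' @param seed RNG seed for the initial velocities.
#' @param dt_fs time step (fs).
#' @param total_fs total simulated time (fs).
#' @param sample_window_fs tail window frames are drawn from (fs).
#' @param n_frames number of equally spaced frames to return.
#' @return list of geometries (length `n_frames`).
#' @export
generate_test_set_aimd <- function(eq, method, temperature = 300, seed = 1L,
                                   dt_fs = 0.5, total_fs = 2000,
                                   sample_window_fs = 1000, n_frames = 100L) {
  v0 <- maxwell_boltzmann_velocities(eq, temperature, seed)
  prov <- engine_force_provider(method)
  n_steps <- round(total_fs / dt_fs)
  traj <- run_nve(eq, v0, prov, dt_fs, n_steps)
  if (!is.null(attr(traj, "error")))
    stop("reference dynamics aborted: ", attr(traj, "error"))
  times <- vapply(traj$states, function(s) s$time, 0)
  t_end <- times[length(times)]
  sel_times <- seq(t_end - sample_window_fs + sample_window_fs / n_frames,
                   t_end, length.out = n_frames)
  idx <- vapply(sel_times, function(tt) which.min(abs(times - tt)), 0L)
  lapply(traj$states[idx], function(s) with_positions(eq, s$positions))
}
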