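# Self-consistent-field engine adapter.
#
# A narrow interface supplying every ab initio quantity the learning workflow
# consumes: external potential matrix v-hat, overlap, converged 1-RDM, total
# energy, analytic forces, Fock builds, one-electron properties, normal modes
# and derivative integrals.  The built-in backend is a deterministic,
# single-threaded restricted Hartree-Fock implementation over contracted
# Cartesian Gaussians; the learning stack only sees this contract, so another
# engine (or the toy quadratic mock used in tests) can stand in.

#' Electronic-structure method specification
#'
#' @param functional mean-field method name; the built-in engine resolves
#'   `"HF"`/`"RHF"` only (DFT functionals would need an engine with an
#'   exchange-correlation quadrature; requesting one raises a configuration
#'   error).
#' @param basis Gaussian basis-set name (`"STO-3G"` or `"6-31G"`).
#' @param scf_convergence SCF energy convergence threshold in hartree;
#'   must be <= 1e-6 (tighter than the accuracy the surrogate claims).
#' @param max_iter maximum SCF iterations.
#' @return a `method_spec`.
#' @export
method_spec <- function(functional = "HF", basis = "STO-3G",
                        scf_convergence = 1e-9, max_iter = 128L) {
  fn <- toupper(functional)
  if (!fn %in% c("HF", "RHF"))
    stop("configuration error: functional '", functional,
         "' is not resolvable by the built-in engine (use \"HF\")")
  if (scf_convergence > 1e-6)
    stop("scf_convergence must be <= 1e-6 Ha")
  structure(list(functional = "HF", basis = basis,
                 scf_convergence = scf_convergence,
                 max_iter = as.integer(max_iter)),
            class = "method_spec")
}

#' @export
print.method_spec <- function(x, ...) {
  cat("<method_spec> ", x$functional, "/", x$basis,
      " (SCF conv ", format(x$scf_convergence), " Ha)\n", sep = "")
  invisible(x)
}

# integral context: everything that depends only on (geometry, basis)
engine_context <- function(g, method) {
  shells <- basis_shells(g, method$basis)
  coords_bohr <- g$positions * BOHR_PER_ANGSTROM
  st <- cpp_overlap_kinetic(shells)
  V <- cpp_potential(shells, as.numeric(g$Z), coords_bohr)
  M <- attr(shells, "M")
  eri <- cpp_eri(shells)
  list(geometry = g, method = method, shells = shells, M = M,
       S = st$S, T = st$T, V = V, H = st$T + V, eri = eri,
       coords_bohr = coords_bohr,
       enuc = nuclear_repulsion(g))
}

nuclear_repulsion <- function(g) {
  p <- g$positions * BOHR_PER_ANGSTROM
  e <- 0
  n <- nrow(p)
  if (n < 2) return(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    e <- e + g$Z[i] * g$Z[j] / sqrt(sum((p[i, ] - p[j, ])^2))
  e
}

nuclear_repulsion_grad <- function(g) {
  # dVnn/dR in Ha/angstrom
  p <- g$positions * BOHR_PER_ANGSTROM
  n <- nrow(p)
  gr <- matrix(0, n, 3)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- p[i, ] - p[j, ]
    r <- sqrt(sum(d^2))
    gr[i, ] <- gr[i, ] - g$Z[i] * g$Z[j] * d / r^3
  }
  gr * BOHR_PER_ANGSTROM
}

#' External (electron-nuclear) potential matrix
#'
#' Matrix representation of the all-electron Coulomb potential
#' \eqn{v(r) = -\sum_I Z_I / |r - R_I|} in the AO basis; the model's input
#' feature.
#'
#' @param g a [geometry()].
#' @param method a [method_spec()].
#' @return an [ao_matrix()] with role `"potential"` (hartree).
#' @export
external_potential_matrix <- function(g, method) {
  shells <- basis_shells(g, method$basis)
  V <- cpp_potential(shells, as.numeric(g$Z), g$positions * BOHR_PER_ANGSTROM)
  ao_matrix(V, role = "potential", basis_label = method$basis,
            geometry_fingerprint = ao_fingerprint(g, method))
}

#' Overlap matrix
#' @inheritParams external_potential_matrix
#' @return an [ao_matrix()] with role `"overlap"`.
#' @export
overlap_matrix <- function(g, method) {
  shells <- basis_shells(g, method$basis)
  st <- cpp_overlap_kinetic(shells)
  ao_matrix(st$S, role = "overlap", basis_label = method$basis,
            geometry_fingerprint = ao_fingerprint(g, method))
}

# symmetric orthogonalizer S^{-1/2}
loewdin <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < tol)
    stop("overlap matrix numerically singular (min eigenvalue ",
         format(min(e$values)), ")")
  e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
}

#' Run a self-consistent-field calculation
#'
#' Restricted Hartree-Fock with DIIS acceleration. The converged closed-shell
#' density satisfies `Tr[gamma S] = N` and `gamma S gamma = 2 gamma`.
#'
#' @param g a [geometry()].
#' @param method a [method_spec()].
#' @param ctx optional precomputed integral context (internal reuse).
#' @param guess optional initial density matrix (e.g. from a previous MD step).
#' @return an `scf_result`: `gamma` (density [ao_matrix()]), `energy` (Ha),
#'   `forces` (n x 3, Ha/angstrom, lazily computed — see
#'   [analytic_forces_from_dm()]), `overlap`, `orbital_energies` (Ha),
#'   `mo_coefficients`, `dipole` (a.u.), `converged`, `n_iter`.
#' @export
run_scf <- function(g, method, ctx = NULL, guess = NULL) {
  if (is.null(ctx)) ctx <- engine_context(g, method)
  N <- n_electrons(g)
  nocc <- N %/% 2L
  X <- loewdin(ctx$S)
  dens_from_C <- function(C) 2 * tcrossprod(C[, seq_len(nocc), drop = FALSE])
  if (is.null(guess)) {
    # core-Hamiltonian guess
    Fm <- ctx$H
    e <- eigen(t(X) %*% Fm %*% X, symmetric = TRUE)
    C <- X %*% e$vectors[, order(e$values), drop = FALSE]
    P <- dens_from_C(C)
  } else P <- ao_values(guess)
  e_old <- Inf
  converged <- FALSE
  err_list <- list(); fock_list <- list()
  n_iter <- 0L
  orbital_energies <- NULL; C <- NULL
  for (it in seq_len(method$max_iter)) {
    n_iter <- it
    G <- cpp_fock_2e(ctx$eri, ctx$M, P)
    Fm <- ctx$H + G
    E <- 0.5 * sum(P * (ctx$H + Fm)) + ctx$enuc
    # DIIS on the orthonormal-basis commutator FPS - SPF
    err <- t(X) %*% (Fm %*% P %*% ctx$S - ctx$S %*% P %*% Fm) %*% X
    err_list[[length(err_list) + 1L]] <- err
    fock_list[[length(fock_list) + 1L]] <- Fm
    if (length(err_list) > 8L) {
      err_list <- err_list[-1L]; fock_list <- fock_list[-1L]
    }
    nd <- length(err_list)
    if (nd > 1L) {
      B <- matrix(0, nd + 1L, nd + 1L)
      for (i in seq_len(nd)) for (j in seq_len(nd))
        B[i, j] <- sum(err_list[[i]] * err_list[[j]])
      B[nd + 1L, seq_len(nd)] <- -1
      B[seq_len(nd), nd + 1L] <- -1
      rhs <- c(rep(0, nd), -1)
      cw <- tryCatch(solve(B, rhs)[seq_len(nd)], error = function(e) NULL)
      if (!is.null(cw)) {
        Fm <- Reduce(`+`, Map(`*`, fock_list, cw))
      }
    }
    ed <- eigen(t(X) %*% Fm %*% X, symmetric = TRUE)
    ord <- order(ed$values)
    C <- X %*% ed$vectors[, ord, drop = FALSE]
    orbital_energies <- ed$values[ord]
    P_new <- dens_from_C(C)
    de <- abs(E - e_old)
    derr <- max(abs(err))
    e_old <- E
    P <- P_new
    if (de < method$scf_convergence && derr < 1e-7) {
      converged <- TRUE
      break
    }
  }
  # final energy with the converged density
  G <- cpp_fock_2e(ctx$eri, ctx$M, P)
  Fm <- ctx$H + G
  E <- 0.5 * sum(P * (ctx$H + Fm)) + ctx$enuc
  fp <- ao_fingerprint(g, method)
  dip <- scf_dipole(ctx, P)
  structure(list(
    gamma = ao_matrix(P, role = "density", basis_label = method$basis,
                      geometry_fingerprint = fp),
    energy = E,
    fock = ao_matrix(Fm, role = "fock", basis_label = method$basis,
                     geometry_fingerprint = fp),
    overlap = ao_matrix(ctx$S, role = "overlap", basis_label = method$basis,
                        geometry_fingerprint = fp),
    orbital_energies = orbital_energies,
    mo_coefficients = C,
    nocc = nocc,
    dipole = dip,
    converged = converged,
    n_iter = n_iter,
    geometry = g, method = method, ctx = ctx), class = "scf_result")
}

#' @export
print.scf_result <- function(x, ...) {
  cat("<scf_result> E = ", format(x$energy, digits = 12), " Ha, ",
      if (x$converged) "converged" else "NOT CONVERGED",
      " in ", x$n_iter, " iterations\n", sep = "")
  invisible(x)
}

scf_dipole <- function(ctx, P) {
  d <- cpp_dipole(ctx$shells)
  elec <- -c(sum(P * d$x), sum(P * d$y), sum(P * d$z))
  nuc <- drop(crossprod(ctx$coords_bohr, ctx$geometry$Z))
  elec + nuc
}

#' Forces of a converged SCF result
#'
#' Analytic RHF gradient (Hellmann-Feynman + Pulay terms) using the converged
#' density and its energy-weighted density matrix.
#' @param scf an `scf_result`.
#' @return n x 3 matrix of forces in Ha/angstrom.
#' @export
scf_forces <- function(scf) {
  W <- energy_weighted_density(scf$mo_coefficients, scf$orbital_energies,
                               scf$nocc)
  analytic_forces_from_dm(scf$gamma, W, scf$geometry, scf$method,
                          ctx = scf$ctx)
}

energy_weighted_density <- function(C, eps, nocc) {
  Co <- C[, seq_len(nocc), drop = FALSE]
  2 * Co %*% (eps[seq_len(nocc)] * t(Co))
}

#' Fock matrix for a given density
#'
#' The Fock operator is the functional derivative of the total energy with
#' respect to the 1-RDM; for RHF, `f = h + J[gamma] - K[gamma]/2`.
#'
#' @param gamma density [ao_matrix()] (or plain matrix) with
#'   `Tr[gamma S]` within 0.1 electron of N.
#' @inheritParams external_potential_matrix
#' @param ctx optional precomputed context.
#' @return Fock [ao_matrix()] (hartree).
#' @export
fock_build <- function(gamma, g, method, ctx = NULL) {
  if (is.null(ctx)) ctx <- engine_context(g, method)
  P <- ao_values(gamma)
  tr <- sum(P * ctx$S)
  if (abs(tr - n_electrons(g)) > 0.1)
    stop("input error: Tr[gamma S] = ", format(tr),
         " violates the electron count ", n_electrons(g))
  Fm <- ctx$H + cpp_fock_2e(ctx$eri, ctx$M, P)
  ao_matrix(Fm, role = "fock", basis_label = method$basis,
            geometry_fingerprint = ao_fingerprint(g, method))
}

#' Total energy as a functional of the 1-RDM
#'
#' `E[gamma] = Tr[gamma h] + E_2[gamma] + V_nn`; at the converged SCF density
#' this equals the SCF energy, and for any N-representable gamma it is an
#' upper bound to it (variational principle).
#'
#' @inheritParams fock_build
#' @return total energy in hartree.
#' @export
energy_from_dm <- function(gamma, g, method, ctx = NULL) {
  if (is.null(ctx)) ctx <- engine_context(g, method)
  P <- ao_values(gamma)
  tr <- sum(P * ctx$S)
  if (abs(tr - n_electrons(g)) > 0.1)
    stop("input error: Tr[gamma S] = ", format(tr),
         " violates the electron count ", n_electrons(g))
  sum(P * ctx$H) + cpp_eri_energy(ctx$eri, ctx$M, P) + ctx$enuc
}

#' Analytic forces for a (density, energy-weighted density) pair
#'
#' Generic RHF gradient machinery: Hellmann-Feynman and Pulay contributions
#' evaluated for an arbitrary symmetric density `gamma` and energy-weighted
#' density `weighted_density` (rho_eps). With the converged SCF pair this
#' reproduces the engine's analytic forces.
#'
#' @param gamma density [ao_matrix()].
#' @param weighted_density energy-weighted density matrix (same basis/frame).
#' @inheritParams fock_build
#' @return n x 3 matrix of forces (Ha/angstrom).
#' @export
analytic_forces_from_dm <- function(gamma, weighted_density, g, method,
                                    ctx = NULL) {
  if (is.null(ctx)) ctx <- engine_context(g, method)
  P <- ao_values(gamma); W <- ao_values(weighted_density)
  if (!all(dim(P) == dim(W)) || nrow(P) != ctx$M)
    stop("input error: basis/frame mismatch between gamma and rho_eps")
  g1 <- cpp_grad_one_electron(ctx$shells, as.numeric(g$Z), ctx$coords_bohr,
                              P, W)
  g2 <- cpp_grad_eri(ctx$shells, P)
  # gradients from C++ are dE/dR in Ha/bohr
  dE <- (g1 + g2) * BOHR_PER_ANGSTROM + nuclear_repulsion_grad(g)
  -dE
}

#' Derivatives of the external potential matrix
#'
#' Returns, for every atom I, the three matrices \eqn{\partial \hat v /
#' \partial R_{I\alpha}} (alpha = x, y, z), including both the basis-center
#' and the Coulomb-operator-center dependence. Validated against central
#' finite differences of [external_potential_matrix()].
#'
#' @inheritParams external_potential_matrix
#' @return list over atoms; each element a list of matrices `x`, `y`, `z`
#'   (Ha/angstrom).
#' @export
nuclear_attraction_derivatives <- function(g, method) {
  shells <- basis_shells(g, method$basis)
  raw <- cpp_nuc_attr_grad(shells, as.numeric(g$Z),
                           g$positions * BOHR_PER_ANGSTROM)
  lapply(raw, function(a)
    list(x = a$x * BOHR_PER_ANGSTROM, y = a$y * BOHR_PER_ANGSTROM,
         z = a$z * BOHR_PER_ANGSTROM))
}

#' One-electron properties from a 1-RDM
#'
#' The 1-RDM gives direct access to any one-electron operator, including
#' nonmultiplicative ones such as the kinetic energy.
#'
#' @param gamma density [ao_matrix()].
#' @param which `"dipole"` (returns the 3-vector `Tr[gamma mu] + nuclear`,
#'   a.u.) or `"kinetic"` (returns `Tr[gamma T]`, Ha).
#' @inheritParams fock_build
#' @return numeric value or 3-vector.
#' @export
one_electron_property <- function(gamma, which = c("dipole", "kinetic"),
                                  g, method, ctx = NULL) {
  which <- match.arg(which)
  if (is.null(ctx)) ctx <- engine_context(g, method)
  P <- ao_values(gamma)
  tr <- sum(P * ctx$S)
  if (abs(tr - n_electrons(g)) > 0.1)
    stop("input error: trace-inconsistent density")
  if (which == "kinetic") return(sum(P * ctx$T))
  scf_dipole(ctx, P)
}

#' Vibrational normal modes at a relaxed geometry
#'
#' Mass-weighted Hessian by central finite differences of the analytic
#' gradient; rigid translations and rotations are projected out, leaving
#' `3N - 6` (`3N - 5` for linear molecules) modes.
#'
#' @param g relaxed [geometry()] (max |F| <= `force_tol`, verified).
#' @param method a [method_spec()].
#' @param step finite-difference step (angstrom).
#' @param force_tol relaxation tolerance (Ha/angstrom).
#' @param scheme `"central"` (2 x 3N gradients) or `"forward"` (3N + 1).
#' @param imaginary_tol frequencies below `-imaginary_tol` (cm^-1) raise a
#'   not-a-minimum error.
#' @return a `normal_modes` object: `frequencies_au`, `frequencies_cm1`,
#'   `modes` (3N x N_vib, mass-weighted, orthonormal), `n_vib`, `geometry`.
#' @export
hessian_normal_modes <- function(g, method, step = 2e-3, force_tol = 1e-4,
                                 scheme = c("central", "forward"),
                                 imaginary_tol = 30) {
  scheme <- match.arg(scheme)
  scf0 <- run_scf(g, method)
  if (!scf0$converged) stop("SCF not converged at the reference geometry")
  F0 <- scf_forces(scf0)
  if (max(abs(F0)) > force_tol)
    stop("not a relaxed minimum: max |F| = ", format(max(abs(F0))),
         " Ha/angstrom exceeds ", force_tol)
  n <- length(g$Z)
  H <- matrix(0, 3 * n, 3 * n)
  grad_at <- function(pos) {
    s <- run_scf(with_positions(g, pos), method)
    if (!s$converged) stop("SCF failure during Hessian displacement")
    -scf_forces(s)
  }
  for (i in seq_len(n)) for (d in 1:3) {
    k <- 3 * (i - 1) + d
    pp <- g$positions; pp[i, d] <- pp[i, d] + step
    gp <- grad_at(pp)
    if (scheme == "central") {
      pm <- g$positions; pm[i, d] <- pm[i, d] - step
      gm <- grad_at(pm)
      H[k, ] <- as.vector(t(gp - gm)) / (2 * step)
    } else {
      H[k, ] <- as.vector(t(gp - (-F0))) / step
    }
  }
  H <- (H + t(H)) / 2                     # Ha / angstrom^2
  H <- H / BOHR_PER_ANGSTROM^2            # Ha / bohr^2
  m_me <- rep(g$masses * ME_PER_AMU, each = 3)
  Hmw <- H / sqrt(outer(m_me, m_me))      # mass-weighted, atomic units
  # project out rigid translations and rotations
  P <- trans_rot_projector(g)
  Hp <- t(P) %*% Hmw %*% P
  e <- eigen((Hp + t(Hp)) / 2, symmetric = TRUE)
  lam <- rev(e$values)                    # ascending
  vec <- P %*% e$vectors[, rev(seq_along(e$values)), drop = FALSE]
  freq_cm <- sign(lam) * sqrt(abs(lam)) * AU_FREQ_TO_CM1
  if (any(freq_cm < -imaginary_tol))
    stop("not-a-minimum error: imaginary frequency ",
         format(min(freq_cm), digits = 4), " cm^-1")
  keep <- freq_cm > 0
  lam <- lam[keep]; vec <- vec[, keep, drop = FALSE]
  structure(list(frequencies_au = sqrt(pmax(lam, 0)),
                 frequencies_cm1 = sqrt(pmax(lam, 0)) * AU_FREQ_TO_CM1,
                 modes = vec, n_vib = sum(keep), geometry = g,
                 method = method), class = "normal_modes")
}

#' @export
print.normal_modes <- function(x, ...) {
  cat("<normal_modes> N_vib =", x$n_vib, "; frequencies (cm^-1):",
      paste(format(x$frequencies_cm1, digits = 5), collapse = " "), "\n")
  invisible(x)
}

# orthonormal basis of the complement of rigid translations/rotations in
# mass-weighted coordinates; returns 3N x (3N - 6 or 3N - 5)
trans_rot_projector <- function(g) {
  n <- length(g$Z)
  sm <- sqrt(g$masses * ME_PER_AMU)
  com <- center_of_mass(g)
  X <- sweep(g$positions, 2, com)
  B <- matrix(0, 3 * n, 6)
  for (d in 1:3) B[seq(d, 3 * n, by = 3), d] <- sm
  # rotations about x, y, z
  rx <- cbind(0, -X[, 3], X[, 2]) * sm
  ry <- cbind(X[, 3], 0, -X[, 1]) * sm
  rz <- cbind(-X[, 2], X[, 1], 0) * sm
  B[, 4] <- as.vector(t(rx)); B[, 5] <- as.vector(t(ry)); B[, 6] <- as.vector(t(rz))
  # drop numerically-null rotation generators (linear molecules have one)
  norms <- sqrt(colSums(B^2))
  B <- B[, norms > 1e-8 * max(norms), drop = FALSE]
  q <- qr(B)
  rank <- q$rank                       # 5 for linear molecules
  Bo <- qr.Q(q)[, seq_len(rank), drop = FALSE]
  # orthonormal complement: eigenvectors of I - Bo Bo^T with eigenvalue 1
  e <- eigen(diag(3 * n) - tcrossprod(Bo), symmetric = TRUE)
  e$vectors[, e$values > 0.5, drop = FALSE]
}

#' Relax a geometry to a local minimum
#'
#' BFGS minimization of the total SCF energy with analytic gradients,
#' polished until `max |F| <= force_tol`.
#'
#' @param g starting [geometry()].
#' @param method a [method_spec()].
#' @param force_tol convergence threshold on the max force component
#'   (Ha/angstrom).
#' @param max_iter outer iteration budget.
#' @return list with `geometry`, `energy`, `forces`, `converged`.
#' @export
optimize_geometry <- function(g, method, force_tol = 1e-4, max_iter = 300L) {
  n <- length(g$Z)
  fn <- function(x) {
    s <- run_scf(with_positions(g, matrix(x, n, 3, byrow = TRUE)), method)
    if (!s$converged) return(1e6)
    s$energy
  }
  gr <- function(x) {
    s <- run_scf(with_positions(g, matrix(x, n, 3, byrow = TRUE)), method)
    as.vector(t(-scf_forces(s)))
  }
  x0 <- as.vector(t(g$positions))
  opt <- stats::optim(x0, fn, gr, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = max_iter))
  gout <- with_positions(g, matrix(opt$par, n, 3, byrow = TRUE))
  s <- run_scf(gout, method)
  f <- scf_forces(s)
  # steepest-descent polish if BFGS stalled above tolerance
  it <- 0L
  while (max(abs(f)) > force_tol && it < 60L) {
    gout <- with_positions(gout, gout$positions + 0.6 * f)
    s <- run_scf(gout, method)
    f <- scf_forces(s)
    it <- it + 1L
  }
  list(geometry = gout, energy = s$energy, forces = f,
       converged = max(abs(f)) <= force_tol)
}
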