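# Property and force evaluation from predicted 1-RDMs, including the
# correction for their nonvariational character:
#   F_I = F_I[Hellmann-Feynman + Pulay](gamma, rho_eps) + Tr[(f - f') dgamma/dR_I]
# where f' is the Fock operator made co-diagonal with gamma's natural
# orbitals; the correction vanishes when [f, gamma] = 0 (converged SCF).

#' HOMO-LUMO gap from a (predicted) 1-RDM
#'
#' Builds the Fock matrix for the given density and diagonalizes it
#' (generalized eigenproblem with S); the single diagonalization of
#' `f[gamma]` recovers canonical orbitals of better quality than the input
#' density (Harris-functional effect). Gap = eps(LUMO) - eps(HOMO).
#'
#' @param gamma purified density [ao_matrix()].
#' @param g [geometry()] the density belongs to.
#' @param method a [method_spec()].
#' @param units `"Ha"` (default) or `"eV"`.
#' @param ctx optional precomputed engine context.
#' @return gap (non-positive values return with a warning).
#' @export
homo_lumo_gap <- function(gamma, g, method, units = c("Ha", "eV"),
                          ctx = NULL) {
  units <- match.arg(units)
  if (is.null(ctx)) ctx <- engine_context(g, method)
  f <- fock_build(gamma, g, method, ctx = ctx)
  eps <- generalized_eigvals(ao_values(f), ctx$S)
  nocc <- n_electrons(g) %/% 2L
  gap <- eps[nocc + 1] - eps[nocc]
  if (gap <= 0) warning("non-positive HOMO-LUMO gap (near-degeneracy)")
  if (units == "eV") gap * EV_PER_HARTREE else gap
}

generalized_eigvals <- function(Fm, S) {
  X <- loewdin(S)
  sort(eigen(t(X) %*% Fm %*% X, symmetric = TRUE, only.values = TRUE)$values)
}

generalized_eig <- function(Fm, S) {
  X <- loewdin(S)
  e <- eigen(t(X) %*% Fm %*% X, symmetric = TRUE)
  ord <- order(e$values)
  list(values = e$values[ord], vectors = X %*% e$vectors[, ord, drop = FALSE])
}

#' The co-diagonal Fock operator f'
#'
#' The Fock operator whose spectral decomposition yields the natural orbitals
#' of `gamma`: f with its off-diagonal elements zeroed in gamma's
#' natural-orbital basis. For an aufbau-purified density the occupations are
#' exactly 0/2, so the natural orbitals are only defined up to rotations
#' inside the occupied and virtual subspaces; the unique representative is
#' obtained by choosing, within each subspace, the orbitals that diagonalize
#' f there. Equivalently, f' keeps the occupied-occupied and
#' virtual-virtual blocks of f, and the residual `delta f = f - f'` is the
#' occupied-virtual coupling - the orbital-rotation gradient, which vanishes
#' at SCF convergence (Brillouin condition) and for any gamma commuting
#' with f.
#'
#' @param fock Fock [ao_matrix()] built from `gamma`.
#' @param gamma purified density (occupations in \{0, 2\}).
#' @param S overlap matrix.
#' @param n_occ optional occupied count; default: number of occupations > 1.
#' @return f' as an [ao_matrix()] with role `"fock"`.
#' @export
fock_prime <- function(fock, gamma, S, n_occ = NULL) {
  Fv <- ao_values(fock); Sv <- ao_values(S)
  if (!all(dim(Fv) == dim(ao_values(gamma))))
    stop("basis mismatch between fock and gamma")
  no <- natural_orbitals(gamma, Sv)
  C <- no$orbitals                        # S-orthonormal, occ first
  if (is.null(n_occ)) n_occ <- sum(no$occupations > 1)
  Fmo <- t(C) %*% Fv %*% C
  o <- seq_len(n_occ); v <- setdiff(seq_len(ncol(C)), o)
  Fblk <- Fmo
  Fblk[o, v] <- 0
  Fblk[v, o] <- 0
  SC <- Sv %*% C
  out <- SC %*% Fblk %*% t(SC)
  ao_matrix((out + t(out)) / 2, role = "fock",
            basis_label = if (inherits(fock, "ao_matrix")) fock$basis_label else "")
}

#' Gradient of the predicted 1-RDM with respect to nuclear positions
#'
#' Two evaluation modes. `"fd"` (default): central finite differences of the
#' full align-predict(-purify) pipeline in the lab frame (default step
#' 5e-4 angstrom, chosen where the O(h^2) truncation error drops below the
#' force accuracy of interest); this is the mode the force correction uses
#' (`what = "purified"`).
#' `"analytic"`: chain rule through the KRR model - kernel gradients (RBF:
#' `-2 Gamma (x - x_i) K_i`, LIN/POL analogues) composed with the analytic
#' external-potential derivatives and the frame-transform response (the
#' latter obtained by differencing the closed-form Kabsch map, which involves
#' no engine or kernel calls); available for the raw prediction only, since
#' purification is not smoothly differentiable through its eigensolver.
#'
#' @param model a `gamma_model`.
#' @param g lab-frame [geometry()].
#' @param mode `"fd"` or `"analytic"`.
#' @param what differentiate the `"purified"` or `"raw"` prediction
#'   (`"analytic"` supports `"raw"` only).
#' @param step finite-difference step (angstrom).
#' @return list over atoms; each element a list of M x M matrices `x`, `y`,
#'   `z` (per angstrom).
#' @export
grad_gamma_ml <- function(model, g, mode = c("fd", "analytic"),
                          what = c("purified", "raw"), step = 5e-4) {
  mode <- match.arg(mode); what <- match.arg(what)
  n <- length(g$Z)
  dims <- c("x", "y", "z")
  if (mode == "fd") {
    pred_at <- function(pos) {
      gi <- with_positions(g, pos)
      al <- align_to_reference(gi, model$ref)
      v <- pack_symmetric(external_potential_matrix(al$geometry,
                                                    model$method))
      raw <- predict_gamma(model, v)
      gam <- if (what == "purified") {
        Sref <- overlap_matrix(al$geometry, model$method)
        purify(raw, Sref, n_electrons(g))
      } else raw
      inv <- invert_transform(al$transform)
      rotate_ao_matrix(gam, inv, basis_shells(gi, model$method$basis))$values
    }
    out <- vector("list", n)
    for (i in seq_len(n)) {
      di <- list()
      for (d in 1:3) {
        pp <- g$positions; pp[i, d] <- pp[i, d] + step
        pm <- g$positions; pm[i, d] <- pm[i, d] - step
        di[[dims[d]]] <- (pred_at(pp) - pred_at(pm)) / (2 * step)
      }
      out[[i]] <- di
    }
    return(out)
  }
  if (what != "raw")
    stop("analytic mode differentiates the raw prediction only")
  # ---- analytic kernel chain rule -------------------------------------
  al <- align_to_reference(g, model$ref)
  ga <- al$geometry
  v <- pack_symmetric(external_potential_matrix(ga, model$method))
  kk <- model$kernel
  Kv <- drop(kernel_matrix(matrix(v, 1), model$X, kk))    # K(v_i, v), length n_train
  G <- resolve_gamma(kk, length(v))
  # dK_i/dv as rows (n_train x nf); RBF: -2 Gamma (v - x_i) K_i
  dK <- if (kk$kind == "RBF") -2 * G * sweep(-model$X, 2, -v) * Kv else NULL
  grad_v_aligned <- nuclear_attraction_derivatives(ga, model$method)
  # Jacobian of the aligned positions wrt lab positions, by differencing the
  # closed-form alignment map (geometry-only; includes the Kabsch response)
  hh <- 1e-5
  Jac <- array(0, c(n, 3, n, 3))  # d ga[j,beta] / d g[i,alpha]
  for (i in seq_len(n)) for (d in 1:3) {
    pp <- g$positions; pp[i, d] <- pp[i, d] + hh
    pm <- g$positions; pm[i, d] <- pm[i, d] - hh
    ap <- align_to_reference(with_positions(g, pp), model$ref)$geometry
    am <- align_to_reference(with_positions(g, pm), model$ref)$geometry
    Jac[, , i, d] <- (ap$positions - am$positions) / (2 * hh)
  }
  # dv/d(aligned position j,beta), packed rows
  nf <- length(v)
  dv_d_ga <- matrix(0, n * 3, nf)
  for (j in seq_len(n)) for (b in 1:3)
    dv_d_ga[3 * (j - 1) + b, ] <-
      pack_symmetric(grad_v_aligned[[j]][[dims[b]]])
  lab_shells <- basis_shells(g, model$method$basis)
  inv <- invert_transform(al$transform)
  U <- ao_rotation_matrix(lab_shells, inv$rotation)
  # frame response of the back-rotation, also by closed-form differencing
  out <- vector("list", n)
  raw_aligned <- predict_gamma(model, v)$values
  for (i in seq_len(n)) {
    di <- list()
    for (d in 1:3) {
      # dv/d g[i,d] through the frame map
      dv <- numeric(nf)
      for (j in seq_len(n)) for (b in 1:3) {
        w <- Jac[j, b, i, d]
        if (abs(w) > 1e-12) dv <- dv + w * dv_d_ga[3 * (j - 1) + b, ]
      }
      dgamma_aligned <- switch(kk$kind,
        RBF = {
          dKi <- drop(dK %*% dv)               # n_train scalars
          unpack_symmetric(drop(crossprod(model$B, dKi)), model$M)
        },
        LIN = unpack_symmetric(drop(crossprod(model$B,
                                              drop(model$X %*% dv))), model$M),
        POL = {
          base <- G * drop(model$X %*% v) + kk$offset
          dKi <- kk$degree * base^(kk$degree - 1) * G * drop(model$X %*% dv)
          unpack_symmetric(drop(crossprod(model$B, dKi)), model$M)
        })
      # back-rotation: U fixed part ...
      fixed <- t(U) %*% dgamma_aligned %*% U
      # ... plus the response of the rotation itself
      pp <- g$positions; pp[i, d] <- pp[i, d] + hh
      pm <- g$positions; pm[i, d] <- pm[i, d] - hh
      tp <- invert_transform(align_to_reference(with_positions(g, pp),
                                                model$ref)$transform)
      tm <- invert_transform(align_to_reference(with_positions(g, pm),
                                                model$ref)$transform)
      Up <- ao_rotation_matrix(lab_shells, tp$rotation)
      Um <- ao_rotation_matrix(lab_shells, tm$rotation)
      dU <- (Up - Um) / (2 * hh)
      rot_resp <- t(dU) %*% raw_aligned %*% U + t(U) %*% raw_aligned %*% dU
      di[[dims[d]]] <- fixed + rot_resp
    }
    out[[i]] <- di
  }
  out
}

#' Atomic forces from a surrogate model
#'
#' Three modes. `"hellmann_feynman"`: the generic gradient machinery with the
#' energy-weighted density built from diagonalizing `f[gamma]` with aufbau
#' occupations - exact for a variational density, biased for a predicted one.
#' `"corrected"`: adds `Tr[(f - f') dgamma/dR_I]` per atom and component,
#' compensating the nonvariational character of the prediction.
#' `"delta_learned"`: the affine force model of a `delta_properties` stack.
#'
#' @param mode force mode (above).
#' @param stack a [model_stack()] (any mode; `delta_learned` requires a
#'   fitted force delta-model).
#' @param g [geometry()] in the frame the forces are wanted in.
#' @param method a [method_spec()] (defaults to the stack's).
#' @param gamma_purified optional precomputed purified density for `g`.
#' @param ctx optional engine context for `g`.
#' @param grad_gamma optional precomputed [grad_gamma_ml()] result.
#' @param aligned internal flag: `g` is already in the model frame.
#' @return n x 3 force matrix (Ha/angstrom).
#' @export
compute_forces <- function(mode = c("corrected", "hellmann_feynman",
                                    "delta_learned"),
                           stack, g, method = NULL, gamma_purified = NULL,
                           ctx = NULL, grad_gamma = NULL, aligned = FALSE) {
  mode <- match.arg(mode)
  if (inherits(stack, "gamma_model")) stack <- model_stack(stack)
  model <- stack$gamma
  if (is.null(method)) method <- model$method
  if (mode == "delta_learned") {
    if (is.null(stack$delta_props$forces))
      stop("missing force delta-model for delta_learned mode")
    pf <- predict_full(stack_with_flavor(stack, "delta_properties"), g,
                       want_forces = TRUE)
    return(pf$forces)
  }
  if (is.null(ctx)) ctx <- engine_context(g, method)
  if (is.null(gamma_purified)) {
    al <- align_to_reference(g, model$ref)
    v <- pack_symmetric(external_potential_matrix(al$geometry, method))
    raw <- predict_gamma(model, v)
    pur_a <- purify(raw, overlap_matrix(al$geometry, method), n_electrons(g))
    gamma_purified <- rotate_ao_matrix(pur_a, invert_transform(al$transform),
                                       basis_shells(g, method$basis))
  }
  Fm <- ao_values(fock_build(gamma_purified, g, method, ctx = ctx))
  if (mode == "hellmann_feynman") {
    ge <- generalized_eig(Fm, ctx$S)
    nocc <- n_electrons(g) %/% 2L
    occ <- seq_len(nocc)
    rho_eps <- 2 * ge$vectors[, occ, drop = FALSE] %*%
      (ge$values[occ] * t(ge$vectors[, occ, drop = FALSE]))
    return(analytic_forces_from_dm(gamma_purified, rho_eps, g, method,
                                   ctx = ctx))
  }
  # corrected mode: the exact total derivative of the surrogate energy,
  #   F = F_frozen - Tr[f dgamma/dR]
  # with F_frozen the gradient at frozen AO density (no orbital-response
  # term). Splitting f = f' + delta f, the f' part reproduces the standard
  # energy-weighted-density Pulay force at convergence and the delta f part
  # is the nonvariational correction, which vanishes when [f, gamma] = 0;
  # evaluating Tr[f dgamma] in one shot keeps the two contributions exactly
  # consistent with the energy.
  if (is.null(grad_gamma))
    grad_gamma <- grad_gamma_ml(model, g, mode = "fd", what = "purified")
  zero <- matrix(0, ctx$M, ctx$M)
  Ffrozen <- analytic_forces_from_dm(gamma_purified, zero, g, method,
                                     ctx = ctx)
  corr <- matrix(0, length(g$Z), 3)
  dims <- c("x", "y", "z")
  for (i in seq_along(g$Z)) for (d in 1:3)
    corr[i, d] <- sum(Fm * grad_gamma[[i]][[dims[d]]])
  Ffrozen - corr
}

stack_with_flavor <- function(stack, flavor) {
  stack$flavor <- flavor
  stack
}
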