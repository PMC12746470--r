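# The learning core: matrix-target kernel ridge regression for the
# v-hat -> gamma-hat map, affine delta-models for refinement and properties,
# and aufbau purification of predicted 1-RDMs.

#' Kernel specification
#'
#' Kernels over packed feature vectors: `LIN` \eqn{x^T y}, `RBF`
#' \eqn{\exp(-\Gamma \|x-y\|^2)}, `POL` \eqn{(\Gamma x^T y + c)^d}.
#' Defaults follow the field conventions: degree `d = 3`, offset `c = 0`, and
#' `Gamma = 1/N_features` recomputed per data set when `gamma_scale = NULL`.
#'
#' @param kind `"RBF"`, `"LIN"` or `"POL"`.
#' @param alpha ridge regularization, `alpha >= 0` (0 gives exact
#'   interpolation on distinct inputs; see [fit_gamma()]).
#' @param gamma_scale kernel scale Gamma; `NULL` means `1/N_features`.
#' @param degree polynomial degree d (POL only).
#' @param offset polynomial offset c (POL only).
#' @return a `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("RBF", "LIN", "POL"), alpha = 0,
                        gamma_scale = NULL, degree = 3, offset = 0) {
  kind <- match.arg(kind)
  if (alpha < 0) stop("alpha must be >= 0")
  structure(list(kind = kind, alpha = alpha, gamma_scale = gamma_scale,
                 degree = degree, offset = offset),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("<kernel_spec> ", x$kind, " alpha=", x$alpha, " Gamma=",
      if (is.null(x$gamma_scale)) "1/N_features" else x$gamma_scale,
      if (x$kind == "POL") paste0(" d=", x$degree, " c=", x$offset) else "",
      "\n", sep = "")
  invisible(x)
}

resolve_gamma <- function(k, n_features) {
  if (!is.null(k$gamma_scale)) k$gamma_scale else 1 / n_features
}

#' Evaluate a kernel between two feature vectors
#' @param x,y numeric feature vectors of equal length.
#' @param k a [kernel_spec()].
#' @return scalar kernel value.
#' @export
kernel_eval <- function(x, y, k) {
  if (length(x) != length(y)) stop("feature length mismatch")
  G <- resolve_gamma(k, length(x))
  switch(k$kind,
         LIN = sum(x * y),
         RBF = exp(-G * sum((x - y)^2)),
         POL = (G * sum(x * y) + k$offset)^k$degree)
}

#' Kernel matrix between two sets of feature rows
#' @param X,Y matrices with features in rows (`Y = NULL` means `Y = X`).
#' @param k a [kernel_spec()].
#' @return `nrow(X) x nrow(Y)` kernel matrix (symmetric and PSD for LIN/RBF
#'   when `Y = X`).
#' @export
kernel_matrix <- function(X, Y = NULL, k) {
  if (is.null(Y)) Y <- X
  if (ncol(X) != ncol(Y)) stop("feature dimension mismatch")
  G <- resolve_gamma(k, ncol(X))
  switch(k$kind,
         LIN = X %*% t(Y),
         RBF = {
           # center on a reference row first: raw potential features carry a
           # large common offset (||v||^2 >> ||v - v'||^2) and the textbook
           # expansion loses ~8 digits to cancellation otherwise
           mu <- Y[1, ]
           Xc <- sweep(X, 2, mu); Yc <- sweep(Y, 2, mu)
           d2 <- outer(rowSums(Xc^2), rowSums(Yc^2), "+") - 2 * Xc %*% t(Yc)
           exp(-G * pmax(d2, 0))
         },
         POL = (G * (X %*% t(Y)) + k$offset)^k$degree)
}

# solve (K + alpha I) B = Y; for alpha = 0 fall back to escalating jitter,
# scaled by the kernel magnitude (features are raw potential-matrix elements,
# so LIN/POL kernel values can be O(1e4))
krr_solve <- function(K, Yt, alpha) {
  n <- nrow(K)
  kscale <- max(mean(diag(K)), 1)
  jitters <- if (alpha > 0) alpha else c(0, 1e-12, 1e-10, 1e-8) * kscale
  for (j in jitters) {
    A <- K + diag(j, n)
    B <- tryCatch({
      ch <- chol(A)
      backsolve(ch, forwardsolve(t(ch), Yt))
    }, error = function(e) NULL)
    if (!is.null(B)) {
      if (alpha == 0 && j > 0)
        message("KRR: kernel matrix required diagonal jitter ", j)
      return(B)
    }
  }
  stop("kernel matrix numerically singular with alpha = 0 ",
       "(duplicate training inputs?); increase alpha or deduplicate")
}

#' Fit the gamma-learning model (kernel ridge regression)
#'
#' Solves `(K + alpha I) B = Y` for the matrix-shaped weights; each weight
#' row unpacks to a symmetric matrix of the same shape as the 1-RDM. At
#' `alpha = 0` the model interpolates every training target exactly (up to
#' solver tolerance) on distinct inputs.
#'
#' @param ts a `training_set`.
#' @param k a [kernel_spec()].
#' @return a `gamma_model`: training features `X`, weights `B`, `kernel`,
#'   reference geometry/method metadata, basis dimension `M`.
#' @export
fit_gamma <- function(ts, k) {
  n <- nrow(ts$X)
  if (n < 1) stop("need at least one training record")
  if (k$alpha == 0 && n > 1) {
    if (anyDuplicated(round(ts$X, 12)))
      stop("duplicate feature rows with alpha = 0; deduplicate or set alpha")
  }
  kk <- k
  kk$gamma_scale <- resolve_gamma(k, ncol(ts$X))  # freeze the data-set Gamma
  K <- kernel_matrix(ts$X, NULL, kk)
  B <- krr_solve(K, ts$Y, kk$alpha)
  structure(list(X = ts$X, B = B, kernel = kk, ref = ts$ref,
                 method = ts$method, M = ts$M,
                 n_train = n), class = "gamma_model")
}

#' @export
print.gamma_model <- function(x, ...) {
  cat("<gamma_model> ", x$kernel$kind, " KRR, n_train=", x$n_train,
      ", M=", x$M, " (", x$method$functional, "/", x$method$basis, ")\n",
      sep = "")
  invisible(x)
}

#' Predict a raw (unpurified) 1-RDM from a potential feature vector
#'
#' `gamma[v] = sum_i B_i K(v_i, v)`; symmetric by construction but with no
#' N-representability guarantee — follow with [purify()].
#'
#' @param model a `gamma_model`.
#' @param v packed external-potential features (aligned frame) or an
#'   [ao_matrix()] with role `"potential"`.
#' @return raw predicted density as an [ao_matrix()].
#' @export
predict_gamma <- function(model, v) {
  if (inherits(v, "ao_matrix")) v <- pack_symmetric(v)
  if (length(v) != ncol(model$X))
    stop("feature dimension mismatch: got ", length(v), ", model expects ",
         ncol(model$X))
  kv <- kernel_matrix(matrix(v, 1), model$X, model$kernel)  # 1 x n
  y <- drop(kv %*% model$B)
  ao_matrix(unpack_symmetric(y, model$M), role = "density",
            basis_label = model$method$basis)
}

#' Aufbau purification of a predicted 1-RDM
#'
#' Imposes N-representability by a single diagonalization: transform to the
#' Loewdin-orthogonalized basis, diagonalize, occupy the N/2 largest natural
#' orbitals with occupation 2 and all others with 0, and back-transform.
#' The output satisfies `Tr[gamma S] = N` (1e-10) and
#' `gamma S gamma = 2 gamma` (1e-8) exactly by construction; purification is
#' idempotent.
#'
#' @param raw predicted density ([ao_matrix()] or matrix).
#' @param S overlap matrix of the same frame/basis.
#' @param N even electron count.
#' @param tie_tol occupations closer than this at the aufbau boundary log a
#'   warning (deterministic eigenvector ordering breaks the tie).
#' @return purified density [ao_matrix()].
#' @export
purify <- function(raw, S, N, tie_tol = 1e-10) {
  P <- ao_values(raw); Sv <- ao_values(S)
  if (N %% 2 != 0) stop("N must be even (spin-compensated)")
  nocc <- N / 2
  es <- eigen(Sv, symmetric = TRUE)
  Xh <- es$vectors %*% (sqrt(es$values) * t(es$vectors))     # S^{1/2}
  Xm <- es$vectors %*% ((1 / sqrt(es$values)) * t(es$vectors))  # S^{-1/2}
  Po <- Xh %*% P %*% Xh                 # orthonormal-basis density
  e <- eigen((Po + t(Po)) / 2, symmetric = TRUE)
  # descending occupations; deterministic sign convention
  occ <- e$values
  vec <- e$vectors
  if (nocc >= 1 && nocc < length(occ) &&
      abs(occ[nocc] - occ[nocc + 1]) < tie_tol)
    warning("degenerate occupations at the aufbau boundary; ",
            "tie broken by deterministic eigenvector ordering")
  sel <- seq_len(nocc)
  Vo <- vec[, sel, drop = FALSE]
  Pnew <- 2 * tcrossprod(Vo)
  out <- Xm %*% Pnew %*% Xm
  m <- if (inherits(raw, "ao_matrix")) raw else
    ao_matrix(out, role = "density")
  m$values <- (out + t(out)) / 2
  m$role <- "density"
  m
}

#' Natural orbitals and occupations of a density in a nonorthogonal basis
#'
#' Solves the generalized eigenproblem `gamma S c = n c` via Loewdin
#' orthogonalization; returns S-orthonormal orbital coefficients and
#' occupations sorted in decreasing order with a deterministic sign
#' convention (first nonzero component positive).
#'
#' @param gamma density matrix.
#' @param S overlap matrix.
#' @return list `occupations`, `orbitals` (AO coefficients, columns).
#' @export
natural_orbitals <- function(gamma, S) {
  P <- ao_values(gamma); Sv <- ao_values(S)
  es <- eigen(Sv, symmetric = TRUE)
  Xh <- es$vectors %*% (sqrt(es$values) * t(es$vectors))
  Xm <- es$vectors %*% ((1 / sqrt(es$values)) * t(es$vectors))
  Po <- Xh %*% P %*% Xh
  e <- eigen((Po + t(Po)) / 2, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  occ <- e$values[ord]
  V <- Xm %*% e$vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(V))) {
    nz <- which(abs(V[, j]) > 1e-8)[1]
    if (!is.na(nz) && V[nz, j] < 0) V[, j] <- -V[, j]
  }
  list(occupations = occ, orbitals = V)
}

#' Fit an affine delta-model
#'
#' Ordinary least squares with intercept mapping flattened 1-RDM features to
#' targets; rank-deficient systems get the minimum-norm solution via SVD.
#' Used both for gamma-refinement (targets = reference gamma features) and
#' for property learning (targets = energies / flattened forces).
#'
#' @param X feature matrix (rows = records).
#' @param Yt target matrix or vector.
#' @param target_kind `"gamma_refine"`, `"energy"` or `"forces"`.
#' @return a `delta_model` with coefficients `W`, intercept `b`.
#' @export
fit_delta <- function(X, Yt, target_kind = c("gamma_refine", "energy",
                                             "forces")) {
  target_kind <- match.arg(target_kind)
  Yt <- as.matrix(Yt)
  if (nrow(X) != nrow(Yt)) stop("row count mismatch")
  xm <- colMeans(X); ym <- colMeans(Yt)
  Xc <- sweep(X, 2, xm); Yc <- sweep(Yt, 2, ym)
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * max(sv$d, 0) * .Machine$double.eps
  pos <- sv$d > tol
  W <- if (any(pos)) {
    sv$v[, pos, drop = FALSE] %*%
      ((1 / sv$d[pos]) * (t(sv$u[, pos, drop = FALSE]) %*% Yc))
  } else matrix(0, ncol(X), ncol(Yt))
  b <- ym - drop(crossprod(W, xm))
  structure(list(W = W, b = b, target_kind = target_kind,
                 p_in = ncol(X), p_out = ncol(Yt)), class = "delta_model")
}

#' @rdname fit_delta
#' @param pred_feats,target_feats flattened predicted / reference gamma rows.
#' @export
fit_delta_refine <- function(pred_feats, target_feats) {
  fit_delta(pred_feats, target_feats, "gamma_refine")
}

#' Fit delta-models for energies and forces
#' @param gamma_feats flattened (purified) predicted-density features.
#' @param energies training energies (Ha).
#' @param forces list of n x 3 force matrices (aligned frame, Ha/angstrom).
#' @return list with `energy` and `forces` `delta_model`s.
#' @export
fit_delta_properties <- function(gamma_feats, energies, forces = NULL) {
  out <- list(energy = fit_delta(gamma_feats, energies, "energy"))
  if (!is.null(forces)) {
    Fm <- t(vapply(forces, function(f) as.vector(t(f)),
                   numeric(length(forces[[1]]))))
    out$forces <- fit_delta(gamma_feats, Fm, "forces")
  }
  out
}

#' Predict from a delta-model
#' @param object a `delta_model`.
#' @param newdata feature matrix or vector.
#' @param ... unused.
#' @return prediction matrix (rows = records).
#' @export
predict.delta_model <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, 1) else as.matrix(newdata)
  sweep(X %*% object$W, 2, object$b, "+")
}

#' Assemble a surrogate model stack
#'
#' Bundles the fitted pieces into one of the three model flavors:
#' `"gamma"` (properties straight from the purified predicted 1-RDM),
#' `"gamma+delta_gamma"` (adds the linear gamma-refinement before property
#' evaluation), and `"delta_properties"` (energies/forces from delta-models;
#' the purified 1-RDM remains available).
#'
#' @param gamma_model fitted [fit_gamma()] model.
#' @param flavor model flavor (above).
#' @param delta_refine optional `delta_model` for gamma refinement.
#' @param delta_props optional list from [fit_delta_properties()].
#' @return a `model_stack`.
#' @export
model_stack <- function(gamma_model,
                        flavor = c("gamma", "gamma+delta_gamma",
                                   "delta_properties"),
                        delta_refine = NULL, delta_props = NULL) {
  flavor <- match.arg(flavor)
  if (flavor == "gamma+delta_gamma" && is.null(delta_refine))
    stop("flavor gamma+delta_gamma requires delta_refine")
  if (flavor == "delta_properties" && is.null(delta_props))
    stop("flavor delta_properties requires delta_props")
  structure(list(gamma = gamma_model, flavor = flavor,
                 delta_refine = delta_refine, delta_props = delta_props),
            class = "model_stack")
}

#' @export
print.model_stack <- function(x, ...) {
  cat("<model_stack> flavor=", x$flavor, "; ", sep = "")
  print(x$gamma)
  invisible(x)
}

#' Full surrogate prediction for a lab-frame geometry
#'
#' The end-to-end pipeline: Kabsch-align the geometry to the model's
#' reference frame, build the external potential there, predict the 1-RDM,
#' purify it, optionally apply the gamma-refinement, evaluate energy (and on
#' request forces/properties), and rotate the density back to the lab frame.
#' The purified 1-RDM is always returned, for every flavor.
#'
#' @param stack a [model_stack()].
#' @param g lab-frame [geometry()].
#' @param want_forces also compute forces (see [compute_forces()] for modes).
#' @param force_mode force evaluation mode for non-delta flavors:
#'   `"corrected"` (default) or `"hellmann_feynman"`.
#' @param engine_energy if `TRUE` (default for non-delta flavors) evaluate
#'   the energy functional `E[gamma]` with the engine; delta flavor uses its
#'   energy model and performs no Fock build.
#' @return list: `gamma` (purified, lab frame), `gamma_aligned`, `energy`,
#'   optional `forces` (lab frame), `transform`, `n_fock_builds`.
#' @export
predict_full <- function(stack, g, want_forces = FALSE,
                         force_mode = c("corrected", "hellmann_feynman"),
                         engine_energy = NULL) {
  force_mode <- match.arg(force_mode)
  model <- stack$gamma
  method <- model$method
  al <- align_to_reference(g, model$ref)
  ga <- al$geometry
  v <- pack_symmetric(external_potential_matrix(ga, method))
  raw <- predict_gamma(model, v)
  Sref <- overlap_matrix(ga, method)
  N <- n_electrons(g)
  pur <- purify(raw, Sref, N)
  n_fock <- 0L
  if (stack$flavor == "gamma+delta_gamma") {
    refined <- predict(stack$delta_refine, pack_symmetric(pur))
    pur <- purify(ao_matrix(unpack_symmetric(drop(refined), model$M),
                            role = "density", basis_label = method$basis),
                  Sref, N)
  }
  shells <- basis_shells(ga, method$basis)
  out <- list(transform = al$transform, gamma_aligned = pur)
  if (stack$flavor == "delta_properties") {
    feats <- matrix(pack_symmetric(pur), 1)
    out$energy <- drop(predict(stack$delta_props$energy, feats))
    if (want_forces) {
      if (is.null(stack$delta_props$forces))
        stop("delta_properties stack lacks a force model")
      fv <- drop(predict(stack$delta_props$forces, feats))
      Fal <- matrix(fv, ncol = 3, byrow = TRUE)
      # rotate aligned-frame forces back to the lab frame
      out$forces <- Fal %*% al$transform$rotation
    }
  } else {
    ctx <- engine_context(ga, method)
    out$energy <- energy_from_dm(pur, ga, method, ctx = ctx)
    n_fock <- n_fock + 1L  # energy evaluation builds the two-electron part
    if (want_forces) {
      Fal <- compute_forces(force_mode, stack, ga, method,
                            gamma_purified = pur, ctx = ctx,
                            aligned = TRUE)
      out$forces <- Fal %*% al$transform$rotation
      n_fock <- n_fock + 1L
    }
  }
  # lab-frame density: rotate back with the inverse AO rotation
  inv <- invert_transform(al$transform)
  lab_shells <- basis_shells(g, method$basis)
  out$gamma <- rotate_ao_matrix(pur, inv, lab_shells)
  out$gamma$geometry_fingerprint <- ao_fingerprint(g, method)
  out$n_fock_builds <- n_fock
  out
}
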