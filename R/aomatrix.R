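#' Basis-tagged symmetric AO matrix
#'
#' The common currency of the pipeline: a symmetric matrix in the atomic
#' orbital basis, tagged with its role (external potential, density, Fock,
#' overlap, ...), the basis label and a geometry fingerprint.
#'
#' @param values square numeric matrix; must be symmetric to 1e-10 relative
#'   tolerance.
#' @param role one of `"potential"`, `"density"`, `"fock"`, `"overlap"`,
#'   `"dipole_component"`, `"kinetic"`.
#' @param basis_label basis-set name the matrix is expressed in.
#' @param geometry_fingerprint hash identifying the geometry (see
#'   [ao_fingerprint()]).
#' @return an `ao_matrix`.
#' @export
ao_matrix <- function(values, role = c("potential", "density", "fock",
                                       "overlap", "dipole_component",
                                       "kinetic"),
                      basis_label = "", geometry_fingerprint = "") {
  role <- match.arg(role)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("representation error: AO matrix must be square")
  rel <- max(abs(values - t(values))) / max(1, max(abs(values)))
  if (rel > 1e-10)
    stop("representation error: AO matrix not symmetric (rel. asymmetry ",
         format(rel, digits = 3), ")")
  values <- (values + t(values)) / 2
  structure(list(values = unname(values), role = role,
                 basis_label = basis_label,
                 geometry_fingerprint = geometry_fingerprint),
            class = "ao_matrix")
}

#' @export
print.ao_matrix <- function(x, ...) {
  cat("<ao_matrix> role=", x$role, " M=", nrow(x$values),
      " basis=", x$basis_label, "\n", sep = "")
  invisible(x)
}

ao_values <- function(m) if (inherits(m, "ao_matrix")) m$values else m

#' Fingerprint helper for AO matrices
#' @param g geometry
#' @param method a [method_spec()] (optional)
#' @return character hash
#' @export
ao_fingerprint <- function(g, method = NULL) geometry_fingerprint(g, method)

#' Pack a symmetric matrix into a feature vector
#'
#' Flattens the upper triangle (row-major, diagonal included) of a symmetric
#' M x M matrix into a vector of length M(M+1)/2; each off-diagonal element
#' appears exactly once, so N_features = M(M+1)/2. `unpack_symmetric` is the
#' exact inverse.
#'
#' @param m an `ao_matrix` or symmetric numeric matrix.
#' @return numeric feature vector with attribute `M`.
#' @examples
#' pack_symmetric(diag(2))        # (1, 0, 1)
#' unpack_symmetric(c(1, 2, 3), 2)
#' @export
pack_symmetric <- function(m) {
  v <- ao_values(m)
  if (nrow(v) != ncol(v))
    stop("representation error: input must be square")
  if (max(abs(v - t(v))) > 1e-10 * max(1, max(abs(v))))
    stop("representation error: input must be symmetric")
  M <- nrow(v)
  out <- t(v)[lower.tri(v, diag = TRUE)]  # upper triangle, row-major
  attr(out, "M") <- M
  out
}

#' @rdname pack_symmetric
#' @param v packed feature vector of length M(M+1)/2.
#' @param M matrix dimension.
#' @export
unpack_symmetric <- function(v, M) {
  v <- as.numeric(v)
  if (length(v) != M * (M + 1) / 2)
    stop("representation error: length ", length(v),
         " inconsistent with M = ", M)
  out <- matrix(0, M, M)
  out[lower.tri(out, diag = TRUE)] <- v
  out <- t(out)
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

#' Block-orthogonal AO rotation matrix for a rigid rotation
#'
#' Builds the M x M orthogonal matrix U implementing a rigid rotation R on the
#' AO basis, block-diagonal per shell: s shells are invariant; p shells (in
#' x, y, z component order) transform with the Cartesian rotation itself.
#' Shells with l >= 2 are not supported by the shipped basis sets.
#'
#' @param shells shell list from [basis_shells()].
#' @param rotation 3 x 3 orthogonal matrix with det +1.
#' @return M x M orthogonal matrix.
#' @export
ao_rotation_matrix <- function(shells, rotation) {
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-10 ||
      abs(det(rotation) - 1) > 1e-10)
    stop("rotation must be proper orthogonal (det +1) to 1e-10")
  M <- attr(shells, "M")
  U <- matrix(0, M, M)
  off <- 0L
  for (sh in shells) {
    nc <- (sh$l + 1) * (sh$l + 2) / 2
    # p components transform as a vector; the block is stored transposed so
    # that t(U) %*% m %*% U maps a matrix to the rotated geometry's frame
    blk <- switch(as.character(sh$l),
                  "0" = matrix(1, 1, 1),
                  "1" = t(rotation),
                  stop("AO rotation for l >= 2 shells is not supported"))
    U[off + seq_len(nc), off + seq_len(nc)] <- blk
    off <- off + nc
  }
  U
}

#' Rotate an AO matrix between frames
#'
#' Applies the block-orthogonal AO rotation of a frame transform:
#' `t(U) %*% m %*% U`. With `U = ao_rotation_matrix(shells, R)` this maps a
#' matrix computed at a geometry into the matrix the engine would compute at
#' the R-rotated geometry. Role and basis label are preserved.
#'
#' @param m `ao_matrix` (or plain symmetric matrix).
#' @param t a `frame_transform` (its `rotation` is used), or an M x M
#'   orthogonal matrix directly.
#' @param shells shell list matching `m` (needed when `t` is a 3 x 3 rotation).
#' @return rotated matrix of the same class as the input.
#' @export
rotate_ao_matrix <- function(m, t, shells = NULL) {
  U <- if (is.matrix(t) && nrow(t) > 3) {
    t
  } else {
    R <- if (inherits(t, "frame_transform")) t$rotation else t
    if (is.null(shells)) stop("shells required to build the AO rotation")
    ao_rotation_matrix(shells, R)
  }
  v <- ao_values(m)
  if (nrow(v) != nrow(U))
    stop("representation error: AO rotation dimension mismatch (",
         nrow(U), " vs ", nrow(v), ")")
  out <- t(U) %*% v %*% U
  if (inherits(m, "ao_matrix")) {
    m$values <- (out + t(out)) / 2
    m
  } else out
}
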