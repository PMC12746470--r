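#' Molecular geometry
#'
#' A closed-shell molecular geometry: nuclear charges, Cartesian positions in
#' angstrom, total charge and spin multiplicity. All supported workflows are
#' spin-compensated (multiplicity 1, even electron count).
#'
#' @param symbols character vector of element symbols (alternative to `Z`).
#' @param positions numeric n x 3 matrix of Cartesian coordinates (angstrom).
#' @param Z integer vector of nuclear charges (alternative to `symbols`).
#' @param charge integer total molecular charge.
#' @param multiplicity integer spin multiplicity; must be 1.
#' @return an object of class `geometry` with fields `Z`, `symbols`,
#'   `positions`, `charge`, `multiplicity`, `masses` (amu).
#' @examples
#' g <- geometry(c("O", "H", "H"),
#'               rbind(c(0, 0, 0.117), c(0, 0.757, -0.467), c(0, -0.757, -0.467)))
#' n_electrons(g)
#' @export
geometry <- function(symbols = NULL, positions, Z = NULL, charge = 0L,
                     multiplicity = 1L) {
  if (is.null(Z)) Z <- element_Z(symbols)
  Z <- as.integer(Z)
  if (is.null(symbols)) symbols <- element_symbol(Z)
  positions <- as.matrix(positions)
  if (length(Z) < 1L) stop("geometry needs at least one atom")
  if (!is.numeric(positions) || ncol(positions) != 3L ||
      nrow(positions) != length(Z))
    stop("positions must be a numeric n x 3 matrix matching the atom count")
  if (multiplicity != 1L)
    stop("only closed-shell (multiplicity 1) systems are supported")
  n <- sum(Z) - charge
  if (n %% 2L != 0L)
    stop("odd electron count (", n, "); closed-shell systems only")
  structure(list(Z = Z, symbols = symbols,
                 positions = unname(positions), charge = as.integer(charge),
                 multiplicity = 1L, masses = element_mass(Z)),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat("<geometry> ", paste0(x$symbols, collapse = ""), ": ",
      length(x$Z), " atoms, charge ", x$charge,
      ", ", n_electrons(x), " electrons\n", sep = "")
  invisible(x)
}

#' Number of electrons of a geometry
#' @param g a [geometry()].
#' @return integer electron count.
#' @export
n_electrons <- function(g) sum(g$Z) - g$charge

#' Center of mass (angstrom)
#' @param g a [geometry()].
#' @return length-3 numeric vector.
#' @export
center_of_mass <- function(g) {
  drop(crossprod(g$positions, g$masses)) / sum(g$masses)
}

with_positions <- function(g, positions) {
  g$positions <- unname(as.matrix(positions))
  g
}

geometry_fingerprint <- function(g, method = NULL) {
  v <- c(g$Z, round(g$positions, 10), g$charge)
  s <- paste(format(v, digits = 12), collapse = ",")
  if (!is.null(method)) s <- paste(s, method$functional, method$basis, sep = "|")
  # small stable hash (djb2); enough for frame/basis consistency checks
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%010d", h)
}

#' Mass-weighted RMSD between two geometries (no alignment)
#' @param a,b geometries with identical atom ordering.
#' @return RMSD in angstrom.
#' @export
rmsd <- function(a, b) {
  d <- a$positions - b$positions
  sqrt(sum(a$masses * rowSums(d^2)) / sum(a$masses))
}

#' Kabsch alignment of a geometry onto a reference
#'
#' Finds the rigid rotation + translation minimizing the mass-weighted RMSD to
#' `ref` and returns the moved geometry together with the exact
#' `frame_transform` that maps the input onto it. Atom count and element
#' ordering must match; no permutation matching is attempted.
#'
#' @param g geometry to align.
#' @param ref reference geometry.
#' @return list with `geometry` (aligned), `transform` (a `frame_transform`
#'   with fields `rotation` (3 x 3, det +1), `translation`), and `rmsd`.
#' @export
align_to_reference <- function(g, ref) {
  if (length(g$Z) != length(ref$Z) || any(g$Z != ref$Z))
    stop("alignment error: atom count or element ordering differs from reference")
  w <- g$masses / sum(g$masses)
  cg <- drop(crossprod(g$positions, w))
  cr <- drop(crossprod(ref$positions, w))
  X <- sweep(g$positions, 2, cg)    # moving, centered
  Y <- sweep(ref$positions, 2, cr)  # target, centered
  H <- t(X * w) %*% Y
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  Dm <- diag(c(1, 1, d))
  R <- sv$v %*% Dm %*% t(sv$u)      # aligned row-vectors: x_new = x %*% t(R)
  newpos <- X %*% t(R)
  newpos <- sweep(newpos, 2, cr, "+")
  tr <- structure(list(rotation = R,
                       translation = cr,
                       center = cg),
                  class = "frame_transform")
  out_g <- with_positions(g, newpos)
  list(geometry = out_g, transform = tr, rmsd = rmsd(out_g, ref))
}

#' Apply or invert a frame transform on coordinates
#'
#' `apply_transform` maps lab-frame coordinates into the aligned frame exactly
#' as [align_to_reference()] did; `invert_transform` returns the inverse
#' transform.
#' @param t a `frame_transform`.
#' @param positions n x 3 matrix (angstrom).
#' @return transformed n x 3 matrix (or inverted transform).
#' @export
apply_transform <- function(t, positions) {
  sweep(sweep(positions, 2, t$center) %*% t(t$rotation), 2, t$translation, "+")
}

#' @rdname apply_transform
#' @export
invert_transform <- function(t) {
  structure(list(rotation = t(t$rotation),
                 translation = t$center,
                 center = t$translation),
            class = "frame_transform")
}

identity_transform <- function() {
  structure(list(rotation = diag(3), translation = c(0, 0, 0),
                 center = c(0, 0, 0)),
            class = "frame_transform")
}
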