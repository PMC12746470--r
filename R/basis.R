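# Gaussian basis sets.
#
# STO-3G is generated from the published least-squares STO-nG expansion:
# primitive exponents are fixed fit values scaled by zeta^2 with the standard
# per-element Slater exponents; this construction reproduces the distributed
# STO-3G tables (e.g. O 2sp: 5.033151, 1.169596, 0.380389) to ~1e-5.
# 6-31G is tabulated directly for H, C, N, O.  Heavier elements or basis sets
# with d shells (6-31G*, cc-pVTZ) are not shipped: no basis-set database is
# available to this package, and all bundled workflows use H/C/N/O molecules.

.STO3G_FIT <- list(
  # exponents and coefficients for a zeta = 1 Slater function
  s1 = list(exps = c(2.227660584, 0.405771156, 0.109818),
            coefs = c(0.154328967, 0.535328142, 0.444634542)),
  sp2 = list(exps = c(0.994203, 0.231031, 0.0751386),
             s = c(-0.09996723, 0.39951283, 0.70011547),
             p = c(0.15591627, 0.60768372, 0.39195739))
)

.STO3G_ZETA <- list(
  H = c(z1 = 1.24),
  C = c(z1 = 5.67, z2 = 1.72),
  N = c(z1 = 6.67, z2 = 1.95),
  O = c(z1 = 7.66, z2 = 2.25)
)

.G631 <- list(
  H = list(
    list(l = 0L, exps = c(18.73113696, 2.825394365, 0.6401216923),
         coefs = c(0.03349460434, 0.2347269535, 0.8137573261)),
    list(l = 0L, exps = 0.1612777588, coefs = 1.0)
  ),
  C = list(
    list(l = 0L,
         exps = c(3047.52488, 457.369518, 103.948685, 29.2101553,
                  9.28666296, 3.16392696),
         coefs = c(0.001834737132, 0.01403732281, 0.06884262226,
                   0.2321844432, 0.4679413484, 0.3623119853)),
    list(l = 0L, exps = c(7.86827235, 1.88128854, 0.544249258),
         coefs = c(-0.1193324198, -0.1608541517, 1.143456438)),
    list(l = 1L, exps = c(7.86827235, 1.88128854, 0.544249258),
         coefs = c(0.06899906659, 0.316423961, 0.7443082909)),
    list(l = 0L, exps = 0.1687144782, coefs = 1.0),
    list(l = 1L, exps = 0.1687144782, coefs = 1.0)
  ),
  N = list(
    list(l = 0L,
         exps = c(4173.51146, 627.457911, 142.902093, 40.2343293,
                  12.8202129, 4.39043701),
         coefs = c(0.00183477216, 0.013994627, 0.06858655181,
                   0.232240873, 0.4690699481, 0.3604551991)),
    list(l = 0L, exps = c(11.62636186, 2.716279807, 0.7722183966),
         coefs = c(-0.1149611817, -0.1691174786, 1.145851947)),
    list(l = 1L, exps = c(11.62636186, 2.716279807, 0.7722183966),
         coefs = c(0.06757974388, 0.3239072959, 0.7408951398)),
    list(l = 0L, exps = 0.2120314975, coefs = 1.0),
    list(l = 1L, exps = 0.2120314975, coefs = 1.0)
  ),
  O = list(
    list(l = 0L,
         exps = c(5484.67166, 825.234946, 188.046958, 52.9645,
                  16.8975704, 5.79963534),
         coefs = c(0.00183107443, 0.0139501722, 0.0684450781,
                   0.232714336, 0.470192898, 0.358520853)),
    list(l = 0L, exps = c(15.53961625, 3.599933586, 1.01376175),
         coefs = c(-0.1107775495, -0.1480262627, 1.130767015)),
    list(l = 1L, exps = c(15.53961625, 3.599933586, 1.01376175),
         coefs = c(0.07087426823, 0.3397528391, 0.7271585773)),
    list(l = 0L, exps = 0.2700058226, coefs = 1.0),
    list(l = 1L, exps = 0.2700058226, coefs = 1.0)
  )
)

sto3g_element <- function(symbol) {
  z <- .STO3G_ZETA[[symbol]]
  if (is.null(z)) stop("STO-3G not available for element ", symbol)
  f <- .STO3G_FIT
  out <- list(list(l = 0L, exps = f$s1$exps * z[["z1"]]^2, coefs = f$s1$coefs))
  if (length(z) > 1) {
    out <- c(out, list(
      list(l = 0L, exps = f$sp2$exps * z[["z2"]]^2, coefs = f$sp2$s),
      list(l = 1L, exps = f$sp2$exps * z[["z2"]]^2, coefs = f$sp2$p)
    ))
  }
  out
}

#' Build the contracted-shell list for a geometry
#'
#' Expands a named basis set over the atoms of a geometry into the shell
#' structure consumed by the integral engine (centers in bohr).
#'
#' @param g a [geometry()].
#' @param basis basis-set name: `"STO-3G"` or `"6-31G"`.
#' @return list of shells (`l`, `exps`, `coefs`, `center`, `atom`) plus
#'   attributes `M` (basis dimension) and `basis_label`.
#' @export
basis_shells <- function(g, basis = "STO-3G") {
  key <- toupper(gsub("\\s", "", basis))
  shells <- list()
  for (i in seq_along(g$Z)) {
    sym <- g$symbols[i]
    el <- switch(key,
      "STO-3G" = sto3g_element(sym),
      "6-31G" = {
        b <- .G631[[sym]]
        if (is.null(b)) stop("6-31G not available for element ", sym)
        b
      },
      stop("configuration error: basis set '", basis,
           "' is not resolvable by the engine (available: STO-3G, 6-31G)")
    )
    for (sh in el) {
      sh$center <- g$positions[i, ] * BOHR_PER_ANGSTROM
      sh$atom <- i
      shells[[length(shells) + 1L]] <- sh
    }
  }
  M <- sum(vapply(shells, function(s) (s$l + 1) * (s$l + 2) / 2, 0))
  attr(shells, "M") <- as.integer(M)
  attr(shells, "basis_label") <- basis
  shells
}

#' Basis dimension for a geometry and basis-set name
#' @inheritParams basis_shells
#' @return integer number of basis functions M.
#' @export
basis_dimension <- function(g, basis = "STO-3G") {
  attr(basis_shells(g, basis), "M")
}
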