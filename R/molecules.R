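# Built-in starting geometries (idealized; relax with optimize_geometry()
# before normal-mode analysis).  Coordinates in angstrom.

#' Built-in molecular geometries
#'
#' Idealized starting structures for the molecules used throughout the
#' package: `"water"`, `"ammonia"`, `"co2"`, `"methanol"`, `"benzene"`,
#' `"biphenyl"`. These are not relaxed; pass them through
#' [optimize_geometry()] (or load a relaxed fixture) before sampling.
#'
#' @param name molecule name.
#' @return a [geometry()].
#' @export
builtin_molecule <- function(name) {
  name <- tolower(name)
  switch(name,
    water = geometry(c("O", "H", "H"),
                     rbind(c(0, 0, 0.1173),
                           c(0, 0.7572, -0.4692),
                           c(0, -0.7572, -0.4692))),
    ammonia = geometry(c("N", "H", "H", "H"),
                       rbind(c(0, 0, 0.1111),
                             c(0, 0.9316, -0.2592),
                             c(0.8068, -0.4658, -0.2592),
                             c(-0.8068, -0.4658, -0.2592))),
    co2 = geometry(c("C", "O", "O"),
                   rbind(c(0, 0, 0), c(0, 0, 1.16), c(0, 0, -1.16))),
    methanol = geometry(c("C", "O", "H", "H", "H", "H"),
                        rbind(c(-0.0503, 0.6685, 0),
                              c(-0.0503, -0.7585, 0),
                              c(0.9408, 1.1188, 0),
                              c(-0.5807, 1.0282, 0.8862),
                              c(-0.5807, 1.0282, -0.8862),
                              c(-0.8539, -1.0621, 0))),  # OH anti to the in-plane CH (staggered minimum)
    benzene = {
      ang <- seq(0, 300, by = 60) * pi / 180
      pos <- rbind(cbind(1.39 * cos(ang), 1.39 * sin(ang), 0),
                   cbind(2.47 * cos(ang), 2.47 * sin(ang), 0))
      geometry(c(rep("C", 6), rep("H", 6)), pos)
    },
    biphenyl = {
      # two para-linked phenyl rings, ipso carbons on the x axis, ring B
      # twisted about x by 45 degrees (near the known equilibrium dihedral)
      half <- 1.48 / 2 + 1.39
      ringA <- (0:5) * 60 * pi / 180            # ipso at angle 0 (+x side)
      ringB <- ringA + pi                       # ipso at angle 180
      twist <- 45 * pi / 180
      rotx <- function(p, th) cbind(p[, 1], p[, 2] * cos(th) - p[, 3] * sin(th),
                                    p[, 2] * sin(th) + p[, 3] * cos(th))
      cA <- cbind(1.39 * cos(ringA) - half, 1.39 * sin(ringA), 0)
      hA <- cbind(2.47 * cos(ringA[-1]) - half, 2.47 * sin(ringA[-1]), 0)
      cB0 <- cbind(1.39 * cos(ringB), 1.39 * sin(ringB), 0)
      hB0 <- cbind(2.47 * cos(ringB[-1]), 2.47 * sin(ringB[-1]), 0)
      cB <- sweep(rotx(cB0, twist), 2, c(half, 0, 0), "+")
      hB <- sweep(rotx(hB0, twist), 2, c(half, 0, 0), "+")
      geometry(c(rep("C", 12), rep("H", 10)), rbind(cA, cB, hA, hB))
    },
    stop("unknown builtin molecule: ", name)
  )
}
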