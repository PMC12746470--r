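# Physical constants (CODATA 2018) and element data.
# Internal unit policy: hartree atomic units for all electronic-structure
# quantities; geometry I/O in angstrom; MD uses angstrom / femtosecond / amu;
# forces are reported in Ha/angstrom.

BOHR_PER_ANGSTROM <- 1 / 0.529177210903
ANGSTROM_PER_BOHR <- 0.529177210903
HARTREE_PER_KCALMOL <- 1 / 627.509474063
KCALMOL_PER_HARTREE <- 627.509474063
EV_PER_HARTREE <- 27.211386245988
KB_HARTREE <- 3.166811563e-6        # Boltzmann constant, Ha / K
AMU_PER_ME <- 1 / 1822.888486209    # electron masses per amu
ME_PER_AMU <- 1822.888486209
AU_FREQ_TO_CM1 <- 219474.6313632    # hartree-au angular frequency -> cm^-1

# acceleration constant: a[A/fs^2] = F[Ha/A] / m[amu] * MD_ACC
# derived from Ha = 4.3597447222071e-18 J, amu = 1.66053906660e-27 kg
MD_ACC <- 4.3597447222071e-18 / 1.66053906660e-27 * 1e-30 / 1e-20
# kinetic energy: E[Ha] = 0.5 * m[amu] * v[A/fs]^2 / MD_ACC

ELEMENTS <- data.frame(
  symbol = c("H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne"),
  Z = 1:10,
  # most-abundant-isotope masses (amu), the normal-mode convention
  mass = c(1.00782503207, 4.002603254, 7.01600455, 9.0121822, 11.0093054,
           12.0, 14.0030740048, 15.99491461956, 18.99840322, 19.9924401754),
  stringsAsFactors = FALSE
)

element_Z <- function(symbols) {
  idx <- match(symbols, ELEMENTS$symbol)
  if (anyNA(idx)) stop("unknown element symbol: ",
                       paste(symbols[is.na(idx)], collapse = ", "))
  ELEMENTS$Z[idx]
}

element_symbol <- function(Z) {
  idx <- match(Z, ELEMENTS$Z)
  if (anyNA(idx)) stop("unsupported atomic number: ",
                       paste(Z[is.na(idx)], collapse = ", "))
  ELEMENTS$symbol[idx]
}

element_mass <- function(Z) {
  idx <- match(Z, ELEMENTS$Z)
  if (anyNA(idx)) stop("unsupported atomic number: ",
                       paste(Z[is.na(idx)], collapse = ", "))
  ELEMENTS$mass[idx]
}
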