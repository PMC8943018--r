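## Internal unit system: lengths in Angstrom, charges in e0, energies in eV,
## electric fields in V/Angstrom, time in fs, masses in amu.

# Coulomb constant, eV*Angstrom/e0^2
KE <- 14.399645
# Boltzmann constant, eV/K
KB <- 8.617333262e-5
# Bohr radius, Angstrom
BOHR <- 0.529177210903
# 1 e0*Angstrom in Debye
DEBYE_PER_EA <- 4.80321
# acceleration in Angstrom/fs^2 per (eV/Angstrom)/amu
ACC_CONV <- 9.64853322e-3

ATOMIC_MASSES <- c(O = 15.999, H = 1.008)

#' Physical constants used internally
#'
#' Returns the constants that define the package's internal unit system
#' (Angstrom, e0, eV, V/Angstrom, fs, amu).
#'
#' @return Named list: `ke` (Coulomb constant, eV A/e0^2), `kb` (eV/K),
#'   `bohr` (A), `debye_per_eA` (Debye per e0 A), `acc_conv`
#'   (A/fs^2 per (eV/A)/amu).
#' @export
scfnn_constants <- function() {
  list(ke = KE, kb = KB, bohr = BOHR, debye_per_eA = DEBYE_PER_EA,
       acc_conv = ACC_CONV)
}
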