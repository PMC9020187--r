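# Internal unit system: kJ/mol, nm, ps, amu, K, bar (GROMACS-style units).

# Boltzmann constant, kJ mol^-1 K^-1
.kB <- 0.0083144621

# kJ mol^-1 nm^-3  ->  bar
.PRESS_UNIT <- 16.6054

# amu -> g (1 / Avogadro)
.AMU_G <- 1.66053907e-24

# nm^3 -> cm^3
.NM3_CM3 <- 1e-21

#' Physical constants used by the simulator
#'
#' Returns the constants of the internal unit system (kJ/mol, nm, ps, amu,
#' K, bar) so that analysis code outside the package can reproduce unit
#' conversions exactly.
#'
#' @return Named list with `kB` (kJ mol^-1 K^-1), `pressure_unit`
#'   (conversion kJ mol^-1 nm^-3 to bar), `amu_to_g`, and `nm3_to_cm3`.
#' @export
cg_constants <- function() {
  list(kB = .kB, pressure_unit = .PRESS_UNIT,
       amu_to_g = .AMU_G, nm3_to_cm3 = .NM3_CM3)
}
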