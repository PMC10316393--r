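## Physical constants and unit conversions used across the package.
## Energies kJ/mol, lengths nm, charges e, volumes bohr^3 unless stated.

#' Physical constants used by the package
#'
#' Fixed conversion constants: 1 hartree = 2625.4996 kJ/mol,
#' 1 bohr = 0.052917721 nm, Boltzmann constant 0.0083144621 kJ/(mol K),
#' Avogadro constant 6.02214076e23 1/mol.
#'
#' @return Named list with elements `hartree_kjmol`, `bohr_nm`,
#'   `kb_kjmol`, `avogadro`.
#' @examples
#' ff_constants()$bohr_nm
#' @export
ff_constants <- function() {
  list(
    hartree_kjmol = 2625.4996,
    bohr_nm       = 0.052917721,
    kb_kjmol      = 0.0083144621,
    avogadro      = 6.02214076e23
  )
}

## 1 Ha bohr^6 expressed in kJ mol^-1 nm^6 (dispersion coefficient units)
.ha_bohr6_to_kjmol_nm6 <- function() {
  k <- ff_constants()
  k$hartree_kjmol * k$bohr_nm^6
}

## kJ mol^-1 nm^-2 -> J m^-2 (per-area enthalpies)
.kjmol_nm2_to_J_m2 <- function(x) {
  k <- ff_constants()
  x * 1000 / k$avogadro / 1e-18
}
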