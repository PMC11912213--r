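#' Hartree to kcal/mol conversion factor
#' @export
HARTREE_KCAL <- 627.509

#' Boltzmann-weighted ensemble free energy
#'
#' `-k_B T ln sum_i exp(-G_i / k_B T)`, evaluated with a max-shift so very
#' deep or very shallow conformers cannot overflow. The result is bracketed
#' by `min(G) - k_B T ln(n) <= G_ens <= min(G)`.
#'
#' @param G_list per-structure free energies, kcal/mol
#' @param temperature kelvin
#' @param k_B Boltzmann constant, kcal/(mol K)
#' @return scalar kcal/mol
#' @export
boltzmann_ensemble_G <- function(G_list, temperature = 300, k_B = KB_KCAL) {
  stopifnot(length(G_list) >= 1, all(is.finite(G_list)), temperature > 0)
  kt <- k_B * temperature
  g0 <- min(G_list)
  g0 - kt * log(sum(exp(-(G_list - g0) / kt)))
}

#' Ensemble hydration free energy
#'
#' The Gibbs free energy of transferring the solute from the gas phase into
#' water: the Boltzmann-weighted ensemble free energy in implicit solvent
#' minus that in the gas phase. More negative values mean the molecule
#' prefers to be surrounded by water, i.e. better solubility.
#'
#' @param G_solv,G_gas per-structure free energies in the two phases (equal
#'   lengths), in `unit`
#' @param temperature kelvin (weighting temperature)
#' @param unit `"kcal/mol"` or `"hartree"` (converted with [HARTREE_KCAL])
#' @return Delta G_hyd in kcal/mol
#' @export
hydration_free_energy <- function(G_solv, G_gas, temperature = 300,
                                  unit = c("kcal/mol", "hartree")) {
  unit <- match.arg(unit)
  stopifnot(length(G_solv) == length(G_gas), length(G_solv) >= 1)
  if (unit == "hartree") {
    G_solv <- G_solv * HARTREE_KCAL
    G_gas <- G_gas * HARTREE_KCAL
  }
  boltzmann_ensemble_G(G_solv, temperature) -
    boltzmann_ensemble_G(G_gas, temperature)
}

#' Per-residue normalization of an extensive energy
#'
#' Divides a whole-molecule value by the number of residues so peptides of
#' different length can be compared (hydrophobicity, and with it the surface
#' term of implicit solvation, grows with chain length).
#'
#' @param value kcal/mol
#' @param n_residues positive integer
#' @return kcal/mol per residue
#' @export
per_residue_normalize <- function(value, n_residues) {
  stopifnot(n_residues > 0)
  value / n_residues
}

#' Unit conversion helpers
#' @param x energy values
#' @return converted values
#' @export
hartree_to_kcal <- function(x) x * HARTREE_KCAL

#' @rdname hartree_to_kcal
#' @export
kcal_to_hartree <- function(x) x / HARTREE_KCAL
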