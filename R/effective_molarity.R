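#' Competitor concentration at which direct-transfer flux overtakes
#' intrinsic dissociation
#'
#' For a complex dissociating at `k_minus1` (s^-1) and transferring to a
#' competitor at `k_theta` (M^-1 s^-1), the pseudo-first-order transfer rate
#' `k_theta * [C]` equals the intrinsic dissociation rate at the crossover
#' concentration `[C]* = k_minus1 / k_theta = 1 / (k_theta / k_minus1)`.
#' Above this effective molarity, flux through the direct-transfer pathway
#' exceeds classic dissociation. Typical protein-nucleic-acid values of
#' `k_theta / k_minus1 ~ 1e5 M^-1` put the crossover near 10 uM.
#'
#' @param k_minus1 Intrinsic dissociation rate constant (s^-1), or `NULL`
#'   when `ratio` is given directly.
#' @param k_theta Direct-transfer rate constant (M^-1 s^-1).
#' @param ratio Alternative specification: the ratio `k_theta / k_minus1`
#'   (M^-1).
#' @return Crossover competitor concentration (M).
#' @examples
#' flux_crossover(ratio = 1e5)          # 1e-5 M = 10 uM
#' flux_crossover(9.1e-5, 260)          # dsDNA self-competition: ~0.35 uM
#' @export
flux_crossover <- function(k_minus1 = NULL, k_theta = NULL, ratio = NULL) {
  if (!is.null(ratio)) {
    stopifnot(ratio > 0)
    return(1 / ratio)
  }
  stopifnot(is.numeric(k_minus1), is.numeric(k_theta),
            k_minus1 >= 0, k_theta > 0)
  k_minus1 / k_theta
}

#' Convert a nucleotide concentration to a polynucleotide species
#' concentration
#'
#' The nucleotide concentration of RNA in a cell nucleus is ~1 mM; expressed
#' as discrete n-mer species this corresponds to `[nt] / n` molar species
#' concentration (e.g. ~50 uM of a 20-nt RNA).
#'
#' @param nt_conc Total nucleotide concentration (M).
#' @param length_nt Length of the polynucleotide species (nt).
#' @return Species (molecule) concentration (M).
#' @examples
#' nucleotides_to_species(1e-3, 20)   # 5e-5 M = 50 uM
#' @export
nucleotides_to_species <- function(nt_conc, length_nt) {
  stopifnot(nt_conc >= 0, length_nt >= 1)
  nt_conc / length_nt
}
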