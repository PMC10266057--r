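#' Parameters for the competitive (PRC2-like) HMTase scheme
#'
#' Defaults are the empirically determined constants for PRC2: off-rates
#' and transfer constants from the self- and cross-competition
#' measurements, affinities from the equilibrium titrations, and the
#' literature EZH2 methylation rate constant. `k1N`/`k1R` are derived from
#' `k_minus1 / Kd`.
#'
#' @param k_minus1N,k_minus1R Dissociation rate constants (s^-1).
#' @param k_thetaN Direct-transfer constant, RNA-bound enzyme + nucleosome
#'   (M^-1 s^-1).
#' @param k_thetaR Direct-transfer constant, nucleosome-bound enzyme + RNA.
#' @param k_thetaNN Nucleosome-to-nucleosome self-transfer constant.
#' @param KdN,KdR Equilibrium dissociation constants (M).
#' @param k_cat Methylation rate constant (s^-1).
#' @param N_T Total nucleosome concentration (M).
#' @param E_T Total enzyme concentration (M); default 2 x KdN.
#' @param alpha Effective-molarity tuning for RNA-nucleosome direct-transfer
#'   reactions (dimensionless; 1 = free solution).
#' @param t_end Simulated reaction span (s); default 7200 s, the
#'   experimental 120-min observation window.
#' @return `prc2_params` object (a named list).
#' @export
prc2_params <- function(k_minus1N = 9.1e-5, k_minus1R = 1.7e-3,
                        k_thetaN = 91, k_thetaR = 170, k_thetaNN = 260,
                        KdN = 5.1e-9, KdR = 2.3e-9, k_cat = 0.1,
                        N_T = 5e-9, E_T = 2 * KdN, alpha = 1,
                        t_end = 7200) {
  p <- list(k_minus1N = k_minus1N, k_minus1R = k_minus1R,
            k_thetaN = k_thetaN, k_thetaR = k_thetaR,
            k_thetaNN = k_thetaNN, KdN = KdN, KdR = KdR, k_cat = k_cat,
            N_T = N_T, E_T = E_T, alpha = alpha, t_end = t_end)
  stopifnot(all(vapply(p, function(v) is.numeric(v) && v >= 0, logical(1))))
  structure(p, class = "prc2_params")
}

#' Parameters for the independent (cobinder, YY1-like) binding scheme
#'
#' Defaults use the reported YY1-consistent affinities (KdR = 400 nM,
#' KdN = 200 nM), a typical association rate constant k1 = 1e5 M^-1 s^-1
#' with `k_minus1 = Kd * k1`, and the same methylation rate constant as the
#' competitive scheme. The tuning parameters are: `alpha` — effective
#' molarity for ternary-complex formation; `beta` — effect of bound RNA on
#' catalysis (1 = none, 0 = fully suppressed); `delta1` — effect of the
#' prior ligand on ternary association; `delta2N`/`delta2R` — effects on
#' nucleosome/RNA dissociation from the ternary complex.
#'
#' @param KdR,KdN Equilibrium dissociation constants (M).
#' @param k1 Association rate constant for both pairs (M^-1 s^-1).
#' @param k_cat Methylation rate constant (s^-1); 0 for the
#'   transcription-factor (binding-only) readout.
#' @param N_T,E_T Totals (M); default E_T = 0.125 x KdN (the protein level
#'   shown for this scheme's time courses).
#' @param alpha,beta,delta1,delta2N,delta2R Dimensionless tuning parameters.
#' @param t_end Simulated reaction span (s).
#' @return `cobinder_params` object.
#' @export
cobinder_params <- function(KdR = 400e-9, KdN = 200e-9, k1 = 1e5,
                            k_cat = 0.1, N_T = 5e-9, E_T = 0.125 * KdN,
                            alpha = 1, beta = 1, delta1 = 1,
                            delta2N = 1, delta2R = 1, t_end = 7200) {
  p <- list(KdR = KdR, KdN = KdN, k1 = k1,
            k_minus1R = KdR * k1, k_minus1N = KdN * k1, k_cat = k_cat,
            N_T = N_T, E_T = E_T, alpha = alpha, beta = beta,
            delta1 = delta1, delta2N = delta2N, delta2R = delta2R,
            t_end = t_end)
  stopifnot(all(vapply(p, function(v) is.numeric(v) && v >= 0, logical(1))),
            beta <= 1)
  structure(p, class = "cobinder_params")
}

#' @export
print.prc2_params <- function(x, ...) {
  cat("<prc2_params>\n")
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' @export
print.cobinder_params <- function(x, ...) {
  cat("<cobinder_params>\n")
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Parameter presets for the published ablation studies
#'
#' Returns scheme parameters with the printed modifications applied:
#' \describe{
#'   \item{S5_unstable_rna}{competitive scheme; destabilized enzyme-RNA
#'     complex (`k_minus1R = 1.7e6 s^-1`, `KdR = 2.3 M`) — all RNA effects
#'     ablated.}
#'   \item{S6_no_transfer}{competitive scheme; all transfer constants 0 —
#'     RNA-mediated rate boosts ablated.}
#'   \item{S7_beta_sweep}{cobinder scheme; defaults, with the catalytic
#'     suppression sweep `beta = 0, 0.25, 0.5, 0.75, 1` attached as
#'     attribute `beta_grid`.}
#'   \item{S8_no_ternary}{cobinder scheme; `delta1 = 0`, ternary-complex
#'     formation prevented.}
#'   \item{S9D}{cobinder, binding-only (`k_cat = 0`); mildly unstable
#'     ternary complex without ligand bias (`delta1 = 0.1`,
#'     `delta2N = delta2R = 1e2`).}
#'   \item{S9E}{as S9D but biased toward RNA dissociation
#'     (`delta2N = 1e4`, `delta2R = 1e6`) — RNA-mediated recruitment.}
#'   \item{S9F}{as S9D but biased toward nucleosome dissociation
#'     (`delta2N = 1e6`, `delta2R = 1e4`) — RNA-mediated inhibition.}
#'   \item{S10_unstable_ternary}{cobinder with catalysis; million-fold
#'     destabilized ternary complex (`delta1 = 0.1`, `delta2 = 1e5`) —
#'     still allows RNA facilitation.}
#' }
#'
#' @param name Preset name.
#' @return A `prc2_params` or `cobinder_params` object.
#' @export
ablation_preset <- function(name) {
  switch(name,
    S5_unstable_rna = prc2_params(k_minus1R = 1.7e6, KdR = 2.3),
    S6_no_transfer = prc2_params(k_thetaN = 0, k_thetaR = 0, k_thetaNN = 0),
    S7_beta_sweep = structure(cobinder_params(),
                              beta_grid = c(0, 0.25, 0.5, 0.75, 1)),
    S8_no_ternary = cobinder_params(delta1 = 0),
    S9D = cobinder_params(k_cat = 0, delta1 = 1e-1,
                          delta2N = 1e2, delta2R = 1e2),
    S9E = cobinder_params(k_cat = 0, delta1 = 1e-1,
                          delta2N = 1e4, delta2R = 1e6),
    S9F = cobinder_params(k_cat = 0, delta1 = 1e-1,
                          delta2N = 1e6, delta2R = 1e4),
    S10_unstable_ternary = cobinder_params(delta1 = 1e-1,
                                           delta2N = 1e5, delta2R = 1e5),
    stop("unknown preset '", name, "'")
  )
}
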