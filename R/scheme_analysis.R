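.prc2_network <- function(params) {
  k1N <- params$k_minus1N / params$KdN
  k1R <- params$k_minus1R / params$KdR
  build_scheme("prc2",
               c(k1N = k1N, k_minus1N = params$k_minus1N,
                 k1R = k1R, k_minus1R = params$k_minus1R,
                 k_thetaN = params$k_thetaN, k_thetaR = params$k_thetaR,
                 k_thetaNN = params$k_thetaNN, k_cat = params$k_cat),
               tuning = list(alpha = params$alpha))
}

.cobinder_network <- function(params) {
  build_scheme("cobinder",
               c(k1N = params$k1, k_minus1N = params$k_minus1N,
                 k1R = params$k1, k_minus1R = params$k_minus1R,
                 k_cat = params$k_cat),
               tuning = list(alpha = params$alpha, beta = params$beta,
                             delta1 = params$delta1,
                             delta2N = params$delta2N,
                             delta2R = params$delta2R))
}

# Shared simulation driver: initial state (all free at t = 0, or the
# catalysis-off binding pre-equilibrium), integration over a grid whose
# points include the 5% initial-rate window boundary, and V0 extraction.
.run_scheme <- function(network, params, rna_nuc_ratio, preequilibrate,
                        n_out, window_frac = 0.05) {
  stopifnot(rna_nuc_ratio >= 0)
  R_T <- rna_nuc_ratio * params$N_T
  totals <- c(E = params$E_T, R = R_T, N = params$N_T)
  if (preequilibrate) {
    net0 <- network
    net0$constants[["k_cat"]] <- 0
    init <- equilibrium_state(net0, totals)
  } else {
    init <- totals
  }
  # grid step divides the V0 window so its endpoint is an exact grid point
  n_out <- 20 * ceiling((n_out - 1) / 20) + 1
  tg <- seq(0, params$t_end, length.out = n_out)
  traj <- integrate_network(network, init, tg)
  m <- traj$conc[, "Nm"]
  t_win <- window_frac * params$t_end
  i_win <- which.min(abs(traj$time - t_win))
  v0 <- (m[i_win] - m[1]) / (traj$time[i_win] - traj$time[1])
  v0res <- structure(list(V0 = v0, window_frac = window_frac,
                          rna_nuc_ratio = rna_nuc_ratio,
                          alpha = params$alpha,
                          m_T = data.frame(time_s = traj$time,
                                           m_T_M = as.numeric(m))),
                     class = "v0_result")
  list(trajectory = traj, v0 = v0res)
}

#' @export
print.v0_result <- function(x, ...) {
  cat(sprintf("<v0_result> V0 = %.4g M/s over first %.0f%% of span (ratio %g, alpha %g)\n",
              x$V0, 100 * x$window_frac, x$rna_nuc_ratio, x$alpha))
  invisible(x)
}

#' Simulate the competitive (PRC2-like) HMTase scheme
#'
#' Integrates the competitive RNA/nucleosome binding scheme with direct
#' transfer and catalysis, and computes the initial methylation rate V0 as
#' the average rate of change of total methylated nucleosome during the
#' first 5% of the simulated span.
#'
#' @param params [prc2_params()].
#' @param rna_nuc_ratio RNA:nucleosome molar ratio (R_T = ratio * N_T).
#' @param preequilibrate Start from the catalysis-off binding equilibrium
#'   instead of all species free at t = 0.
#' @param n_out Number of output time points.
#' @return List with `trajectory` and `v0` (a `v0_result`).
#' @export
simulate_hmtase <- function(params = prc2_params(), rna_nuc_ratio = 0,
                            preequilibrate = FALSE, n_out = 401) {
  stopifnot(inherits(params, "prc2_params"))
  .run_scheme(.prc2_network(params), params, rna_nuc_ratio,
              preequilibrate, n_out)
}

#' Simulate the independent-binding (cobinder) scheme
#'
#' @inheritParams simulate_hmtase
#' @param params [cobinder_params()].
#' @return List with `trajectory` and `v0`.
#' @export
simulate_cobinder <- function(params = cobinder_params(), rna_nuc_ratio = 0,
                              preequilibrate = FALSE, n_out = 401) {
  stopifnot(inherits(params, "cobinder_params"))
  .run_scheme(.cobinder_network(params), params, rna_nuc_ratio,
              preequilibrate, n_out)
}

.simulate_any <- function(params, ratio, preequilibrate, n_out = 401) {
  if (inherits(params, "prc2_params"))
    simulate_hmtase(params, ratio, preequilibrate, n_out)
  else simulate_cobinder(params, ratio, preequilibrate, n_out)
}

#' Relative initial-rate surface over alpha / RNA:Nuc ratio / protein level
#'
#' For each protein level (expressed as a multiple of KdN) and each
#' effective-molarity value alpha, simulates the scheme across RNA:Nuc
#' ratios and reports V0 relative to the RNA-free baseline of the same
#' protein level. Values < 1 mean RNA antagonizes activity; > 1 mean RNA
#' facilitates it.
#'
#' @param params [prc2_params()] or [cobinder_params()].
#' @param alphas Effective-molarity values to scan.
#' @param ratios RNA:Nuc molar ratios (0 is added internally for the
#'   baseline).
#' @param protein_levels Protein totals as multiples of KdN.
#' @param preequilibrate Passed to the simulators.
#' @param n_out Output time points per simulation.
#' @return data.frame with columns `E_mult`, `alpha`, `ratio`, `V0`,
#'   `relV0`.
#' @export
relative_v0_grid <- function(params,
                             alphas = c(1, 5, 10, 50, 100, 500),
                             ratios = c(1, 2, 4, 8),
                             protein_levels = 2,
                             preequilibrate = FALSE, n_out = 201) {
  stopifnot(length(alphas) > 0, length(ratios) > 0,
            length(protein_levels) > 0)
  out <- list()
  for (em in protein_levels) {
    p0 <- params
    p0$E_T <- em * params$KdN
    base <- .simulate_any(p0, 0, preequilibrate, n_out)$v0$V0
    for (a in alphas) {
      pa <- p0
      pa$alpha <- a
      for (r in ratios) {
        v0 <- .simulate_any(pa, r, preequilibrate, n_out)$v0$V0
        out[[length(out) + 1L]] <- data.frame(
          E_mult = em, alpha = a, ratio = r, V0 = v0,
          relV0 = if (r == 0) 1 else v0 / base)
      }
    }
  }
  do.call(rbind, out)
}

#' Nucleosome occupancy of a binding-only (transcription-factor) cobinder
#'
#' With catalysis disabled (`k_cat = 0`), the cobinder scheme reads out as
#' nucleosome occupancy, `([EN] + [ERN]) / N_T`, the chromatin-binding
#' activity of an RNA-binding transcription factor.
#'
#' @param params [cobinder_params()] with `k_cat = 0`.
#' @param rna_nuc_ratio RNA:Nuc molar ratio.
#' @param preequilibrate Passed to the simulator.
#' @param n_out Output time points.
#' @return List with `occupancy` (data.frame `time_s`, `occupancy`) and
#'   `steady_state` (occupancy at the final time point).
#' @export
rbtf_occupancy <- function(params, rna_nuc_ratio = 0,
                           preequilibrate = FALSE, n_out = 401) {
  stopifnot(inherits(params, "cobinder_params"))
  if (params$k_cat != 0) stop("rbtf_occupancy requires k_cat = 0")
  sim <- simulate_cobinder(params, rna_nuc_ratio, preequilibrate, n_out)
  conc <- sim$trajectory$conc
  occ <- (conc[, "EN"] + conc[, "ERN"]) / params$N_T
  list(occupancy = data.frame(time_s = sim$trajectory$time,
                              occupancy = as.numeric(occ)),
       steady_state = occ[length(occ)],
       trajectory = sim$trajectory)
}
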