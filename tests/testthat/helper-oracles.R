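# Independently coded oracles the package implementations are checked
# against. These deliberately avoid build_scheme()/integrate_network():
# the derivative below is written out by hand for the two-reaction
# classic-competition system.

# PL(t) for P + L <-> PL, P + C <-> PC (no direct transfer)
oracle_classic_PL <- function(k1P, km1P, k1C, km1C, init, times) {
  deriv <- function(t, y, p) {
    vPL <- k1P * y[["P"]] * y[["L"]] - km1P * y[["PL"]]
    vPC <- k1C * y[["P"]] * y[["C"]] - km1C * y[["PC"]]
    list(c(-vPL - vPC, -vPL, -vPC, vPL, vPC))
  }
  out <- deSolve::ode(y = init[c("P", "L", "C", "PL", "PC")], times = times,
                      func = deriv, parms = NULL, method = "lsoda",
                      atol = 1e-16, rtol = 1e-10)
  as.numeric(out[, "PL"])
}

# closed-form simple linear regression (slope, intercept)
oracle_ols <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  m <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  c(m = m, b = (sy - m * sx) / n)
}

# exact equilibrium [PL] of a single pair with ligand depletion
oracle_quadratic_PL <- function(P_T, L_T, Kd) {
  s <- P_T + L_T + Kd
  (s - sqrt(s^2 - 4 * P_T * L_T)) / 2
}

# minimal hand-built plate_table for IO / normalization unit tests
mk_plate <- function(df, metadata = list(plate_type = "fpcd",
                                         ligand = "L", competitor = "C",
                                         buffer = "BB_10")) {
  structure(df, class = c("plate_table", "data.frame"), metadata = metadata)
}
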