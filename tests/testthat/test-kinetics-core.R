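test_that("complete_rate_constants fills the missing member of each pair", {
  rcs <- rate_constant_set(list(EN = list(k_minus1 = 9.1e-5, Kd = 5.1e-9)))
  out <- complete_rate_constants(rcs)
  expect_equal(out$pairs$EN$k1, 9.1e-5 / 5.1e-9, tolerance = 1e-12)
  expect_equal(out$pairs$EN$k1, 1.784e4, tolerance = 1e-3)

  rcs <- rate_constant_set(list(ER = list(k1 = 1e5, Kd = 400e-9)))
  expect_equal(complete_rate_constants(rcs)$pairs$ER$k_minus1, 0.04)

  rcs <- rate_constant_set(list(PL = list(k1 = 1, k_minus1 = 0)))
  expect_identical(complete_rate_constants(rcs)$pairs$PL$Kd, 0)
})

test_that("complete_rate_constants rejects bad pairs", {
  expect_error(
    complete_rate_constants(rate_constant_set(list(PL = list(k1 = 1)))),
    "underdetermined pair")
  expect_error(
    complete_rate_constants(rate_constant_set(
      list(PL = list(k1 = 1e5, k_minus1 = 1e-3, Kd = 5e-9)))),
    "inconsistent constants")
  # a consistent triple passes untouched
  out <- complete_rate_constants(rate_constant_set(
    list(PL = list(k1 = 1e5, k_minus1 = 1e-3, Kd = 1e-8))))
  expect_equal(out$pairs$PL$Kd, 1e-8)
})

test_that("rate_constant_set validates its inputs", {
  expect_error(rate_constant_set(list(list(k1 = 1))), "must be named")
  expect_error(rate_constant_set(list(PL = list(bogus = 1))), "unknown field")
  expect_error(rate_constant_set(list(PL = list(k1 = -1))), "non-negative")
  expect_error(rate_constant_set(k_theta = c(1, 2)), "must be named")
})

test_that("build_scheme rejects unknown schemes and missing constants", {
  expect_error(build_scheme("nope", c(k1P = 1)), "unknown scheme_id")
  expect_error(build_scheme("fpcd", c(k1P = 1, k_minus1P = 1)),
               "missing constant")
})

test_that("fpcd scheme with k_theta = 0 matches an independent competition oracle", {
  k1 <- 9.1e-5 / 5.1e-9
  net <- build_scheme("fpcd", c(k1P = k1, k_minus1P = 9.1e-5,
                                k1C = k1, k_minus1C = 9.1e-5,
                                k_thetaD = 0, k_thetaL = 0))
  PL0 <- oracle_quadratic_PL(1e-7, 5e-9, 5.1e-9)
  init <- c(P = 1e-7 - PL0, L = 5e-9 - PL0, C = 1e-6, PL = PL0, PC = 0)
  tg <- seq(0, 7200, by = 300)
  traj <- integrate_network(net, init, tg)
  ref <- oracle_classic_PL(k1, 9.1e-5, k1, 9.1e-5, init, tg)
  expect_equal(as.numeric(traj$conc[, "PL"]), ref, tolerance = 1e-6)
})

test_that("integration from an equilibrium initial condition is a fixed point", {
  k1 <- 1e-3 / 5e-9
  net <- build_scheme("fpcd", c(k1P = k1, k_minus1P = 1e-3,
                                k1C = k1, k_minus1C = 1e-3,
                                k_thetaD = 100, k_thetaL = 100))
  eq <- equilibrium_state(net, c(P = 1e-7, L = 5e-9, C = 5e-9))
  traj <- integrate_network(net, eq, seq(0, 7200, by = 600))
  for (sp in colnames(traj$conc)) {
    span <- diff(range(traj$conc[, sp]))
    expect_lt(span, 1e-6 * max(eq[sp], 1e-15))
  }
})

test_that("PL decay with rebinding blocked is a single exponential", {
  net <- build_scheme("fpcd", c(k1P = 0, k_minus1P = 2e-3,
                                k1C = 0, k_minus1C = 2e-3,
                                k_thetaD = 0, k_thetaL = 0))
  tg <- seq(0, 3600, by = 60)
  traj <- integrate_network(net, c(PL = 4e-9), tg)
  expect_equal(as.numeric(traj$conc[, "PL"]), 4e-9 * exp(-2e-3 * tg),
               tolerance = 1e-7)
})

test_that("pseudo-first-order limit: PL decays at ~ k_minus1P + k_thetaD * [C]", {
  k1 <- 9.1e-5 / 5.1e-9
  net <- build_scheme("fpcd", c(k1P = k1, k_minus1P = 9.1e-5,
                                k1C = k1, k_minus1C = 9.1e-5,
                                k_thetaD = 260, k_thetaL = 260))
  PL0 <- oracle_quadratic_PL(1e-7, 5e-9, 5.1e-9)
  init <- c(P = 1e-7 - PL0, L = 5e-9 - PL0, C = 1e-5, PL = PL0, PC = 0)
  tg <- seq(0, 2400, by = 30)
  traj <- integrate_network(net, init, tg)
  fit <- fit_decay(data.frame(time_s = tg,
                              y = as.numeric(traj$conc[, "PL"]) / PL0))
  expect_equal(fit$lambda, 9.1e-5 + 260 * 1e-5, tolerance = 0.02)
})

test_that("integrate_network validates inputs and reports diagnostics", {
  net <- build_scheme("fpcd", c(k1P = 1e4, k_minus1P = 1e-3,
                                k1C = 1e4, k_minus1C = 1e-3,
                                k_thetaD = 0, k_thetaL = 0))
  expect_error(integrate_network(net, c(PL = 1e-9), c(0, 0, 1)),
               "strictly increasing")
  expect_error(integrate_network(net, c(PL = -1e-9), c(0, 1)), ">= 0")
  expect_error(integrate_network(net, c(XX = 1e-9), c(0, 1)),
               "unknown species")
  traj <- integrate_network(net, c(P = 1e-7, L = 5e-9), seq(0, 600, by = 30))
  expect_true(is.numeric(traj$diagnostics$n_steps))
  expect_lt(traj$diagnostics$max_conservation_drift, 1e-6)
})

test_that("conservation_report recomputes drift and flags tampering", {
  net <- build_scheme("fpcd", c(k1P = 1e4, k_minus1P = 1e-3,
                                k1C = 1e4, k_minus1C = 1e-3,
                                k_thetaD = 50, k_thetaL = 50))
  traj <- integrate_network(net, c(P = 1e-7, L = 5e-9, C = 1e-7),
                            seq(0, 3600, by = 60))
  rep <- conservation_report(traj)
  expect_setequal(rep$moiety, c("P", "L", "C"))
  expect_true(all(rep$max_rel_drift < 1e-6))
  expect_false(any(rep$breach))
  # scale one species mid-trajectory: drift must now register
  bad <- traj
  mid <- ceiling(nrow(bad$conc) / 2)
  bad$conc[mid, "PL"] <- bad$conc[mid, "PL"] * 1.01
  rep2 <- conservation_report(bad)
  expect_true(any(rep2$breach))
  share <- unname((0.01 / 1.01) * bad$conc[mid, "PL"] /
                    rep2$total_0[rep2$moiety == "L"])
  expect_equal(rep2$max_rel_drift[rep2$moiety == "L"], share,
               tolerance = 1e-2)
})

test_that("equilibrium_state reproduces half-saturation and long-time integration", {
  Kd <- 5.1e-9
  k1 <- 9.1e-5 / Kd
  net <- build_scheme("fpcd", c(k1P = k1, k_minus1P = 9.1e-5,
                                k1C = k1, k_minus1C = 9.1e-5,
                                k_thetaD = 0, k_thetaL = 0))
  # trace ligand at [P] = Kd binds half the ligand
  eq <- equilibrium_state(net, c(P = Kd, L = 1e-13, C = 0))
  expect_equal(unname(eq[["PL"]] / 1e-13), 0.5, tolerance = 1e-3)

  # two competing ligands at the packaged affinities, equal totals:
  # agrees with a long integration endpoint
  k1L <- 9.1e-5 / 5.1e-9
  k1C <- 9.1e-5 / 2.3e-9
  net2 <- build_scheme("fpcd", c(k1P = k1L, k_minus1P = 9.1e-5,
                                 k1C = k1C, k_minus1C = 9.1e-5,
                                 k_thetaD = 0, k_thetaL = 0))
  tot <- c(P = 1e-8, L = 1e-8, C = 1e-8)
  eq2 <- equilibrium_state(net2, tot)
  traj <- integrate_network(net2, tot, c(0, 10^seq(0, 6, length.out = 50)))
  endpoint <- traj$conc[nrow(traj$conc), ]
  expect_equal(unname(eq2[names(endpoint)]), unname(endpoint),
               tolerance = 1e-6)
})

test_that("equilibrium_state refuses irreversible networks", {
  p <- prc2_params()
  net <- build_scheme("prc2", c(k1N = p$k_minus1N / p$KdN,
                                k_minus1N = p$k_minus1N,
                                k1R = p$k_minus1R / p$KdR,
                                k_minus1R = p$k_minus1R,
                                k_thetaN = p$k_thetaN, k_thetaR = p$k_thetaR,
                                k_thetaNN = p$k_thetaNN, k_cat = p$k_cat))
  expect_error(equilibrium_state(net, c(E = 1e-8, R = 0, N = 5e-9)),
               "no equilibrium solver available")
})

test_that("trajectory export is tidy long format", {
  net <- build_scheme("fpcd", c(k1P = 1e4, k_minus1P = 1e-3,
                                k1C = 1e4, k_minus1C = 1e-3,
                                k_thetaD = 0, k_thetaL = 0))
  traj <- integrate_network(net, c(P = 1e-7, L = 5e-9), seq(0, 300, by = 30))
  df <- as.data.frame(traj)
  expect_named(df, c("time_s", "species", "concentration_M"))
  expect_equal(nrow(df), length(traj$time) * ncol(traj$conc))
})
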