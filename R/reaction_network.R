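#' Mass-action reaction networks
#'
#' Internal representation: species labels, an integer stoichiometric matrix
#' (species x reactions), and per-reaction mass-action rate laws, each
#' referencing one named rate constant and an optional scalar multiplier
#' (tuning parameters such as alpha, beta, delta). Conserved moieties are
#' declared explicitly as a moiety x species composition matrix so that
#' integration can be audited for conservation drift.
#'
#' @name reaction_network
NULL

new_reaction_network <- function(species, reactions, constants, moieties,
                                 scheme = "custom") {
  S <- matrix(0L, nrow = length(species), ncol = length(reactions),
              dimnames = list(species, vapply(reactions, `[[`, "", "name")))
  for (j in seq_along(reactions)) {
    r <- reactions[[j]]
    for (sp in r$reactants) S[sp, j] <- S[sp, j] - 1L
    for (sp in r$products)  S[sp, j] <- S[sp, j] + 1L
    if (is.null(r$mult)) reactions[[j]]$mult <- 1
    if (!r$k %in% names(constants))
      stop("reaction '", r$name, "' references missing rate constant '", r$k, "'")
  }
  # every reaction must conserve every declared moiety
  drift <- moieties %*% S
  if (any(abs(drift) > 0))
    stop("reaction(s) violate declared conservation: ",
         paste(colnames(S)[colSums(abs(drift)) > 0], collapse = ", "))
  structure(list(species = species, stoich = S, reactions = reactions,
                 constants = constants, moieties = moieties, scheme = scheme),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> scheme:", x$scheme, "|", length(x$species),
      "species,", length(x$reactions), "reactions\n")
  for (r in x$reactions) {
    cat(sprintf("  %-14s %s -> %s  @ %s%s\n", r$name,
                paste(r$reactants, collapse = " + "),
                paste(r$products, collapse = " + "), r$k,
                if (r$mult != 1) paste0(" x ", format(r$mult)) else ""))
  }
  invisible(x)
}

# Flatten a rate_constant_set into the named numeric vector a scheme needs.
# Pair names follow the field's subscript convention: pair "PL" (labeled
# ligand complex) -> k1P/k_minus1P, "PC" (competitor) -> k1C/k_minus1C,
# "ER" -> k1R/k_minus1R, "EN" -> k1N/k_minus1N. k_theta entries keep their
# own suffix (D, L, N, R, NN).
.flatten_constants <- function(constants) {
  if (inherits(constants, "rate_constant_set")) {
    constants <- complete_rate_constants(constants)
    suffix_map <- c(PL = "P", PC = "C", ER = "R", EN = "N")
    out <- c()
    for (nm in names(constants$pairs)) {
      p <- constants$pairs[[nm]]
      sfx <- if (nm %in% names(suffix_map)) suffix_map[[nm]] else nm
      v <- setNames(c(p$k1, p$k_minus1),
                    paste0(c("k1", "k_minus1"), sfx))
      out <- c(out, v)
    }
    if (length(constants$k_theta)) {
      kt <- constants$k_theta
      names(kt) <- paste0("k_theta", names(kt))
      out <- c(out, kt)
    }
    if (!is.null(constants$k_cat)) out <- c(out, k_cat = constants$k_cat)
    return(out)
  }
  unlist(constants)
}

#' Build a named reaction scheme
#'
#' Constructs the mass-action network for one of three schemes:
#' \describe{
#'   \item{`fpcd`}{Competitive dissociation with direct transfer: protein P,
#'     labeled ligand L, unlabeled competitor C. Reversible binding
#'     P + L <-> PL (`k1P`, `k_minus1P`) and P + C <-> PC (`k1C`,
#'     `k_minus1C`), plus bimolecular exchange PL + C -> PC + L (`k_thetaD`)
#'     and PC + L -> PL + C (`k_thetaL`) through an implied unstable ternary
#'     intermediate. Setting both transfer constants to 0 collapses the
#'     scheme to classic competition.}
#'   \item{`prc2`}{Competitive (mutually exclusive) RNA/nucleosome binding by
#'     an HMTase E with direct transfer and catalysis: E + R <-> ER, E + N
#'     <-> EN, transfer ER + N -> EN + R (`alpha * k_thetaN`), EN + R ->
#'     ER + N (`alpha * k_thetaR`), nucleosome-to-nucleosome self transfer at
#'     `k_thetaNN` (not alpha-scaled: the effective-molarity adjustment
#'     applies only to RNA-nucleosome transfers), and methylation EN -> E +
#'     Nm (`k_cat`). Methylated nucleosome Nm is an inert product.}
#'   \item{`cobinder`}{Independent RNA/nucleosome binding with a stable
#'     ternary complex: binding as above plus ER + N -> ERN
#'     (`alpha * delta1 * k1N`), ERN -> ER + N (`delta2N * k_minus1N`),
#'     EN + R -> ERN (`alpha * delta1 * k1R`), ERN -> EN + R
#'     (`delta2R * k_minus1R`), and catalysis EN -> E + Nm (`k_cat`),
#'     ERN -> ER + Nm (`beta * k_cat`).}
#' }
#'
#' @param scheme_id One of `"fpcd"`, `"prc2"`, `"cobinder"`.
#' @param constants A [rate_constant_set()] or a named numeric vector/list of
#'   the constants the scheme references (see Details above for names).
#' @param tuning Named list/vector of scalar tuning parameters: `alpha`
#'   (effective molarity for transfer / ternary formation), and for
#'   `cobinder` also `beta`, `delta1`, `delta2N`, `delta2R`. Missing entries
#'   default to 1.
#'
#' @return A `reaction_network`.
#' @examples
#' net <- build_scheme("fpcd", c(k1P = 1.8e4, k_minus1P = 9.1e-5,
#'                               k1C = 1.8e4, k_minus1C = 9.1e-5,
#'                               k_thetaD = 260, k_thetaL = 260))
#' net
#' @export
build_scheme <- function(scheme_id, constants, tuning = list()) {
  tuning <- as.list(tuning)
  tune <- function(nm) if (is.null(tuning[[nm]])) 1 else as.numeric(tuning[[nm]])
  k <- .flatten_constants(constants)

  need <- function(nms) {
    miss <- setdiff(nms, names(k))
    if (length(miss))
      stop("missing constant(s) for scheme '", scheme_id, "': ",
           paste(miss, collapse = ", "))
  }
  rxn <- function(name, reactants, products, kname, mult = 1)
    list(name = name, reactants = reactants, products = products,
         k = kname, mult = mult)

  if (identical(scheme_id, "fpcd")) {
    need(c("k1P", "k_minus1P", "k1C", "k_minus1C", "k_thetaD", "k_thetaL"))
    species <- c("P", "L", "C", "PL", "PC")
    reactions <- list(
      rxn("bind_PL",   c("P", "L"), "PL", "k1P"),
      rxn("unbind_PL", "PL", c("P", "L"), "k_minus1P"),
      rxn("bind_PC",   c("P", "C"), "PC", "k1C"),
      rxn("unbind_PC", "PC", c("P", "C"), "k_minus1C"),
      rxn("xfer_LtoC", c("PL", "C"), c("PC", "L"), "k_thetaD"),
      rxn("xfer_CtoL", c("PC", "L"), c("PL", "C"), "k_thetaL"))
    moieties <- rbind(P = c(P = 1, L = 0, C = 0, PL = 1, PC = 1),
                      L = c(0, 1, 0, 1, 0),
                      C = c(0, 0, 1, 0, 1))
    colnames(moieties) <- species
  } else if (identical(scheme_id, "prc2")) {
    need(c("k1R", "k_minus1R", "k1N", "k_minus1N",
           "k_thetaN", "k_thetaR", "k_thetaNN", "k_cat"))
    a <- tune("alpha")
    species <- c("E", "R", "N", "ER", "EN", "Nm")
    reactions <- list(
      rxn("bind_ER",   c("E", "R"), "ER", "k1R"),
      rxn("unbind_ER", "ER", c("E", "R"), "k_minus1R"),
      rxn("bind_EN",   c("E", "N"), "EN", "k1N"),
      rxn("unbind_EN", "EN", c("E", "N"), "k_minus1N"),
      rxn("xfer_RtoN", c("ER", "N"), c("EN", "R"), "k_thetaN", a),
      rxn("xfer_NtoR", c("EN", "R"), c("ER", "N"), "k_thetaR", a),
      # nucleosome self transfer: identical species on both sides, so it has
      # zero net stoichiometry; retained so the scheme is complete on paper
      rxn("xfer_NtoN", c("EN", "N"), c("EN", "N"), "k_thetaNN"),
      rxn("methylate", "EN", c("E", "Nm"), "k_cat"))
    moieties <- rbind(E = c(E = 1, R = 0, N = 0, ER = 1, EN = 1, Nm = 0),
                      R = c(0, 1, 0, 1, 0, 0),
                      N = c(0, 0, 1, 0, 1, 1))
    colnames(moieties) <- species
  } else if (identical(scheme_id, "cobinder")) {
    need(c("k1R", "k_minus1R", "k1N", "k_minus1N", "k_cat"))
    a  <- tune("alpha"); b <- tune("beta")
    d1 <- tune("delta1"); d2N <- tune("delta2N"); d2R <- tune("delta2R")
    species <- c("E", "R", "N", "ER", "EN", "ERN", "Nm")
    reactions <- list(
      rxn("bind_ER",    c("E", "R"), "ER", "k1R"),
      rxn("unbind_ER",  "ER", c("E", "R"), "k_minus1R"),
      rxn("bind_EN",    c("E", "N"), "EN", "k1N"),
      rxn("unbind_EN",  "EN", c("E", "N"), "k_minus1N"),
      rxn("tern_addN",  c("ER", "N"), "ERN", "k1N", a * d1),
      rxn("tern_loseN", "ERN", c("ER", "N"), "k_minus1N", d2N),
      rxn("tern_addR",  c("EN", "R"), "ERN", "k1R", a * d1),
      rxn("tern_loseR", "ERN", c("EN", "R"), "k_minus1R", d2R),
      rxn("methylate",       "EN", c("E", "Nm"), "k_cat"),
      rxn("methylate_tern", "ERN", c("ER", "Nm"), "k_cat", b))
    moieties <- rbind(E = c(E = 1, R = 0, N = 0, ER = 1, EN = 1, ERN = 1, Nm = 0),
                      R = c(0, 1, 0, 1, 0, 1, 0),
                      N = c(0, 0, 1, 0, 1, 1, 1))
    colnames(moieties) <- species
  } else {
    stop("unknown scheme_id '", scheme_id,
         "'; must be one of fpcd, prc2, cobinder")
  }
  new_reaction_network(species, reactions, k, moieties, scheme = scheme_id)
}

# reaction rate vector at state c (named numeric, molar)
.reaction_rates <- function(network, conc) {
  vapply(network$reactions, function(r) {
    v <- network$constants[[r$k]] * r$mult
    for (sp in r$reactants) v <- v * conc[[sp]]
    v
  }, numeric(1))
}

.network_deriv <- function(network) {
  S <- network$stoich
  force(S)
  function(t, y, parms) {
    v <- .reaction_rates(network, as.list(y))
    list(as.numeric(S %*% v))
  }
}

#' Integrate a reaction network
#'
#' Solves the mass-action ODE system with a stiff-capable implicit
#' integrator (`deSolve::ode`, method `"lsoda"`) and audits conservation of
#' the declared moieties. Default tolerances are tight (atol 1e-15 M,
#' rtol 1e-9) because typical concentrations are nanomolar.
#'
#' @param network A `reaction_network` from [build_scheme()].
#' @param initial Named concentration map (M); species not named start at 0.
#' @param t_grid Strictly increasing time grid (s); must start at the
#'   initial time (first element is taken as t0).
#' @param solver_opts List with optional `atol`, `rtol`, `method`.
#'
#' @return A `trajectory`: list with `time` (s), `conc` (matrix, M, one
#'   column per species), `diagnostics` (solver step count, max relative
#'   conservation drift), and the originating network.
#' @export
integrate_network <- function(network, initial, t_grid, solver_opts = list()) {
  stopifnot(inherits(network, "reaction_network"))
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  y0 <- setNames(numeric(length(network$species)), network$species)
  unknown <- setdiff(names(initial), network$species)
  if (length(unknown))
    stop("initial concentrations for unknown species: ",
         paste(unknown, collapse = ", "))
  y0[names(initial)] <- as.numeric(initial)
  if (any(y0 < 0)) stop("initial concentrations must be >= 0")
  atol <- if (is.null(solver_opts$atol)) 1e-15 else solver_opts$atol
  rtol <- if (is.null(solver_opts$rtol)) 1e-9 else solver_opts$rtol
  method <- if (is.null(solver_opts$method)) "lsoda" else solver_opts$method

  sol <- deSolve::ode(y = y0, times = t_grid, func = .network_deriv(network),
                      parms = NULL, method = method, atol = atol, rtol = rtol)
  diagn <- attr(sol, "istate")
  if (nrow(sol) < length(t_grid))
    stop("solver failed to converge; last accepted time = ",
         sol[nrow(sol), "time"], " s")
  conc <- sol[, network$species, drop = FALSE]
  rownames(conc) <- NULL
  traj <- structure(list(time = as.numeric(sol[, "time"]), conc = conc,
                         network = network,
                         diagnostics = list(n_steps = unname(diagn[3]))),
                    class = "trajectory")
  rep <- conservation_report(traj)
  traj$diagnostics$max_conservation_drift <- max(rep$max_rel_drift)
  traj
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", length(x$time), "time points,",
      ncol(x$conc), "species; span", x$time[1], "-",
      x$time[length(x$time)], "s\n")
  cat("  max conservation drift:",
      format(x$diagnostics$max_conservation_drift), "\n")
  invisible(x)
}

#' Tidy a trajectory for export
#'
#' @param x A `trajectory`.
#' @param row.names,optional,... Passed through (standard generic arguments).
#' @return Long-format data.frame with columns `time_s`, `species`,
#'   `concentration_M`.
#' @export
as.data.frame.trajectory <- function(x, row.names = NULL, optional = FALSE, ...) {
  sp <- colnames(x$conc)
  data.frame(time_s = rep(x$time, times = length(sp)),
             species = rep(sp, each = length(x$time)),
             concentration_M = as.numeric(x$conc),
             stringsAsFactors = FALSE)
}

#' Conservation drift report
#'
#' Recomputes every declared conserved total along a trajectory and reports
#' its maximum relative drift from the initial value, flagging any breach of
#' the 1e-6 relative tolerance the integrator is expected to meet.
#'
#' @param trajectory A `trajectory` from [integrate_network()].
#' @param tol Relative drift threshold for the `breach` flag.
#' @return data.frame with columns `moiety`, `total_0`, `max_rel_drift`,
#'   `breach`.
#' @export
conservation_report <- function(trajectory, tol = 1e-6) {
  stopifnot(inherits(trajectory, "trajectory"))
  if (!length(trajectory$time)) stop("empty trajectory")
  A <- trajectory$network$moieties
  totals <- trajectory$conc %*% t(A)   # time x moiety
  t0 <- totals[1, ]
  scale <- pmax(abs(t0), .Machine$double.xmin)
  drift <- vapply(seq_len(ncol(totals)), function(i)
    max(abs(totals[, i] - t0[i])) / scale[i], numeric(1))
  data.frame(moiety = rownames(A), total_0 = unname(t0),
             max_rel_drift = unname(drift), breach = unname(drift > tol),
             stringsAsFactors = FALSE)
}

#' Equilibrium state of a reversible network
#'
#' Finds the detailed-balance equilibrium of a network containing only
#' reversible reactions (every reaction with a nonzero rate constant must
#' have a partner with the exact reversed stoichiometry). The state is
#' located by integrating towards steady state and then polishing with
#' Levenberg-Marquardt on the steady-state + conservation residuals, using a
#' square-root parameterization to keep concentrations non-negative.
#'
#' @param network A `reaction_network` with no irreversible reactions
#'   (e.g. catalysis disabled, `k_cat = 0`).
#' @param totals Named vector of conserved-moiety totals (M), named after
#'   the network's moieties.
#' @return Named concentration vector (M) at equilibrium.
#' @export
equilibrium_state <- function(network, totals) {
  stopifnot(inherits(network, "reaction_network"))
  A <- network$moieties
  if (!all(rownames(A) %in% names(totals)))
    stop("totals must name every conserved moiety: ",
         paste(rownames(A), collapse = ", "))
  tot <- as.numeric(totals[rownames(A)])

  # reversibility check: each active reaction needs an active exact reverse
  S <- network$stoich
  active <- vapply(network$reactions, function(r)
    network$constants[[r$k]] * r$mult > 0, logical(1))
  for (j in which(active)) {
    if (all(S[, j] == 0)) next            # null-stoichiometry self transfer
    rev_found <- any(vapply(which(active), function(jj)
      all(S[, jj] == -S[, j]), logical(1)))
    if (!rev_found)
      stop("no equilibrium solver available: reaction '",
           network$reactions[[j]]$name, "' is irreversible")
  }

  # initial guess: distribute totals on free species, then relax by ODE
  y0 <- setNames(numeric(length(network$species)), network$species)
  for (i in seq_len(nrow(A))) {
    free_sp <- colnames(A)[A[i, ] == 1]
    # prefer a species exclusive to this moiety
    excl <- free_sp[colSums(A[, free_sp, drop = FALSE]) == 1]
    target <- if (length(excl)) excl[1] else free_sp[1]
    y0[target] <- y0[target] + tot[i]
  }
  kvals <- vapply(network$reactions, function(r)
    network$constants[[r$k]] * r$mult, numeric(1))
  k_slow <- min(kvals[kvals > 0])
  t_relax <- max(1e6, 100 / k_slow)
  tg <- c(0, 10^seq(-2, log10(t_relax), length.out = 200))
  traj <- integrate_network(network, y0, tg)
  y_start <- pmax(traj$conc[nrow(traj$conc), ], 0)

  scale_c <- max(tot, .Machine$double.eps)
  deriv <- .network_deriv(network)
  resid <- function(u) {
    conc <- u^2
    names(conc) <- network$species
    d <- deriv(0, conc, NULL)[[1]]
    cons <- as.numeric(A %*% conc) - tot
    c(d / (scale_c * max(kvals)), cons / scale_c)
  }
  fit <- minpack.lm::nls.lm(par = sqrt(y_start), fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-15, ptol = 1e-15))
  eq <- setNames(fit$par^2, network$species)

  # verify: net rates small relative to characteristic flux
  rates <- .reaction_rates(network, as.list(eq))
  char_flux <- max(rates, .Machine$double.xmin)
  net <- as.numeric(S %*% rates)
  if (max(abs(net)) > 1e-9 * char_flux)
    warning("equilibrium residual larger than expected: max |net rate| = ",
            format(max(abs(net))), " vs characteristic flux ",
            format(char_flux))
  eq
}
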