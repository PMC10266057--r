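#' Assay design for simulated plate-reader experiments
#'
#' Defaults mirror the competitive-dissociation protocol: 5 nM labeled
#' ligand, reads every 30 s for 120 min, ~90 s dead time between reaction
#' initiation and the first read, 4 technical replicates per condition,
#' 25 C.
#'
#' @param ligand_M Labeled ligand concentration (M).
#' @param interval_s Read interval (s).
#' @param duration_s Total observation window from reaction initiation (s).
#' @param dead_time_s Delay before the first read (s).
#' @param replicates Technical replicates per condition.
#' @param temperature Temperature label (C).
#' @return `assay_design` object.
#' @export
assay_design <- function(ligand_M = 5e-9, interval_s = 30, duration_s = 7200,
                         dead_time_s = 90, replicates = 4L,
                         temperature = "25") {
  stopifnot(interval_s > 0, duration_s >= interval_s, replicates >= 1,
            dead_time_s >= 0, ligand_M > 0)
  structure(list(ligand_M = ligand_M, interval_s = interval_s,
                 duration_s = duration_s, dead_time_s = dead_time_s,
                 replicates = as.integer(replicates),
                 temperature = temperature),
            class = "assay_design")
}

#' Additive measurement-noise model
#'
#' Gaussian noise added to each polarization read, emulating technical
#' replicate scatter. An identical seed yields identical plates.
#'
#' @param sd_mP Standard deviation of the additive noise (mP); 0 disables.
#' @param seed Integer RNG seed, or `NULL` to use the session RNG stream.
#' @return `noise_model` object.
#' @export
noise_model <- function(sd_mP = 3, seed = NULL) {
  stopifnot(sd_mP >= 0)
  structure(list(sd_mP = sd_mP, seed = seed), class = "noise_model")
}

# Run `fn()` under a temporary seed, restoring the caller's RNG stream.
.with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}

#' Serial-dilution concentration series
#'
#' Geometric series descending from `top` by `dilution_factor`, of length
#' `n_points`, plus a zero point — the standard serial-dilution layout of a
#' titration or competitor series.
#'
#' @param top Highest concentration (M).
#' @param dilution_factor Fold dilution between consecutive points (> 1).
#' @param n_points Number of nonzero points (>= 2).
#' @return Numeric vector of length `n_points + 1`, descending, ending in 0.
#' @examples
#' make_titration(1e-6, 2, 3)   # 1e-6 5e-7 2.5e-7 0
#' @export
make_titration <- function(top, dilution_factor, n_points) {
  stopifnot(top > 0, n_points >= 2)
  if (dilution_factor <= 1) stop("dilution_factor must be > 1")
  c(top / dilution_factor^(seq_len(n_points) - 1), 0)
}

.well_ids <- function(n) {
  if (n > 384) stop("more than 384 wells requested")
  rows <- LETTERS[1:16]
  cols <- sprintf("%02d", 1:24)
  as.vector(t(outer(rows, cols, paste0)))[seq_len(n)]
}

new_plate_table <- function(df, metadata) {
  need <- c("well", "condition", "conc_M", "replicate", "time_s",
            "polarization_mP", "blank")
  stopifnot(all(need %in% names(df)))
  structure(df, class = c("plate_table", "data.frame"), metadata = metadata)
}

#' @export
print.plate_table <- function(x, ...) {
  md <- attr(x, "metadata")
  cat("<plate_table>", md$plate_type, "assay;", length(unique(x$well)),
      "wells,", nrow(x), "reads\n")
  cat("  ligand:", md$ligand, "| competitor:", md$competitor %||% "-",
      "| buffer:", md$buffer, "\n")
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plate metadata
#' @param plate A `plate_table`.
#' @return Named list of plate-level metadata (plate type, ligand and
#'   competitor names, buffer, polarization endpoints, seed).
#' @export
plate_metadata <- function(plate) attr(plate, "metadata")

#' Simulate an equilibrium FP binding titration plate
#'
#' Generates equilibrium polarization reads for a protein titration against
#' a trace labeled ligand. The underlying occupancy uses the standard
#' hyperbolic binding model (see [binding_fraction()]); polarization is
#' linear in fraction bound: `P = P_free + (P_bound - P_free) * f + noise`.
#' Buffer-only blank wells are included.
#'
#' @param species A `species_params` (its PL pair supplies Kd) or a single
#'   numeric Kd (M).
#' @param titration Protein concentrations (M), e.g. from
#'   [make_titration()]; should include 0.
#' @param design [assay_design()]; equilibrium plates typically use a 30-min
#'   read window (`assay_design(duration_s = 1800, dead_time_s = 0)`).
#' @param noise [noise_model()].
#' @param P_free,P_bound Polarization of free and fully bound ligand (mP).
#' @param n_blank Number of buffer-only blank wells.
#' @return `plate_table` with one well per (concentration, replicate).
#' @export
generate_binding_plate <- function(species, titration,
                                   design = assay_design(duration_s = 1800,
                                                         dead_time_s = 0),
                                   noise = noise_model(0),
                                   P_free = 50, P_bound = 200,
                                   n_blank = 2L) {
  Kd <- if (inherits(species, "species_params")) {
    complete_rate_constants(species$constants)$pairs$PL$Kd
  } else as.numeric(species)
  if (is.null(Kd) || !is.finite(Kd) || Kd <= 0)
    stop("Kd must be present in the species constants")
  if (P_bound <= P_free) stop("inverted signal window: P_bound <= P_free")

  times <- seq(design$dead_time_s, design$duration_s, by = design$interval_s)
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      conc_M = titration, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(-grid$conc_M, grid$replicate), ]
  n_wells <- nrow(grid) + n_blank
  wells <- .well_ids(n_wells)

  f <- binding_fraction(grid$conc_M, Kd)
  base <- P_free + (P_bound - P_free) * f
  rows <- data.frame(
    well = rep(wells[seq_len(nrow(grid))], each = length(times)),
    condition = rep(sprintf("E%.4g", grid$conc_M), each = length(times)),
    conc_M = rep(grid$conc_M, each = length(times)),
    replicate = rep(grid$replicate, each = length(times)),
    time_s = rep(times, times = nrow(grid)),
    polarization_mP = rep(base, each = length(times)),
    blank = FALSE, stringsAsFactors = FALSE)
  if (n_blank > 0) {
    rows <- rbind(rows, data.frame(
      well = rep(wells[nrow(grid) + seq_len(n_blank)], each = length(times)),
      condition = "blank", conc_M = NA_real_,
      replicate = rep(seq_len(n_blank), each = length(times)),
      time_s = rep(times, times = n_blank),
      polarization_mP = 0, blank = TRUE, stringsAsFactors = FALSE))
  }
  rows$polarization_mP <- .with_seed(noise$seed, function()
    rows$polarization_mP + rnorm(nrow(rows), 0, noise$sd_mP))

  md <- list(plate_type = "binding",
             ligand = if (inherits(species, "species_params"))
               species$ligand else "ligand",
             competitor = NULL,
             buffer = if (inherits(species, "species_params"))
               species$buffer else "BB_10",
             conc_role = "protein_M",
             P_free_mP = P_free, P_bound_mP = P_bound,
             ligand_M = design$ligand_M, seed = noise$seed)
  new_plate_table(rows, md)
}

#' Simulate a competitive-dissociation (FPCD) time-course plate
#'
#' Protein and trace labeled ligand are pre-equilibrated without competitor;
#' at t = 0 unlabeled competitor is added at each series concentration and
#' the bound fraction relaxes according to the competitive-dissociation
#' scheme with direct transfer (see [build_scheme()], scheme `"fpcd"`),
#' integrated with [integrate_network()]. Reads start at the dead time and
#' continue at the design interval; polarization maps linearly onto the
#' fraction of labeled ligand bound.
#'
#' @param species A `species_params` carrying the PL/PC pairs and transfer
#'   constants.
#' @param competitor_series Competitor concentrations (M); include 0 to
#'   provide the background (no-competitor) condition the downstream
#'   pipeline subtracts.
#' @param design [assay_design()].
#' @param noise [noise_model()].
#' @param P_free,P_bound Polarization endpoints (mP).
#' @param protein_M Total protein concentration (M); default 100 nM, the
#'   reported competition-reaction concentration. A warning is issued below
#'   2x the apparent Kd (unsaturated starting complex).
#' @param carrier Logical flag recording a constant-total-polynucleotide
#'   design (competitor serially diluted in non-binding carrier); metadata
#'   only, the carrier is assumed kinetically inert.
#' @param n_blank Number of buffer-only blank wells.
#' @return `plate_table`.
#' @export
generate_fpcd_plate <- function(species, competitor_series,
                                design = assay_design(),
                                noise = noise_model(0),
                                P_free = 50, P_bound = 200,
                                protein_M = 1e-7, carrier = FALSE,
                                n_blank = 2L) {
  stopifnot(inherits(species, "species_params"))
  if (!length(competitor_series)) stop("competitor series is empty")
  if (P_bound <= P_free) stop("inverted signal window: P_bound <= P_free")
  rcs <- complete_rate_constants(species$constants)
  Kd <- rcs$pairs$PL$Kd
  if (protein_M < 2 * Kd)
    warning("protein concentration below 2x apparent Kd; ",
            "starting complex is not saturated")
  L_T <- design$ligand_M
  net <- build_scheme("fpcd", rcs)

  # exact pre-equilibrium of the two-species pair P + L <-> PL
  s <- protein_M + L_T + Kd
  PL0 <- (s - sqrt(s^2 - 4 * protein_M * L_T)) / 2
  times <- seq(design$dead_time_s, design$duration_s, by = design$interval_s)

  series <- sort(unique(competitor_series), decreasing = TRUE)
  frac_bound <- lapply(series, function(C0) {
    init <- c(P = protein_M - PL0, L = L_T - PL0, C = C0, PL = PL0, PC = 0)
    tg <- unique(c(0, times))
    traj <- integrate_network(net, init, tg)
    idx <- match(times, traj$time)
    traj$conc[idx, "PL"] / L_T
  })

  n_cond <- length(series)
  reps <- design$replicates
  n_wells <- n_cond * reps + n_blank
  wells <- .well_ids(n_wells)
  blocks <- list()
  w <- 0L
  for (i in seq_len(n_cond)) {
    base <- P_free + (P_bound - P_free) * frac_bound[[i]]
    for (r in seq_len(reps)) {
      w <- w + 1L
      blocks[[w]] <- data.frame(
        well = wells[w], condition = sprintf("C%.4g", series[i]),
        conc_M = series[i], replicate = r, time_s = times,
        polarization_mP = base, blank = FALSE, stringsAsFactors = FALSE)
    }
  }
  for (b in seq_len(n_blank)) {
    w <- w + 1L
    blocks[[w]] <- data.frame(
      well = wells[w], condition = "blank", conc_M = NA_real_,
      replicate = b, time_s = times, polarization_mP = 0, blank = TRUE,
      stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, blocks)
  rows$polarization_mP <- .with_seed(noise$seed, function()
    rows$polarization_mP + rnorm(nrow(rows), 0, noise$sd_mP))

  md <- list(plate_type = "fpcd", ligand = species$ligand,
             competitor = species$competitor, buffer = species$buffer,
             conc_role = "competitor_M",
             P_free_mP = P_free, P_bound_mP = P_bound,
             ligand_M = L_T, protein_M = protein_M,
             carrier = isTRUE(carrier), seed = noise$seed)
  new_plate_table(rows, md)
}
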