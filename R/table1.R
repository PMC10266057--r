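#' Packaged reference rate constants
#'
#' Returns the packaged table of empirically determined constants for PRC2
#' binding to fluorescent nucleic-acid ligands: apparent equilibrium
#' dissociation constants in the absence of competitor (Kd_app, nM),
#' intrinsic dissociation rate constants (k_minus1P, s^-1), and direct
#' transfer rate constants (k_thetaD, M^-1 s^-1), per ligand / buffer
#' (BB_X = X mM KCl) / temperature regime / competitor combination, with
#' footnote flags (carrier design, single experiment, somatic-isoform
#' protein prep, manual normalization baseline, ...).
#'
#' @return data.frame, one row per measured combination. `temperature` is
#'   `"25"` (constant 25 C) or `"4to25"` (4 C pre-incubation, 25 C read).
#'   `flags` is a semicolon-separated string, possibly empty.
#' @examples
#' tbl <- table1_reference()
#' subset(tbl, ligand == "ds-[F]d(N)60" & buffer == "BB_10")
#' @export
table1_reference <- function() {
  path <- system.file("extdata", "table1_rate_constants.csv",
                      package = "xferkin", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(temperature = "character"))
  df$flags[is.na(df$flags)] <- ""
  df
}

#' Look up one reference measurement
#'
#' @param ligand Ligand name as printed in the reference table (or a
#'   shorthand alias: `"G4"` = `r(G3A2)4[F]`, `"ds-dN60"` = `ds-[F]d(N)60`,
#'   `"ds-dN50"` = `ds-d(N)50[F]`).
#' @param buffer Buffer label (`BB_10`, `BB_25`, `BB_100`, `BB_200`).
#' @param temperature `"25"` or `"4to25"`.
#' @param competitor Optional competitor name to select a kinetic row; if
#'   `NULL` the first matching row is returned.
#' @return One-row data.frame from [table1_reference()].
#' @export
table1_lookup <- function(ligand, buffer, temperature = "25",
                          competitor = NULL) {
  ligand <- resolve_ligand_alias(ligand)
  tbl <- table1_reference()
  hit <- tbl$ligand == ligand & tbl$buffer == buffer &
    tbl$temperature == as.character(temperature)
  if (!is.null(competitor))
    hit <- hit & !is.na(tbl$competitor) & tbl$competitor == competitor
  out <- tbl[hit, , drop = FALSE]
  if (!nrow(out))
    stop("no reference entry for ligand '", ligand, "', buffer '", buffer,
         "', temperature '", temperature, "'",
         if (!is.null(competitor)) paste0(", competitor '", competitor, "'"))
  out[1, , drop = FALSE]
}

resolve_ligand_alias <- function(ligand) {
  aliases <- c("G4" = "r(G3A2)4[F]",
               "ds-dN60" = "ds-[F]d(N)60",
               "ds-dN50" = "ds-d(N)50[F]")
  if (ligand %in% names(aliases)) aliases[[ligand]] else ligand
}

#' Assemble simulation-ready species parameters from the reference table
#'
#' Builds a `species_params` object (ligand + competitor binding constants)
#' for the competitive-dissociation scheme from one reference row: the
#' labeled-complex pair (PL) gets the row's Kd_app and k_minus1P, the
#' transfer constants are symmetric (`k_thetaD = k_thetaL`) by default, and
#' the competitor pair (PC) defaults to the ligand's constants (the common
#' self-competition design with the unlabeled same species).
#'
#' @param ligand,buffer,temperature,competitor As in [table1_lookup()].
#' @param competitor_pair Optional list(k1, k_minus1, Kd) overriding the
#'   competitor's own binding constants.
#' @return Object of class `species_params`: list with `ligand`,
#'   `competitor`, `buffer`, `temperature`, and a completed
#'   [rate_constant_set()] with pairs `PL`, `PC` and transfer constants
#'   `k_theta["D"]`, `k_theta["L"]`.
#' @examples
#' sp <- table1_species("ds-dN60")   # dsDNA self-competition, BB_10, 25 C
#' sp$constants$pairs$PL$Kd          # 5.1e-9 M
#' @export
table1_species <- function(ligand, buffer = "BB_10", temperature = "25",
                           competitor = NULL, competitor_pair = NULL) {
  row <- table1_lookup(ligand, buffer, temperature, competitor)
  if (is.na(row$Kd_app_nM)) {
    # Kd may only be printed for the constant-25C block of the same ligand
    alt <- try(table1_lookup(ligand, buffer, "25"), silent = TRUE)
    if (!inherits(alt, "try-error") && !is.na(alt$Kd_app_nM))
      row$Kd_app_nM <- alt$Kd_app_nM
  }
  if (is.na(row$Kd_app_nM) || is.na(row$k_minus1P))
    stop("reference row lacks Kd_app and/or k_minus1P; supply constants ",
         "manually via species_params()")
  kthetaD <- if (is.na(row$k_thetaD)) 0 else row$k_thetaD
  species_params(
    ligand = row$ligand, competitor = row$competitor,
    Kd = row$Kd_app_nM * 1e-9, k_minus1 = row$k_minus1P,
    k_thetaD = kthetaD, buffer = row$buffer, temperature = row$temperature,
    competitor_pair = competitor_pair)
}

#' Species parameters for a competitive-dissociation experiment
#'
#' @param ligand,competitor Character names (free text).
#' @param Kd Apparent equilibrium dissociation constant of the labeled
#'   ligand-protein pair (M).
#' @param k_minus1 Intrinsic dissociation rate constant (s^-1).
#' @param k_thetaD Direct-transfer rate constant, labeled complex +
#'   competitor (M^-1 s^-1).
#' @param k_thetaL Reverse transfer constant (competitor complex + labeled
#'   ligand); defaults to `k_thetaD` (symmetric exchange, exact for
#'   self-competition).
#' @param competitor_pair Optional list(k1, k_minus1, Kd) for the competitor
#'   pair; defaults to the ligand's constants.
#' @param buffer,temperature Metadata labels.
#' @return `species_params` object.
#' @export
species_params <- function(ligand, competitor = ligand, Kd, k_minus1,
                           k_thetaD, k_thetaL = k_thetaD,
                           competitor_pair = NULL,
                           buffer = "BB_10", temperature = "25") {
  pl <- list(k_minus1 = k_minus1, Kd = Kd)
  pc <- if (is.null(competitor_pair)) pl else competitor_pair
  rcs <- complete_rate_constants(rate_constant_set(
    pairs = list(PL = pl, PC = pc),
    k_theta = c(D = k_thetaD, L = k_thetaL)))
  structure(list(ligand = ligand, competitor = competitor,
                 constants = rcs, buffer = buffer,
                 temperature = as.character(temperature)),
            class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat("<species_params>", x$ligand, "vs", x$competitor,
      sprintf("(%s, %s C)\n", x$buffer, x$temperature))
  print(x$constants)
  invisible(x)
}
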