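#' Hyperbolic fraction bound under the trace-ligand approximation
#'
#' The standard (non-quadratic, non-Hill) binding model: with the labeled
#' ligand in trace amounts, free protein ~ total protein and the fraction
#' of ligand bound is `f = [E] / (Kd + [E])`.
#'
#' @param E_total Total protein concentration(s) (M).
#' @param Kd Equilibrium dissociation constant (M).
#' @return Fraction bound in [0, 1), monotone increasing in `E_total`.
#' @examples
#' binding_fraction(5.1e-9, 5.1e-9)    # 0.5 at E = Kd
#' @export
binding_fraction <- function(E_total, Kd) {
  stopifnot(all(E_total >= 0), Kd > 0)
  E_total / (Kd + E_total)
}

#' Collapse a binding plate to an equilibrium isotherm
#'
#' For each well, the equilibrium polarization is the mean of the last
#' `n_last` reads; wells are then aggregated per protein concentration into
#' replicate mean and SD.
#'
#' @param plate A binding `plate_table`.
#' @param n_last Number of final reads averaged per well (default 10).
#' @return `isotherm_data`: data.frame with `conc_M`, `polarization_mP`
#'   (replicate mean), `sd_mP`, `n`; the blank mean is kept as attribute
#'   `blank_mP`.
#' @export
isotherm_from_plate <- function(plate, n_last = 10L) {
  stopifnot(inherits(plate, "plate_table"))
  df <- as.data.frame(plate)
  eq_by_well <- function(sub) {
    sub <- sub[order(sub$time_s), ]
    mean(utils::tail(sub$polarization_mP, n_last))
  }
  live <- df[!df$blank, ]
  wells <- split(live, interaction(live$well, drop = TRUE))
  per_well <- data.frame(
    conc_M = vapply(wells, function(s) s$conc_M[1], numeric(1)),
    eq_mP = vapply(wells, eq_by_well, numeric(1)))
  agg_m <- tapply(per_well$eq_mP, per_well$conc_M, mean)
  agg_s <- tapply(per_well$eq_mP, per_well$conc_M, sd)
  agg_n <- tapply(per_well$eq_mP, per_well$conc_M, length)
  out <- data.frame(conc_M = as.numeric(names(agg_m)),
                    polarization_mP = as.numeric(agg_m),
                    sd_mP = as.numeric(agg_s), n = as.integer(agg_n))
  out <- out[order(out$conc_M), ]
  rownames(out) <- NULL
  blank <- df[df$blank, ]
  attr(out, "blank_mP") <- if (nrow(blank)) {
    bw <- split(blank, interaction(blank$well, drop = TRUE))
    mean(vapply(bw, eq_by_well, numeric(1)))
  } else NA_real_
  class(out) <- c("isotherm_data", "data.frame")
  out
}

#' Fit an apparent Kd to an equilibrium isotherm
#'
#' Nonlinear least squares of
#' `P(E) = P_free + (P_bound - P_free) * E / (Kd + E)` over
#' (Kd, P_free, P_bound). The fit is deterministic: it is multi-started
#' from three fixed Kd guesses spanning the titration range (minimum
#' nonzero, geometric midpoint, maximum) and the lowest residual sum of
#' squares wins.
#'
#' @param isotherm An `isotherm_data` (>= 5 concentrations including 0) or a
#'   data.frame with columns `conc_M` and `polarization_mP`.
#' @param weights Optional per-point weights (e.g. `1/sd^2`); unweighted by
#'   default.
#' @return `kd_fit`: list with `Kd` (M), `Kd_se`, `P_free`, `P_bound`
#'   (mP), `rss`, and the `fit` object.
#' @export
fit_kd_app <- function(isotherm, weights = NULL) {
  df <- as.data.frame(isotherm)
  stopifnot(all(c("conc_M", "polarization_mP") %in% names(df)))
  if (nrow(df) < 5 || !any(df$conc_M == 0))
    stop("isotherm needs >= 5 concentrations including 0")
  rng <- range(df$polarization_mP)
  if (diff(rng) < sqrt(.Machine$double.eps) * max(abs(rng), 1))
    stop("unidentifiable: flat isotherm")
  pos <- sort(unique(df$conc_M[df$conc_M > 0]))
  kd_starts <- c(min(pos), sqrt(min(pos) * max(pos)), max(pos))
  # warn on non-monotonic data beyond scatter
  ord <- df[order(df$conc_M), ]
  drops <- diff(ord$polarization_mP)
  has_sd <- "sd_mP" %in% names(df) && any(is.finite(df$sd_mP))
  noise_scale <- if (has_sd) max(df$sd_mP, na.rm = TRUE) else 0.02 * diff(rng)
  if (any(drops < -4 * max(noise_scale, 1e-12)))
    warning("isotherm is non-monotonic beyond expected noise")

  best <- NULL
  for (kd0 in kd_starts) {
    fit <- try(minpack.lm::nlsLM(
      polarization_mP ~ Pf + (Pb - Pf) * conc_M / (Kd + conc_M),
      data = df, weights = if (is.null(weights)) rep(1, nrow(df)) else weights,
      start = list(Kd = kd0, Pf = min(df$polarization_mP),
                   Pb = max(df$polarization_mP)),
      lower = c(Kd = 1e-15, Pf = -Inf, Pb = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("unidentifiable: Kd fit failed to converge")
  cf <- coef(best$fit)
  se <- tryCatch(sqrt(diag(vcov(best$fit)))[["Kd"]], error = function(e) NA_real_)
  if (abs(cf[["Pb"]] - cf[["Pf"]]) < sqrt(.Machine$double.eps))
    stop("unidentifiable: fitted plateaus coincide")
  structure(list(Kd = unname(cf[["Kd"]]), Kd_se = se,
                 P_free = unname(cf[["Pf"]]), P_bound = unname(cf[["Pb"]]),
                 rss = best$rss, fit = best$fit),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("<kd_fit> Kd_app = %.4g M (SE %.2g); P_free = %.4g mP, P_bound = %.4g mP; RSS = %.3g\n",
              x$Kd, x$Kd_se, x$P_free, x$P_bound, x$rss))
  invisible(x)
}

#' Ionic-strength dependence of the apparent Kd
#'
#' Ordinary least squares of `log10(Kd_app)` on `log10([KCl])`. The slope
#' approximates the number of salt bridges in the protein-nucleic-acid
#' interface (record-counting caveats apply); a salt-insensitive
#' interaction gives slope ~ 0.
#'
#' @param kcl_M KCl concentrations (M), >= 3 values.
#' @param kd_M Apparent Kd values (M), same length.
#' @return `salt_fit`: list with `m` (slope), `b` (intercept), `m_se`,
#'   `b_se`, `kcl_M`, and the `lm` fit.
#' @examples
#' # 60-bp dsDNA ligand across 10/25/100 mM KCl:
#' salt_dependence_regression(c(0.010, 0.025, 0.100),
#'                            c(5.1e-9, 82e-9, 170e-9))
#' @export
salt_dependence_regression <- function(kcl_M, kd_M) {
  if (length(kcl_M) < 3 || length(kd_M) != length(kcl_M))
    stop("need >= 3 (KCl, Kd) pairs")
  stopifnot(all(kcl_M > 0), all(kd_M > 0))
  df <- data.frame(x = log10(kcl_M), y = log10(kd_M))
  fit <- lm(y ~ x, data = df)
  cf <- summary(fit)$coefficients
  structure(list(m = unname(cf["x", "Estimate"]),
                 b = unname(cf["(Intercept)", "Estimate"]),
                 m_se = unname(cf["x", "Std. Error"]),
                 b_se = unname(cf["(Intercept)", "Std. Error"]),
                 kcl_M = kcl_M, fit = fit),
            class = "salt_fit")
}

#' @export
print.salt_fit <- function(x, ...) {
  cat(sprintf("<salt_fit> m = %.3g +/- %.2g, b = %.3g +/- %.2g (n = %d)\n",
              x$m, x$m_se, x$b, x$b_se, length(x$kcl_M)))
  invisible(x)
}
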