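#' Kinetic rate-constant sets
#'
#' A `rate_constant_set` collects the mass-action constants describing one
#' reaction scheme: per binding pair, the association rate constant `k1`
#' (M^-1 s^-1), dissociation rate constant `k_minus1` (s^-1), and equilibrium
#' dissociation constant `Kd` (M); plus optional direct-transfer constants
#' `k_theta` (M^-1 s^-1, one per transfer reaction) and a catalytic constant
#' `k_cat` (s^-1). All constants are in molar/second units; any two of
#' \{k1, k_minus1, Kd\} determine the third through Kd = k_minus1 / k1.
#'
#' @param pairs Named list of binding pairs. Each element is a list with any
#'   of the numeric fields `k1`, `k_minus1`, `Kd` (missing members may be
#'   completed later with [complete_rate_constants()]).
#' @param k_theta Named numeric vector of direct-transfer rate constants
#'   (M^-1 s^-1), e.g. `c(D = 260, L = 260)`.
#' @param k_cat Catalytic rate constant (s^-1), or `NULL` when the scheme has
#'   no catalysis.
#'
#' @return An object of class `rate_constant_set`.
#' @examples
#' rcs <- rate_constant_set(
#'   pairs   = list(PL = list(k_minus1 = 9.1e-5, Kd = 5.1e-9)),
#'   k_theta = c(D = 260)
#' )
#' complete_rate_constants(rcs)$pairs$PL$k1
#' @export
rate_constant_set <- function(pairs = list(), k_theta = numeric(), k_cat = NULL) {
  stopifnot(is.list(pairs))
  if (length(pairs) && (is.null(names(pairs)) || any(!nzchar(names(pairs)))))
    stop("every binding pair must be named")
  for (nm in names(pairs)) {
    p <- pairs[[nm]]
    bad <- setdiff(names(p), c("k1", "k_minus1", "Kd"))
    if (length(bad))
      stop("unknown field(s) in pair '", nm, "': ", paste(bad, collapse = ", "))
    for (f in names(p)) {
      v <- p[[f]]
      if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
        stop("pair '", nm, "' field '", f, "' must be a single non-negative number")
    }
  }
  if (length(k_theta)) {
    if (is.null(names(k_theta)) || any(!nzchar(names(k_theta))))
      stop("k_theta entries must be named")
    if (any(k_theta < 0)) stop("k_theta entries must be >= 0")
  }
  if (!is.null(k_cat)) {
    if (!is.numeric(k_cat) || length(k_cat) != 1L || k_cat < 0)
      stop("k_cat must be a single non-negative number")
  }
  structure(list(pairs = pairs, k_theta = k_theta, k_cat = k_cat),
            class = "rate_constant_set")
}

#' @export
print.rate_constant_set <- function(x, ...) {
  cat("<rate_constant_set>\n")
  for (nm in names(x$pairs)) {
    p <- x$pairs[[nm]]
    cat(sprintf("  pair %-4s k1 = %-10s k_minus1 = %-10s Kd = %s\n", nm,
                if (is.null(p$k1)) "?" else format(p$k1),
                if (is.null(p$k_minus1)) "?" else format(p$k_minus1),
                if (is.null(p$Kd)) "?" else format(p$Kd)))
  }
  if (length(x$k_theta))
    cat("  k_theta:", paste(sprintf("%s = %g", names(x$k_theta), x$k_theta),
                            collapse = ", "), "\n")
  if (!is.null(x$k_cat)) cat("  k_cat:", format(x$k_cat), "\n")
  invisible(x)
}

#' Complete a partially specified rate-constant set
#'
#' For every binding pair, fills in whichever of \{k1, k_minus1, Kd\} is
#' missing from the other two using the detailed-balance relation
#' Kd = k_minus1 / k1, and checks that fully specified triples are
#' self-consistent to a relative tolerance.
#'
#' @param partial A [rate_constant_set()] in which each pair carries at least
#'   two of \{k1, k_minus1, Kd\}.
#' @param rel_tol Relative tolerance for the consistency check of complete
#'   triples (default 1e-9).
#'
#' @return A `rate_constant_set` with every pair carrying all three members.
#' @examples
#' # k1 recovered from the off-rate and affinity:
#' rcs <- rate_constant_set(list(EN = list(k_minus1 = 9.1e-5, Kd = 5.1e-9)))
#' complete_rate_constants(rcs)$pairs$EN$k1  # ~1.78e4 M^-1 s^-1
#' @export
complete_rate_constants <- function(partial, rel_tol = 1e-9) {
  stopifnot(inherits(partial, "rate_constant_set"))
  out <- partial
  for (nm in names(out$pairs)) {
    p <- out$pairs[[nm]]
    have <- !vapply(p[c("k1", "k_minus1", "Kd")], is.null, logical(1))
    names(have) <- c("k1", "k_minus1", "Kd")
    n_have <- sum(have)
    if (n_have < 2L)
      stop("underdetermined pair '", nm,
           "': need at least two of {k1, k_minus1, Kd}")
    if (n_have == 3L) {
      # consistency: Kd == k_minus1 / k1 within rel_tol
      lhs <- p$Kd * p$k1
      rhs <- p$k_minus1
      scale <- max(abs(lhs), abs(rhs), .Machine$double.xmin)
      if (abs(lhs - rhs) > rel_tol * scale)
        stop("inconsistent constants in pair '", nm,
             "': Kd * k1 = ", format(lhs), " but k_minus1 = ", format(rhs))
    } else if (!have[["k1"]]) {
      if (p$Kd == 0) {
        if (p$k_minus1 == 0)
          stop("underdetermined pair '", nm, "': Kd = 0 and k_minus1 = 0")
        stop("inconsistent constants in pair '", nm,
             "': Kd = 0 with nonzero k_minus1 implies infinite k1")
      }
      p$k1 <- p$k_minus1 / p$Kd
    } else if (!have[["k_minus1"]]) {
      p$k_minus1 <- p$Kd * p$k1
    } else {
      if (p$k1 == 0)
        stop("underdetermined pair '", nm, "': k1 = 0 leaves Kd undefined")
      p$Kd <- p$k_minus1 / p$k1
    }
    out$pairs[[nm]] <- p[c("k1", "k_minus1", "Kd")]
  }
  out
}
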