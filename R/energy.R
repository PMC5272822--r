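#' Gas constant times temperature, in kcal/mol
#'
#' The default energy constant used throughout the package is 0.592 kcal/mol,
#' the conventional RT at laboratory temperature used in reporting activation
#' free energies from rate measurements.  Supplying a temperature recomputes
#' RT = 0.0019872 * T.
#'
#' @param temperature Absolute temperature in Kelvin, or `NULL` (default) to
#'   use the fixed conventional value 0.592 kcal/mol.
#' @return RT in kcal/mol.
#' @export
#' @examples
#' rt_constant()          # 0.592
#' rt_constant(298.15)    # recomputed from T
rt_constant <- function(temperature = NULL) {
  if (is.null(temperature)) return(0.592)
  stopifnot(is.numeric(temperature), temperature > 0)
  0.0019872 * temperature
}

#' Convert a rate (or rate ratio) to a Gibbs activation energy
#'
#' Applies the transition-state convention dG = -RT log(k): a larger rate or
#' fold-acceleration maps to a more negative free energy.  Rates may be
#' absolute (1/s) or dimensionless accelerations relative to a named
#' reference condition; the transformation is the same.
#'
#' @param k Numeric vector of strictly positive rates or rate ratios.
#' @param rt Energy constant in kcal/mol (default [rt_constant()] = 0.592).
#' @param label Optional condition labels used in error messages.
#' @return Free energies in kcal/mol, same length as `k`.
#' @seealso [free_energy_to_rate()] for the inverse.
#' @export
#' @examples
#' rate_to_free_energy(1)      # 0
#' rate_to_free_energy(1e14)   # -19.08 kcal/mol
rate_to_free_energy <- function(k, rt = rt_constant(), label = NULL) {
  stopifnot(is.numeric(k), is.numeric(rt), length(rt) == 1L, rt > 0)
  bad <- !is.finite(k) | k <= 0
  if (any(bad)) {
    who <- if (!is.null(label)) paste(label[bad], collapse = ", ") else
      paste(which(bad), collapse = ", ")
    stop("rates must be finite and > 0; offending condition(s): ", who)
  }
  -rt * log(k)
}

#' Convert a Gibbs activation energy back to a rate
#'
#' Inverse of [rate_to_free_energy()]: k = exp(-dG/RT).
#'
#' @param dg Free energies, kcal/mol.
#' @param rt Energy constant in kcal/mol.
#' @return Rates (or rate ratios), strictly positive.
#' @export
free_energy_to_rate <- function(dg, rt = rt_constant()) {
  stopifnot(is.numeric(dg), is.numeric(rt), length(rt) == 1L, rt > 0)
  exp(-dg / rt)
}

#' Construct a full-factorial corner-rate table for a thermodynamic cycle
#'
#' A thermodynamic cycle is a 2^N factorial perturbation experiment.  Each
#' corner of the cycle is a combination of factor levels coded +1 (reference:
#' wild-type residue, reference metal) or -1 (perturbed), with a measured
#' rate or fold-acceleration.  The all-(+1) corner is the reference.
#'
#' @param levels Matrix (2^N x N) of corner level vectors, entries +1/-1.
#'   Column names, if present, name the factors.
#' @param rates Strictly positive rate (or acceleration) per corner.
#' @return An object of class `cycle_table`.
#' @export
#' @examples
#' lv <- as.matrix(expand.grid(TrpRS = c(1, -1), Mg = c(1, -1)))
#' cycle_table(lv, rates = c(1e14, 5, 1e9, 1))
cycle_table <- function(levels, rates) {
  levels <- as.matrix(levels)
  storage.mode(levels) <- "double"
  n <- ncol(levels)
  if (n < 1L) stop("cycle needs at least one factor")
  if (!all(levels %in% c(-1, 1)))
    stop("corner levels must be coded +1 (reference) / -1 (perturbed)")
  if (nrow(levels) != 2^n)
    stop("expected ", 2^n, " corners for ", n, " factors, got ", nrow(levels))
  key <- apply(levels, 1L, paste, collapse = ",")
  if (anyDuplicated(key)) stop("duplicate corner level vectors: ",
                               paste(unique(key[duplicated(key)]), collapse = "; "))
  full <- apply(as.matrix(expand.grid(rep(list(c(1, -1)), n))), 1L,
                paste, collapse = ",")
  missing <- setdiff(full, key)
  if (length(missing))
    stop("missing corner level vector(s): ", paste(missing, collapse = "; "))
  stopifnot(length(rates) == nrow(levels))
  if (any(!is.finite(rates) | rates <= 0))
    stop("all corner rates must be finite and > 0; offending corner(s): ",
         paste(key[!is.finite(rates) | rates <= 0], collapse = "; "))
  if (is.null(colnames(levels)))
    colnames(levels) <- paste0("F", seq_len(n))
  structure(list(levels = levels, rates = as.numeric(rates),
                 n_factors = n),
            class = "cycle_table")
}

#' @export
print.cycle_table <- function(x, ...) {
  cat("Thermodynamic cycle: 2^", x$n_factors, " = ", nrow(x$levels),
      " corners (", paste(colnames(x$levels), collapse = ", "), ")\n", sep = "")
  df <- data.frame(x$levels, rate = x$rates, check.names = FALSE)
  print(df, ...)
  invisible(x)
}

# Gray-code ordering of corner indices: consecutive corners differ in one
# factor, so the closed circuit visits every corner once.
gray_order <- function(ct) {
  n <- ct$n_factors
  g <- bitwXor(0:(2^n - 1L), bitwShiftR(0:(2^n - 1L), 1L))
  lv <- t(vapply(g, function(b) 1 - 2 * ((bitwShiftR(b, 0:(n - 1L))) %% 2),
                 numeric(n)))
  key <- apply(ct$levels, 1L, paste, collapse = ",")
  want <- apply(matrix(lv, ncol = n), 1L, paste, collapse = ",")
  match(want, key)
}

#' Check that a closed free-energy circuit sums to zero
#'
#' The total free energy change around any closed thermodynamic circuit is
#' zero; edge free energies that fail this closure indicate inconsistent
#' data or transcription errors.  Input is either a numeric vector of signed
#' edge free energies along a closed circuit, or a [cycle_table()], in which
#' case the edges are the free-energy differences along a Gray-code circuit
#' through all corners (for which closure is exact by construction).
#'
#' @param edges Numeric vector of signed edge free energies (kcal/mol) along
#'   a closed circuit, or a `cycle_table`.
#' @param nodes Optional vector of node labels visited by the circuit; if
#'   supplied, the first and last must coincide (closed circuit).
#' @param tolerance Consistency threshold in kcal/mol (default 1e-9,
#'   appropriate for noiseless data; set from replicate error otherwise).
#' @param rt Energy constant, used only when `edges` is a `cycle_table`.
#' @return List with `deviation` (abs sum, kcal/mol) and `consistent`
#'   (logical: deviation <= tolerance).
#' @export
#' @examples
#' cycle_closure(c(1, -0.4, -1, 0.4))$deviation   # 0
cycle_closure <- function(edges, nodes = NULL, tolerance = 1e-9,
                          rt = rt_constant()) {
  if (inherits(edges, "cycle_table")) {
    ord <- gray_order(edges)
    dg <- rate_to_free_energy(edges$rates[ord], rt = rt)
    edges <- diff(c(dg, dg[1L]))
  }
  stopifnot(is.numeric(edges), length(edges) >= 2L)
  if (!is.null(nodes)) {
    if (length(nodes) != length(edges) + 1L)
      stop("a circuit of ", length(edges), " edges visits ",
           length(edges) + 1L, " nodes")
    if (!identical(nodes[[1L]], nodes[[length(nodes)]]))
      stop("circuit is not closed: starts at '", nodes[[1L]],
           "', ends at '", nodes[[length(nodes)]], "'")
  }
  dev <- abs(sum(edges))
  list(deviation = dev, consistent = dev <= tolerance)
}

#' N-way non-additivity (coupling energy) of a thermodynamic cycle
#'
#' Computes the alternating corner sum of activation free energies: corners
#' with an even number of perturbed (-1) factors enter with +, odd corners
#' with -.  For N = 2 this is the textbook double-mutant-cycle formula
#' dG11 - dG10 - dG01 + dG00.  Under the package's sign convention,
#' perturbations that jointly enhance the rate (stabilize the transition
#' state) give a negative coupling energy.  For noiseless rates generated
#' from an effect-coded linear model, the N-way coupling equals 2^N times
#' the generating N-way coefficient.
#'
#' A degenerate N = 1 "cycle" returns the single edge difference
#' dG(reference) - dG(perturbed).
#'
#' @param cycle A [cycle_table()].
#' @param rt Energy constant, kcal/mol.
#' @return Coupling energy in kcal/mol (length-1 numeric).
#' @export
#' @examples
#' lv <- as.matrix(expand.grid(TrpRS = c(1, -1), Mg = c(1, -1)))
#' ct <- cycle_table(lv, rates = c(1e14, 5, 1e9, 1))
#' cycle_coupling(ct)   # about -5.86 kcal/mol
cycle_coupling <- function(cycle, rt = rt_constant()) {
  stopifnot(inherits(cycle, "cycle_table"))
  dg <- rate_to_free_energy(cycle$rates, rt = rt,
                            label = apply(cycle$levels, 1L, paste, collapse = ","))
  parity <- apply(cycle$levels, 1L, prod)   # (+1)^even, (-1)^odd perturbed
  sum(parity * dg)
}

#' Read a corner-rate table from CSV
#'
#' Expects one row per corner: factor-level columns coded -1/+1, a `rate`
#' column, and optionally a `replicate` column.  Replicated corners are
#' averaged on the free-energy (log-rate) scale before the cycle is built.
#'
#' @param file Path to a CSV file.
#' @param rt Energy constant used for replicate averaging on the log scale.
#' @return A [cycle_table()].
#' @export
read_cycle_csv <- function(file, rt = rt_constant()) {
  df <- utils::read.csv(file, check.names = FALSE)
  if (!"rate" %in% names(df)) stop("CSV must contain a 'rate' column")
  fac <- setdiff(names(df), c("rate", "replicate"))
  lv <- as.matrix(df[fac])
  key <- apply(lv, 1L, paste, collapse = ",")
  dg <- tapply(rate_to_free_energy(df$rate, rt = rt), key, mean)
  ukey <- names(dg)
  ulv <- lv[match(ukey, key), , drop = FALSE]
  cycle_table(ulv, free_energy_to_rate(as.numeric(dg), rt = rt))
}
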