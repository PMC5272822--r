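#' Define a metal-ligand binding equilibrium system
#'
#' Total concentrations and dissociation constants for simultaneous 1:1
#' Mg2+-ligand equilibria (at minimum ATP and EDTA in the depletion assay).
#' Dissociation constants are conditional constants at assay pH; defaults
#' for the Mg.ATP and Mg.EDTA pairs live in [default_kd()].
#'
#' @param mg_total Total Mg2+ concentration, M (>= 0).
#' @param ligands Data frame with columns `name`, `total` (M, >= 0) and
#'   `kd` (M, > 0); may have zero rows.
#' @return Object of class `equilibrium_system`.
#' @export
#' @examples
#' equilibrium_system(1e-5, data.frame(name = c("ATP", "EDTA"),
#'                                     total = c(1e-4, 1e-5),
#'                                     kd = default_kd()))
equilibrium_system <- function(mg_total, ligands = data.frame(
                                 name = character(), total = numeric(),
                                 kd = numeric())) {
  stopifnot(is.numeric(mg_total), length(mg_total) == 1L,
            is.finite(mg_total), mg_total >= 0)
  ligands <- as.data.frame(ligands)
  if (nrow(ligands)) {
    stopifnot(all(c("name", "total", "kd") %in% names(ligands)),
              all(is.finite(ligands$total)), all(ligands$total >= 0),
              all(is.finite(ligands$kd)), all(ligands$kd > 0))
  }
  structure(list(mg_total = mg_total, ligands = ligands),
            class = "equilibrium_system")
}

#' Default conditional dissociation constants (M)
#'
#' Documented defaults for the two chelation equilibria of the depletion
#' assay: Mg.ATP on the 10^-4.5 M scale and Mg.EDTA sub-nanomolar
#' (10^-9.5 M) at assay pH.  These are conditional constants; override them
#' for other buffer conditions.  Parameter recovery from synthetic
#' titrations is insensitive to the choice as long as generation and
#' fitting share the same constants.
#'
#' @return Named numeric vector `c(ATP = , EDTA = )`, M.
#' @export
default_kd <- function() c(ATP = 10^-4.5, EDTA = 10^-9.5)

#' Solve simultaneous metal-ligand binding equilibria
#'
#' Finds free Mg2+ as the unique root of the metal conservation equation
#' `mg_total = m (1 + sum_j total_j / (kd_j + m))`, where each ligand's
#' free and complexed concentrations are closed-form in m.  The root is
#' bracketed on log(m) and polished by Newton iteration to a conservation
#' residual below 1e-10 relative.
#'
#' @param system An [equilibrium_system()].
#' @return Object of class `speciation`: `mg_free` (M), data frame
#'   `ligands` with `free` and `complexed` columns, and the relative
#'   conservation residuals.
#' @export
solve_speciation <- function(system) {
  stopifnot(inherits(system, "equilibrium_system"))
  mg <- system$mg_total
  lig <- system$ligands
  if (mg == 0 || nrow(lig) == 0L) {
    m <- mg
  } else {
    tot <- lig$total; kd <- lig$kd
    g <- function(m) m * (1 + sum(tot / (kd + m))) - mg
    lo <- log(mg) - 80; hi <- log(mg)
    if (g(exp(lo)) > 0 || g(exp(hi)) < 0)
      stop("internal error: conservation equation not bracketed")
    m <- exp(stats::uniroot(function(u) g(exp(u)), c(lo, hi),
                            tol = 1e-15)$root)
    # Newton polish on the conservation residual
    for (i in 1:50) {
      gm <- g(m)
      if (abs(gm) <= 1e-14 * mg) break
      m <- m - gm / (1 + sum(tot * kd / (kd + m)^2))
      if (m <= 0) { m <- .Machine$double.xmin; break }
    }
  }
  if (nrow(lig)) {
    lig$free <- lig$total * lig$kd / (lig$kd + m)
    lig$complexed <- lig$total * m / (lig$kd + m)
  } else {
    lig$free <- numeric(0); lig$complexed <- numeric(0)
  }
  mg_res <- if (mg > 0) abs(m + sum(lig$complexed) - mg) / mg else 0
  lig_res <- if (nrow(lig)) ifelse(lig$total > 0,
    abs(lig$free + lig$complexed - lig$total) / pmax(lig$total, 1e-300), 0)
    else numeric(0)
  structure(list(mg_free = m, ligands = lig,
                 residual_mg = mg_res, residual_ligands = lig_res),
            class = "speciation")
}

#' @export
print.speciation <- function(x, digits = 4, ...) {
  cat("Speciation: free Mg2+ =", signif(x$mg_free, digits), "M\n")
  if (nrow(x$ligands))
    print(within(x$ligands, {
      free <- signif(free, digits); complexed <- signif(complexed, digits)
    }), row.names = FALSE)
  invisible(x)
}

#' Predicted activity of the metal-depletion model
#'
#' Two-parameter saturable model of catalytic activity versus free Mg2+: a
#' metal-free floor `f` (the fractional rate retained with no metal) plus a
#' single transition-state Mg2+ site with dissociation constant `kd_ts`:
#' `v = v_max (f + (1 - f) m / (m + kd_ts))`.  Limits: `f v_max` as m -> 0
#' and `v_max` at saturating Mg2+.
#'
#' @param mg_free Free Mg2+ concentration(s), M, >= 0.
#' @param f Metal-free rate fraction, in (0, 1].
#' @param kd_ts Transition-state Mg2+ dissociation constant, M, > 0.
#' @param v_max Rate at saturating Mg2+ (default 1: fractional activity).
#' @return Predicted rate(s).
#' @export
#' @examples
#' predicted_activity(120e-9, f = 1.1e-5, kd_ts = 120e-9)  # ~ v_max / 2
predicted_activity <- function(mg_free, f, kd_ts, v_max = 1) {
  stopifnot(all(mg_free >= 0), f > 0, f <= 1, kd_ts > 0, v_max > 0)
  v_max * (f + (1 - f) * mg_free / (mg_free + kd_ts))
}

# free Mg at each EDTA total, all other constants fixed
mg_free_on_grid <- function(edta_total, mg_total, atp_total,
                            kd_atp, kd_edta) {
  vapply(edta_total, function(e) {
    solve_speciation(equilibrium_system(mg_total, data.frame(
      name = c("ATP", "EDTA"), total = c(atp_total, e),
      kd = c(kd_atp, kd_edta))))$mg_free
  }, numeric(1))
}

#' Fit the two-parameter metal-depletion model to an EDTA titration
#'
#' Models the EDTA dependence of the logarithm of enzymatic activity: each
#' EDTA total is converted to free Mg2+ by [solve_speciation()] under the
#' supplied chelation constants, and log-activity is fit by nonlinear least
#' squares to `log(k_act E (f + (1 - f) m/(m + kd_ts)))`, jointly across
#' enzyme concentrations (v_max per series is k_act x enzyme).  The fit is
#' on log-activity to stabilize the multi-decade dynamic range of the
#' titration.  Parameters are estimated on the log10 scale (positivity) and
#' reported on the natural scale with delta-method standard errors.
#'
#' @param edta_total EDTA totals, M (>= 6 points; the series should extend
#'   past the Mg-depletion point so the metal-free plateau is visible).
#' @param activity Observed activities, > 0.
#' @param enzyme_conc Enzyme concentration per observation (one value or a
#'   vector defining the series), M.
#' @param mg_total,atp_total Residual metal and ATP totals, M.
#' @param kd_atp,kd_edta Chelation constants, M (defaults [default_kd()]).
#' @return Object of class `depletion_fit`: `f`, `kd_ts` (M), `k_act`,
#'   `v_max` per series, standard errors, identifiability flags
#'   (`kd_identifiable`, `plateau_reached`) and the per-point free-Mg grid.
#' @export
fit_depletion <- function(edta_total, activity, enzyme_conc = 1,
                          mg_total, atp_total,
                          kd_atp = default_kd()[["ATP"]],
                          kd_edta = default_kd()[["EDTA"]]) {
  stopifnot(length(edta_total) == length(activity),
            all(is.finite(edta_total)), all(edta_total >= 0),
            all(is.finite(activity)), all(activity > 0))
  if (length(edta_total) < 6L)
    stop("need >= 6 EDTA points spanning the depletion transition")
  if (length(enzyme_conc) == 1L)
    enzyme_conc <- rep(enzyme_conc, length(edta_total))
  stopifnot(length(enzyme_conc) == length(activity), all(enzyme_conc > 0))
  m <- mg_free_on_grid(edta_total, mg_total, atp_total, kd_atp, kd_edta)
  ly <- log(activity)
  # series plateau diagnostic: range of per-enzyme activity
  rng <- max(activity / enzyme_conc) / min(activity / enzyme_conc)
  if (rng < 1.5) {
    # flat series: metal-independent enzyme; kd_ts carries no information
    kact <- exp(mean(ly - log(enzyme_conc)))
    out <- list(f = min(1, rng^-1), f_se = NA_real_,
                kd_ts = NA_real_, kd_ts_se = NA_real_,
                k_act = kact, k_act_se = NA_real_,
                v_max = kact * unique(enzyme_conc),
                kd_identifiable = FALSE, plateau_reached = NA,
                mg_free = m, edta_total = edta_total,
                activity = activity, enzyme_conc = enzyme_conc,
                fitted.values = rep(exp(mean(ly)), length(ly)),
                residuals = ly - mean(ly))
    return(structure(out, class = "depletion_fit"))
  }
  # data-driven starts: floor ratio, half-transition free Mg, top activity
  f0 <- max(min(activity / enzyme_conc) / max(activity / enzyme_conc),
            1e-12)
  kact0 <- max(activity / enzyme_conc)
  # half-transition on the normalized log scale locates kd_ts on the
  # free-Mg axis
  a_norm <- activity / (enzyme_conc * kact0)
  kd0 <- max(m[which.min(abs(log(a_norm) - log(f0) / 2))], 1e-12)
  dat <- data.frame(ly = ly, m = m, E = enzyme_conc)
  form <- ly ~ log(10^lk * E * (10^lf + (1 - 10^lf) * m / (m + 10^lkd)))
  st <- list(lf = log10(f0), lkd = log10(kd0), lk = log10(kact0))
  fit <- tryCatch(
    stats::nls(form, data = dat, start = st,
               control = stats::nls.control(maxiter = 500,
                                            scaleOffset = 1,
                                            minFactor = 1e-14)),
    error = function(e)
      tryCatch(minpack.lm::nlsLM(form, data = dat, start = st,
                                 control = minpack.lm::nls.lm.control(
                                   maxiter = 1000, ftol = 1e-15,
                                   ptol = 1e-15)),
               error = function(e2)
                 stop("depletion fit did not converge (starts: f = ",
                      signif(f0, 3), ", kd_ts = ", signif(kd0, 3),
                      "): ", conditionMessage(e2))))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e)
                   stats::setNames(rep(NA_real_, 3L), names(cf)))
  f_hat <- min(10^cf[["lf"]], 1)
  kd_hat <- 10^cf[["lkd"]]
  kact_hat <- 10^cf[["lk"]]
  ln10 <- log(10)
  # plateau reached if the metal-free floor dominates at the deepest
  # depletion point actually measured
  m_min <- min(m)
  floor_share <- f_hat / (f_hat + (1 - f_hat) * m_min / (m_min + kd_hat))
  plateau <- is.finite(floor_share) && floor_share > 0.5
  structure(list(f = f_hat, f_se = ln10 * f_hat * se[["lf"]],
                 kd_ts = kd_hat, kd_ts_se = ln10 * kd_hat * se[["lkd"]],
                 k_act = kact_hat,
                 k_act_se = ln10 * kact_hat * se[["lk"]],
                 v_max = kact_hat * sort(unique(enzyme_conc)),
                 kd_identifiable = plateau,
                 plateau_reached = plateau,
                 mg_free = m, edta_total = edta_total,
                 activity = activity, enzyme_conc = enzyme_conc,
                 fitted.values = exp(stats::fitted(fit)),
                 residuals = as.numeric(stats::resid(fit)),
                 nls = fit),
            class = "depletion_fit")
}

#' @export
print.depletion_fit <- function(x, digits = 4, ...) {
  cat("Metal-depletion fit: v = v_max (f + (1-f) m/(m + Kd))\n")
  cat(sprintf("  f     = %.*g (metal-free rate fraction%s)\n", digits, x$f,
              if (is.finite(x$f_se)) sprintf(", se %.2g", x$f_se) else ""))
  if (is.finite(x$kd_ts))
    cat(sprintf("  Kd(TS) = %.*g M = %.*g nM%s%s\n", digits, x$kd_ts,
                digits, x$kd_ts * 1e9,
                if (is.finite(x$kd_ts_se))
                  sprintf(" (se %.2g M)", x$kd_ts_se) else "",
                if (!isTRUE(x$plateau_reached))
                  "  [weakly identified: plateau not reached]" else ""))
  else
    cat("  Kd(TS) unidentifiable: activity flat across the titration\n")
  cat(sprintf("  v_max per series: %s\n",
              paste(signif(x$v_max, digits), collapse = ", ")))
  invisible(x)
}

#' @export
coef.depletion_fit <- function(object, ...)
  c(f = object$f, kd_ts = object$kd_ts, k_act = object$k_act)

#' @export
fitted.depletion_fit <- function(object, ...) object$fitted.values

#' @export
residuals.depletion_fit <- function(object, ...) object$residuals

#' @export
predict.depletion_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(object$fitted.values)
  m <- if (is.list(newdata)) newdata$mg_free else newdata
  predicted_activity(m, object$f, object$kd_ts, object$k_act)
}

#' @export
plot.depletion_fit <- function(x, ...) {
  graphics::plot(x$edta_total, log10(x$activity), xlab = "EDTA total (M)",
                 ylab = "log10 activity", log = "x", ...)
  graphics::points(x$edta_total, log10(x$fitted.values), pch = 3,
                   col = "red3")
  invisible(x)
}

#' Read an EDTA-titration CSV
#'
#' @param file CSV with columns `edta_total`, `activity` and optionally
#'   `enzyme_conc`.
#' @return Data frame.
#' @export
read_titration_csv <- function(file) {
  df <- utils::read.csv(file)
  if (is.null(df$edta_total) || is.null(df$activity))
    stop("CSV must contain 'edta_total' and 'activity' columns")
  if (is.null(df$enzyme_conc)) df$enzyme_conc <- 1
  df
}
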