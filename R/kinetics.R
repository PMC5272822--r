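#' Fit Michaelis-Menten steady-state kinetics
#'
#' Nonlinear least squares of v = kcat * E * S / (KM + S), initialized
#' deterministically from the Hanes-Woolf linearization (S/v regressed on
#' S), so identical inputs always give identical fits.
#'
#' @param substrate Substrate concentrations (>= 4 points; for a well-posed
#'   fit at least one point below and one above the true KM).
#' @param rate Observed rates, 1/s (same length as `substrate`).
#' @param enzyme Total (active) enzyme concentration, same units as
#'   `substrate` times whatever makes `rate` 1/s per enzyme; default 1 so
#'   the fitted kcat is v_max.
#' @return Object of class `mm_fit`: `kcat`, `KM`, standard errors,
#'   `km_identifiable` (FALSE when the data do not constrain KM, e.g. all
#'   points saturating), fitted values and residuals.
#' @export
#' @examples
#' S <- c(12.5, 25, 50, 100, 200, 400, 800)
#' v <- 5 * S / (100 + S)
#' fit_michaelis_menten(S, v)
fit_michaelis_menten <- function(substrate, rate, enzyme = 1) {
  stopifnot(is.numeric(substrate), is.numeric(rate),
            length(substrate) == length(rate),
            all(is.finite(substrate)), all(is.finite(rate)),
            all(substrate > 0), length(enzyme) == 1L, enzyme > 0)
  if (length(substrate) < 4L)
    stop("need at least 4 substrate points, got ", length(substrate))
  # Hanes-Woolf: S/v = KM/(kcat E) + S/(kcat E)
  hw <- stats::lm.fit(cbind(1, substrate), substrate / pmax(rate, .Machine$double.eps))
  kcat0 <- unname(1 / (hw$coefficients[2L] * enzyme))
  km0 <- unname(hw$coefficients[1L] * kcat0 * enzyme)
  if (!is.finite(kcat0) || kcat0 <= 0) kcat0 <- max(rate) / enzyme
  if (!is.finite(km0) || km0 <= 0) km0 <- stats::median(substrate)
  dat <- data.frame(S = substrate, v = rate)
  fit <- tryCatch(
    stats::nls(v ~ kcat * enzyme * S / (KM + S), data = dat,
               start = list(kcat = kcat0, KM = km0),
               control = stats::nls.control(maxiter = 200,
                                            scaleOffset = 1,
                                            minFactor = 1e-12)),
    error = function(e)
      tryCatch(minpack.lm::nlsLM(v ~ kcat * enzyme * S / (KM + S),
                                 data = dat,
                                 start = list(kcat = kcat0, KM = km0),
                                 control = minpack.lm::nls.lm.control(
                                   maxiter = 500)),
               error = function(e2)
                 stop("Michaelis-Menten fit did not converge (last start: ",
                      "kcat = ", signif(kcat0, 4), ", KM = ",
                      signif(km0, 4), "): ", conditionMessage(e2))))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(kcat = NA_real_, KM = NA_real_))
  # all-saturating data leave KM unconstrained from below
  km_ok <- is.finite(cf[["KM"]]) && cf[["KM"]] > 0 &&
    cf[["KM"]] > min(substrate) / 100 &&
    (!is.finite(se[["KM"]]) || se[["KM"]] < abs(cf[["KM"]])) &&
    min(substrate) < 2 * cf[["KM"]]
  structure(list(kcat = cf[["kcat"]], KM = cf[["KM"]],
                 kcat_se = se[["kcat"]], KM_se = se[["KM"]],
                 km_identifiable = km_ok,
                 enzyme = enzyme,
                 fitted.values = stats::fitted(fit),
                 residuals = stats::resid(fit),
                 data = dat, nls = fit),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, digits = 4, ...) {
  cat("Michaelis-Menten fit (v = kcat.E.S/(KM+S))\n")
  cat(sprintf("  kcat = %.*g /s (se %.2g)\n", digits, x$kcat, x$kcat_se))
  cat(sprintf("  KM   = %.*g (se %.2g)%s\n", digits, x$KM, x$KM_se,
              if (!x$km_identifiable) "  [KM unidentifiable: data saturating]"
              else ""))
  invisible(x)
}

#' @export
coef.mm_fit <- function(object, ...) c(kcat = object$kcat, KM = object$KM)

#' @export
fitted.mm_fit <- function(object, ...) object$fitted.values

#' @export
residuals.mm_fit <- function(object, ...) object$residuals

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  S <- if (is.null(newdata)) object$data$S else
    (if (is.list(newdata)) newdata$S else newdata)
  object$kcat * object$enzyme * S / (object$KM + S)
}

#' Construct an active-site-titration time course
#'
#' Pre-steady-state product time course: an exponential burst (amplitude
#' proportional to active enzyme) followed by linear steady-state turnover.
#'
#' @param times Seconds, strictly increasing, >= 5 points spanning both the
#'   burst and the linear phase.
#' @param product Product signal (concentration or proportional counts).
#' @param enzyme_total Total enzyme concentration, product units.
#' @param active_fraction Fraction of enzyme that is catalytically active,
#'   in (0, 1]; determined experimentally by active-site titration,
#'   default 1.
#' @return Object of class `time_course`.
#' @export
time_course <- function(times, product, enzyme_total = 1,
                        active_fraction = 1) {
  stopifnot(is.numeric(times), is.numeric(product),
            length(times) == length(product),
            all(is.finite(times)), all(is.finite(product)),
            length(enzyme_total) == 1L, enzyme_total > 0,
            length(active_fraction) == 1L,
            active_fraction > 0, active_fraction <= 1)
  if (length(times) < 5L)
    stop("need >= 5 time points spanning burst and linear phases")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing (violation at index ",
         which(diff(times) <= 0)[1L] + 1L, ")")
  structure(list(times = as.numeric(times), product = as.numeric(product),
                 enzyme_total = enzyme_total,
                 active_fraction = active_fraction),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat("Active-site-titration time course: ", length(x$times),
      " points, t in [", min(x$times), ", ", max(x$times), "] s, E_total = ",
      x$enzyme_total, " (active fraction ", x$active_fraction, ")\n",
      sep = "")
  invisible(x)
}

# deterministic starting values for the burst fit: steady-state slope and
# intercept from the tail, chemical rate from the early log-decay
burst_start <- function(t, p) {
  n <- length(t)
  tail_i <- seq.int(max(3L, floor(n / 2)), n)
  tl <- stats::lm.fit(cbind(1, t[tail_i]), p[tail_i])
  vss0 <- unname(max(tl$coefficients[2L], 0))
  i0 <- unname(tl$coefficients[1L])          # = A + C on the asymptote
  dev <- i0 + vss0 * t - p                   # ~ A exp(-k t) early on
  pos <- which(dev > 0)
  k0 <- if (length(pos) >= 2L) {
    i1 <- pos[1L]; i2 <- pos[2L]
    max((log(dev[i1]) - log(dev[i2])) / (t[i2] - t[i1]), 1 / max(t))
  } else 1 / t[2L]
  list(A = max(i0, max(p) * 0.1), k_chem = k0, v_ss = vss0, C = 0)
}

# Gauss-Newton refinement with the analytic jacobian: drives noiseless
# fits to machine precision beyond the optimizer's stopping tolerance
burst_polish <- function(cf, t, p, iters = 8L) {
  best <- cf
  rss <- function(th) sum((p - th[["A"]] * (1 - exp(-th[["k_chem"]] * t)) -
                             th[["v_ss"]] * t - th[["C"]])^2)
  best_rss <- rss(best)
  th <- best
  for (i in seq_len(iters)) {
    e <- exp(-th[["k_chem"]] * t)
    r <- p - th[["A"]] * (1 - e) - th[["v_ss"]] * t - th[["C"]]
    J <- cbind(1 - e, th[["A"]] * t * e, t, rep(1, length(t)))
    step <- tryCatch(solve(crossprod(J), crossprod(J, r)),
                     error = function(err) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    th[] <- unlist(th) + as.numeric(step)
    if (th[["A"]] < 0 || th[["k_chem"]] <= 0) break
    cur <- rss(th)
    if (!is.finite(cur) || cur > best_rss) break
    best <- th; best_rss <- cur
  }
  best
}

#' Fit burst (active-site titration) kinetics
#'
#' Fits the standard burst equation
#' P(t) = A (1 - exp(-k_chem t)) + v_ss t + C
#' to a product time course by nonlinear least squares with deterministic
#' initialization (no random restarts).  The exponential phase reports the
#' first-order rate of the chemical step, k_chem; the linear phase reports
#' steady-state turnover, with kcat = v_ss / (enzyme_total x
#' active_fraction).  Their ratio k_chem/kcat measures how much faster the
#' chemical step is than turnover; it is unit-free (any rescaling of the
#' product axis cancels) and is flagged undefined when the burst amplitude
#' is indistinguishable from zero.
#'
#' @param tc A [time_course()], or a numeric vector of times (then supply
#'   `product`).
#' @param product,enzyme_total,active_fraction Used only when `tc` is a
#'   plain numeric vector of times.
#' @return Object of class `burst_fit`: `A`, `k_chem`, `v_ss`, `C`,
#'   `kcat`, `ratio` (k_chem/kcat), standard errors, `burst_detected`.
#' @export
#' @examples
#' t <- c(seq(1e-4, 2e-3, length.out = 12), seq(0.01, 1, length.out = 12))
#' p <- 1 * (1 - exp(-3125 * t)) + 5 * t
#' fit_burst(time_course(t, p))
fit_burst <- function(tc, product = NULL, enzyme_total = 1,
                      active_fraction = 1) {
  if (!inherits(tc, "time_course"))
    tc <- time_course(tc, product, enzyme_total, active_fraction)
  t <- tc$times; p <- tc$product
  st <- burst_start(t, p)
  dat <- data.frame(t = t, p = p)
  form <- p ~ A * (1 - exp(-k_chem * t)) + v_ss * t + C
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = st,
                      lower = c(0, 1e-12, 0, -Inf),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 1000, ftol = 1e-15, ptol = 1e-15)),
    error = function(e)
      tryCatch(stats::nls(form, data = dat, start = st,
                          algorithm = "port",
                          lower = c(A = 0, k_chem = 1e-12, v_ss = 0,
                                    C = -Inf),
                          control = stats::nls.control(maxiter = 500)),
               error = function(e2) NULL))
  if (is.null(fit)) {
    # no resolvable burst: fall back to the degenerate straight-line limit
    ln <- stats::lm(p ~ t)
    cf <- c(A = 0, k_chem = NA_real_,
            v_ss = unname(stats::coef(ln)[2L]),
            C = unname(stats::coef(ln)[1L]))
    se <- c(A = NA_real_, k_chem = NA_real_,
            v_ss = summary(ln)$coefficients[2L, 2L],
            C = summary(ln)$coefficients[1L, 2L])
    fitted_v <- stats::fitted(ln); res <- stats::resid(ln)
  } else {
    cf <- burst_polish(stats::coef(fit), t, p)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e)
                     stats::setNames(rep(NA_real_, 4L), names(cf)))
    fitted_v <- cf[["A"]] * (1 - exp(-cf[["k_chem"]] * t)) +
      cf[["v_ss"]] * t + cf[["C"]]
    res <- p - fitted_v
  }
  active <- tc$enzyme_total * tc$active_fraction
  kcat <- cf[["v_ss"]] / active
  # burst amplitude must stand clear of zero for the ratio to mean anything
  amp_scale <- max(abs(p)) * 1e-8 + 2 * (if (is.finite(se[["A"]])) se[["A"]] else 0)
  burst_detected <- is.finite(cf[["A"]]) && cf[["A"]] > amp_scale &&
    is.finite(cf[["k_chem"]])
  ratio <- if (burst_detected && kcat > 0) cf[["k_chem"]] / kcat else NA_real_
  structure(list(A = cf[["A"]], k_chem = cf[["k_chem"]],
                 v_ss = cf[["v_ss"]], C = cf[["C"]],
                 se = se, kcat = kcat, ratio = ratio,
                 burst_detected = burst_detected,
                 enzyme_total = tc$enzyme_total,
                 active_fraction = tc$active_fraction,
                 fitted.values = as.numeric(fitted_v),
                 residuals = as.numeric(res),
                 time_course = tc),
            class = "burst_fit")
}

#' @export
print.burst_fit <- function(x, digits = 4, ...) {
  cat("Burst-kinetics fit: P(t) = A(1 - exp(-k_chem t)) + v_ss t + C\n")
  cat(sprintf("  A      = %.*g (burst amplitude)\n", digits, x$A))
  cat(sprintf("  k_chem = %.*g /s (chemical step; 1/k = %.3g s)\n",
              digits, x$k_chem,
              if (is.finite(x$k_chem)) 1 / x$k_chem else NA))
  cat(sprintf("  v_ss   = %.*g /s (steady-state slope)\n", digits, x$v_ss))
  cat(sprintf("  kcat   = %.*g /s (v_ss / active enzyme)\n", digits, x$kcat))
  if (x$burst_detected)
    cat(sprintf("  k_chem/kcat = %.*g\n", digits, x$ratio))
  else
    cat("  k_chem/kcat undefined: burst amplitude indistinguishable from 0\n")
  invisible(x)
}

#' @export
coef.burst_fit <- function(object, ...)
  c(A = object$A, k_chem = object$k_chem, v_ss = object$v_ss, C = object$C)

#' @export
fitted.burst_fit <- function(object, ...) object$fitted.values

#' @export
residuals.burst_fit <- function(object, ...) object$residuals

#' @export
predict.burst_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$time_course$times else
    (if (is.list(newdata)) newdata$t else newdata)
  a <- if (is.finite(object$A)) object$A else 0
  k <- if (is.finite(object$k_chem)) object$k_chem else 0
  a * (1 - exp(-k * t)) + object$v_ss * t + object$C
}

#' @export
plot.burst_fit <- function(x, ...) {
  t <- x$time_course$times
  graphics::plot(t, x$time_course$product, xlab = "time (s)",
                 ylab = "product", ...)
  tt <- seq(min(t), max(t), length.out = 300)
  graphics::lines(tt, predict(x, tt), col = "red3")
  invisible(x)
}

#' Characteristic time of the chemical step
#'
#' The reciprocal of the first-order chemical rate constant: the time scale
#' on which the chemical step completes (milliseconds for fast synthetase
#' chemistry).
#'
#' @param k_chem First-order rate, 1/s, > 0.
#' @return Time in seconds.
#' @export
#' @examples
#' chem_step_time(3125)   # 3.2e-4 s
chem_step_time <- function(k_chem) {
  stopifnot(is.numeric(k_chem), all(k_chem > 0))
  1 / k_chem
}

#' Read a (time, signal) CSV time course
#'
#' @param file CSV with columns `time` and `signal` (or `product`).
#' @param enzyme_total,active_fraction Passed to [time_course()].
#' @return A [time_course()].
#' @export
read_time_course_csv <- function(file, enzyme_total = 1,
                                 active_fraction = 1) {
  df <- utils::read.csv(file)
  sig <- if ("signal" %in% names(df)) df$signal else df$product
  if (is.null(df$time) || is.null(sig))
    stop("CSV must contain 'time' and 'signal' (or 'product') columns")
  time_course(df$time, sig, enzyme_total, active_fraction)
}
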