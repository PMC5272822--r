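#' Construct an effect-coded factorial design of free-energy responses
#'
#' Represents a 2^N combinatorial perturbation experiment (point mutations
#' and, optionally, a metal substitution) in the effect coding of the
#' coupling regression: every factor level is +1 (wild-type residue /
#' reference metal) or -1 (mutant / substituted metal).  Responses are
#' Gibbs activation energies; alternatively rates may be supplied and are
#' converted via [rate_to_free_energy()].
#'
#' @param levels Matrix or data frame (n_obs x N) of +1/-1 levels; column
#'   names are the factor names.  Rows repeat for replicates.
#' @param dG Free-energy responses, kcal/mol (one per row of `levels`).
#' @param rates Alternative to `dG`: strictly positive rates, converted with
#'   `rt`.
#' @param replicate Optional replicate identifiers (integer per row).
#' @param response_kind Which free energy is modeled: one of `"kcat"`,
#'   `"KM"`, `"kcat/KM"`, `"kchem"`, `"specificity"`.
#' @param rt Energy constant for rate conversion.
#' @return Object of class `factorial_design` with elements `levels`,
#'   `response`, `replicate`, `factor_names`, `response_kind`,
#'   `full_factorial` (TRUE iff all 2^N level vectors are present).
#' @export
factorial_design <- function(levels, dG = NULL, rates = NULL,
                             replicate = NULL,
                             response_kind = c("kcat", "KM", "kcat/KM",
                                               "kchem", "specificity"),
                             rt = rt_constant()) {
  response_kind <- match.arg(response_kind)
  levels <- as.matrix(levels)
  storage.mode(levels) <- "double"
  if (is.null(colnames(levels)))
    colnames(levels) <- paste0("F", seq_len(ncol(levels)))
  if (!all(levels %in% c(-1, 1)))
    stop("all factor levels must be +1 (reference) or -1 (perturbed)")
  if (is.null(dG) == is.null(rates))
    stop("supply exactly one of 'dG' or 'rates'")
  if (is.null(dG)) dG <- rate_to_free_energy(rates, rt = rt)
  stopifnot(length(dG) == nrow(levels), all(is.finite(dG)))
  if (!is.null(replicate)) stopifnot(length(replicate) == nrow(levels))
  n <- ncol(levels)
  key <- apply(levels, 1L, paste, collapse = ",")
  full <- length(unique(key)) == 2^n
  structure(list(levels = levels, response = as.numeric(dG),
                 replicate = replicate,
                 factor_names = colnames(levels),
                 response_kind = response_kind,
                 full_factorial = full),
            class = "factorial_design")
}

#' @export
print.factorial_design <- function(x, ...) {
  cat("Effect-coded factorial design: ", length(x$factor_names),
      " factor(s) (", paste(x$factor_names, collapse = ", "), "), ",
      length(x$response), " observations",
      if (x$full_factorial) ", full 2^N coverage" else " (incomplete)",
      "\nResponse: dG(", x$response_kind, "), kcal/mol\n", sep = "")
  invisible(x)
}

# all factor subsets of size 1..max_order, ordered by order then position
term_subsets <- function(factor_names, max_order) {
  n <- length(factor_names)
  out <- list()
  for (ord in seq_len(max_order))
    out <- c(out, utils::combn(factor_names, ord, simplify = FALSE))
  out
}

#' Build the effect-coded design matrix of the coupling regression
#'
#' One column per model term: the intercept column is all +1, and the column
#' for a factor subset S at a given condition is the product of that
#' condition's levels over the factors in S.  On a balanced full factorial
#' the columns are mutually orthogonal (X'X = n I).
#'
#' @param design A [factorial_design()], or a +1/-1 level matrix.
#' @param max_order Highest interaction order to include, or `"saturated"`
#'   (all 2^N terms).
#' @return Numeric matrix with named columns; term names join factor names
#'   with `:`, intercept `"(Intercept)"`.  Attribute `"order"` gives each
#'   column's interaction order (0 for the intercept).
#' @export
#' @examples
#' d <- as.matrix(expand.grid(A = c(1, -1), B = c(1, -1)))
#' build_design_matrix(d)          # 4 x 4, orthogonal columns
build_design_matrix <- function(design, max_order = "saturated") {
  lv <- if (inherits(design, "factorial_design")) design$levels
        else as.matrix(design)
  n <- ncol(lv)
  key <- apply(lv, 1L, paste, collapse = ",")
  if (identical(max_order, "saturated")) max_order <- n
  stopifnot(max_order >= 0, max_order <= n)
  subsets <- if (max_order >= 1L) term_subsets(colnames(lv), max_order)
             else list()
  X <- cbind("(Intercept)" = rep(1, nrow(lv)))
  ord <- 0L
  for (s in subsets) {
    X <- cbind(X, apply(lv[, s, drop = FALSE], 1L, prod))
    colnames(X)[ncol(X)] <- paste(s, collapse = ":")
    ord <- c(ord, length(s))
  }
  attr(X, "order") <- ord
  X
}

#' Fit the effect-coded coupling regression on free energies
#'
#' Ordinary least squares of the Gibbs-energy responses on the effect-coded
#' design matrix.  Coefficients are intrinsic (main-effect) and coupling
#' (interaction) free-energy contributions in kcal/mol; for each term the
#' cycle-energy scale 2^order x coefficient is also reported, which for the
#' highest-order term of a noiseless full factorial equals the N-way
#' non-additivity of [cycle_coupling()].  Per-term t tests use the residual
#' degrees of freedom; a saturated fit with one replicate per condition has
#' zero residual df and its standard errors are reported as `NA`
#' (unavailable), never fabricated.
#'
#' @param design A [factorial_design()].
#' @param max_order Highest interaction order, or `"saturated"`.
#' @param p_adjust Multiple-testing adjustment for per-term p values:
#'   `"none"` (default, matching per-term t tests) or `"holm"`.
#' @param weights Optional observation weights (default unweighted OLS).
#' @return Object of class `coupling_fit`; see [summary.coupling_fit()],
#'   [coupling_terms()], [term_histogram()].
#' @export
#' @examples
#' sim <- gen_factorial_dataset(c("I4", "F26"), c("I4:F26" = -1.25),
#'                              sigma = 0, replicates = 1)
#' fit <- fit_coupling(sim)
#' coef(fit)["I4:F26"]    # -1.25
fit_coupling <- function(design, max_order = "saturated",
                         p_adjust = c("none", "holm"), weights = NULL) {
  stopifnot(inherits(design, "factorial_design"))
  p_adjust <- match.arg(p_adjust)
  X <- build_design_matrix(design, max_order)
  y <- design$response
  if (nrow(X) < ncol(X))
    stop("underdetermined model: ", nrow(X), " observations for ",
         ncol(X), " terms; lower max_order or add replicates")
  # contradictory duplicate rows are legal (replicates); a missing-corner
  # design loses orthogonality, so warn that shortcut interpretations fail
  if (!design$full_factorial)
    warning("design is not a full factorial; coefficients are OLS ",
            "estimates, not corner-parity averages")
  fit <- if (is.null(weights)) stats::lm.fit(X, y)
         else stats::lm.wfit(X, y, w = weights)
  if (fit$rank < ncol(X))
    stop("design matrix is rank deficient (rank ", fit$rank, " < ",
         ncol(X), " terms): conditions do not identify all requested terms")
  beta <- fit$coefficients
  df_resid <- length(y) - ncol(X)
  rss <- sum(fit$residuals^2)
  s2 <- if (df_resid > 0) rss / df_resid else NA_real_
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- if (df_resid > 0) sqrt(s2 * diag(XtXinv)) else rep(NA_real_, ncol(X))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df_resid, lower.tail = FALSE)
  if (p_adjust == "holm") {
    keep <- names(beta) != "(Intercept)"
    pval[keep] <- stats::p.adjust(pval[keep], method = "holm")
  }
  ord <- attr(X, "order")
  tss <- sum((y - mean(y))^2)
  mss <- tss - rss
  p_model <- ncol(X) - 1L
  fstat <- if (df_resid > 0 && p_model > 0) (mss / p_model) / (rss / df_resid)
           else NA_real_
  p_of_f <- if (is.finite(fstat))
    stats::pf(fstat, p_model, df_resid, lower.tail = FALSE) else NA_real_
  estimates <- data.frame(
    term = names(beta), order = ord,
    coefficient = as.numeric(beta), std_error = as.numeric(se),
    t_value = as.numeric(tval), p_value = as.numeric(pval),
    cycle_energy = 2^ord * as.numeric(beta),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(estimates = estimates,
                 coefficients = beta,
                 r_squared = if (tss > 0) mss / tss else NA_real_,
                 f_statistic = fstat, p_of_f = p_of_f,
                 residual_df = df_resid,
                 residual_sd = if (df_resid > 0) sqrt(s2) else NA_real_,
                 se_available = df_resid > 0,
                 p_adjust = p_adjust,
                 design = design, X = X,
                 fitted.values = as.numeric(X %*% beta),
                 residuals = as.numeric(fit$residuals),
                 call = match.call()),
            class = "coupling_fit")
}

#' @export
print.coupling_fit <- function(x, digits = 3, ...) {
  cat("Energetic coupling regression (effect-coded OLS on dG, kcal/mol)\n")
  cat("  ", length(x$design$factor_names), " factor(s): ",
      paste(x$design$factor_names, collapse = ", "), "\n", sep = "")
  cat("  ", nrow(x$X), " observations, ", ncol(x$X), " terms, ",
      x$residual_df, " residual df\n", sep = "")
  if (!is.na(x$r_squared))
    cat(sprintf("  R^2 = %.*g", digits, x$r_squared),
        if (is.finite(x$f_statistic))
          sprintf(", F = %.*g, P(F) = %.2g", digits, x$f_statistic, x$p_of_f),
        "\n", sep = "")
  cat("Coefficients:\n")
  print(round(x$coefficients, digits), ...)
  if (!x$se_available)
    cat("(saturated fit with a single replicate per condition:\n",
        " standard errors unavailable)\n")
  invisible(x)
}

#' Per-term estimates of a coupling regression
#'
#' @param fit A [fit_coupling()] result.
#' @return Data frame: term, order, coefficient (kcal/mol), std_error,
#'   t_value, p_value, cycle_energy (= 2^order x coefficient, kcal/mol).
#' @export
coupling_terms <- function(fit) {
  stopifnot(inherits(fit, "coupling_fit"))
  fit$estimates
}

#' @export
coef.coupling_fit <- function(object, ...) object$coefficients

#' @export
fitted.coupling_fit <- function(object, ...) object$fitted.values

#' @export
residuals.coupling_fit <- function(object, ...) object$residuals

#' @export
#' @method summary coupling_fit
summary.coupling_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.coupling_fit")
}

#' @export
print.summary.coupling_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat("\nPer-term estimates",
      if (f$p_adjust == "holm") " (Holm-adjusted p)", ":\n", sep = "")
  est <- f$estimates
  est$stars <- significance_stars(est$p_value)
  print(format(est, digits = digits), row.names = FALSE)
  invisible(x)
}

significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", ifelse(p < 0.1, ".", "")))))
}

#' @export
predict.coupling_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  lv <- as.matrix(newdata)
  colnames(lv) <- colnames(object$design$levels)
  Xn <- build_design_matrix(lv, max_order = max(object$estimates$order))
  as.numeric(Xn[, colnames(object$X), drop = FALSE] %*% object$coefficients)
}

#' @export
vcov.coupling_fit <- function(object, ...) {
  if (!object$se_available)
    stop("covariance unavailable: saturated fit with zero residual df")
  object$residual_sd^2 * chol2inv(chol(crossprod(object$X)))
}

#' @export
confint.coupling_fit <- function(object, parm, level = 0.95, ...) {
  if (!object$se_available)
    stop("confidence intervals unavailable: zero residual df")
  est <- object$estimates
  tq <- stats::qt(1 - (1 - level) / 2, object$residual_df)
  ci <- cbind(lower = est$coefficient - tq * est$std_error,
              upper = est$coefficient + tq * est$std_error)
  rownames(ci) <- est$term
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Simulate response vectors from a fitted coupling model
#'
#' Draws Gaussian free-energy responses at the fit's design points using the
#' fitted coefficients and residual standard deviation.
#'
#' @param object A `coupling_fit` with positive residual df.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @export
simulate.coupling_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (!object$se_available)
    stop("cannot simulate: residual sd unavailable (zero residual df)")
  mu <- object$fitted.values
  out <- as.data.frame(replicate(
    nsim, mu + stats::rnorm(length(mu), 0, object$residual_sd)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Ranked histogram of energetic contributions
#'
#' Orders the fitted terms by absolute coefficient, annotates significance
#' stars, and marks which terms exceed a display threshold (the band the
#' regression reports as its practical significance level, 0.15 kcal/mol by
#' default).  The intercept is excluded.  `plot()` draws the histogram as a
#' horizontal barplot on either the coefficient or cycle-energy scale.
#'
#' @param fit A [fit_coupling()] result.
#' @param threshold Display threshold in kcal/mol; filters display only.
#' @return Data frame of class `term_histogram`.
#' @export
term_histogram <- function(fit, threshold = 0.15) {
  stopifnot(inherits(fit, "coupling_fit"))
  est <- fit$estimates[fit$estimates$term != "(Intercept)", , drop = FALSE]
  intercept <- fit$estimates[fit$estimates$term == "(Intercept)",
                             , drop = FALSE]
  est <- est[order(-abs(est$coefficient)), , drop = FALSE]
  est$stars <- significance_stars(est$p_value)
  est$above_threshold <- abs(est$coefficient) > threshold
  out <- rbind(est, transform(intercept, stars = significance_stars(p_value),
                              above_threshold = NA))
  rownames(out) <- NULL
  structure(out, threshold = threshold, class = c("term_histogram",
                                                  "data.frame"))
}

#' @export
print.term_histogram <- function(x, digits = 3, ...) {
  cat("Energetic contributions (kcal/mol), ranked by |coefficient|;\n",
      "display threshold ", attr(x, "threshold"), " kcal/mol\n", sep = "")
  df <- as.data.frame(x)
  df$coefficient <- round(df$coefficient, digits)
  df$cycle_energy <- round(df$cycle_energy, digits)
  print(df[, c("term", "order", "coefficient", "cycle_energy", "stars",
               "above_threshold")], row.names = FALSE)
  invisible(x)
}

#' @export
plot.coupling_fit <- function(x, scale = c("coefficient", "cycle_energy"),
                              threshold = 0.15, ...) {
  scale <- match.arg(scale)
  h <- term_histogram(x, threshold)
  h <- h[h$term != "(Intercept)", , drop = FALSE]
  vals <- h[[scale]]
  graphics::barplot(rev(vals), names.arg = rev(h$term), horiz = TRUE,
                    las = 1, xlab = paste(scale, "(kcal/mol)"),
                    col = ifelse(rev(vals) < 0, "steelblue", "salmon"), ...)
  graphics::abline(v = c(-threshold, threshold), lty = 3)
  invisible(h)
}

#' Specificity (substrate discrimination) free energy
#'
#' Converts the ratio of catalytic efficiencies for the target versus an
#' off-target substrate (e.g. tryptophan vs tyrosine) into a discrimination
#' free energy -RT log(ratio); more negative means stronger discrimination
#' in favor of the target.  Usable directly as the response of
#' [fit_coupling()].
#'
#' @param kcatKM_target,kcatKM_offtarget Catalytic efficiencies (kcat/KM),
#'   both strictly positive (units cancel).
#' @param rt Energy constant, kcal/mol.
#' @return Discrimination free energy, kcal/mol.
#' @export
#' @examples
#' specificity_response(2.54e4, 1)   # about -6 kcal/mol
specificity_response <- function(kcatKM_target, kcatKM_offtarget,
                                 rt = rt_constant()) {
  if (any(!is.finite(kcatKM_target) | kcatKM_target <= 0) ||
      any(!is.finite(kcatKM_offtarget) | kcatKM_offtarget <= 0))
    stop("catalytic efficiencies must be finite and > 0")
  -rt * log(kcatKM_target / kcatKM_offtarget)
}

#' Read a long-format factorial kinetics table from CSV
#'
#' Expects columns for each factor (-1/+1 levels), optionally `replicate`,
#' and one of: a precomputed `rate`, or `kcat` and `KM` columns from which
#' the requested response is formed.
#'
#' @param file CSV path.
#' @param factors Character vector of factor column names; defaults to all
#'   columns other than the kinetic/replicate columns.
#' @param response One of `"kcat"`, `"KM"`, `"kcat_over_KM"`, `"rate"`.
#' @param rt Energy constant.
#' @return A [factorial_design()].
#' @export
read_factorial_csv <- function(file, factors = NULL,
                               response = c("kcat", "KM", "kcat_over_KM",
                                            "rate"),
                               rt = rt_constant()) {
  response <- match.arg(response)
  df <- utils::read.csv(file, check.names = FALSE)
  known <- c("kcat", "KM", "rate", "replicate")
  if (is.null(factors)) factors <- setdiff(names(df), known)
  lv <- as.matrix(df[factors])
  val <- switch(response,
    rate = df$rate, kcat = df$kcat, KM = df$KM,
    kcat_over_KM = df$kcat / df$KM)
  if (is.null(val)) stop("required kinetic column(s) missing for response '",
                         response, "'")
  kind <- if (response == "kcat_over_KM") "kcat/KM"
          else if (response == "rate") "kcat" else response
  factorial_design(lv, rates = val, replicate = df$replicate,
                   response_kind = kind, rt = rt)
}
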