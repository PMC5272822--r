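# Independent oracles used across the suite.

# N-way non-additivity by direct substitution: alternating corner sum of
# -rt log(rate), sign from the parity of perturbed (-1) levels.
coupling_oracle <- function(levels, rates, rt = 0.592) {
  parity <- apply(levels, 1L, function(r) (-1)^sum(r == -1))
  sum(parity * (-rt * log(rates)))
}

# On a balanced full factorial, every OLS coefficient is the corner-parity
# average of the responses.
parity_average_oracle <- function(levels, y, term) {
  col <- if (length(term) == 0L) rep(1, nrow(levels))
         else apply(levels[, term, drop = FALSE], 1L, prod)
  mean(col * y)
}

# free-Mg speciation by nested grid refinement of the conservation
# residual on log10(m)
speciation_grid_oracle <- function(mg_total, totals, kds) {
  g <- function(m) m * (1 + sum(totals / (kds + m))) - mg_total
  lo <- log10(mg_total) - 40
  hi <- log10(mg_total)
  for (pass in 1:12) {
    grid <- seq(lo, hi, length.out = 200)
    val <- vapply(10^grid, g, numeric(1))
    i <- which(val >= 0)[1L]
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[i]
  }
  10^((lo + hi) / 2)
}

# simple right-handed rotation + translation for invariance checks
rigid_move <- function(ps, angle = 0.7, shift = c(5, -3, 2)) {
  r <- matrix(c(cos(angle), -sin(angle), 0,
                sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  residue_points(ps$ids, sweep(ps$coords %*% r, 2L, shift, `+`),
                 ps$conformation, ps$resid)
}
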