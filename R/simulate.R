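#' Generate a factorial free-energy/rate dataset from the coupling model
#'
#' Forward-simulates the effect-coded linear model: for each corner of the
#' full 2^N factorial and each replicate, dG = sum of term coefficients
#' times the corner's +1/-1 term columns, plus Gaussian noise of sd `sigma`
#' on the free-energy scale (equivalently, lognormal multiplicative noise
#' on rates, the error structure of replicate rate assays).  Rates are
#' exp(-dG/RT).
#'
#' Defaults emulate the combinatorial-mutagenesis study conditions:
#' three-fold replication and a replicate scatter of 0.3 kcal/mol.
#'
#' @param factor_names Character vector of N factor names.
#' @param coefficients Named numeric vector of true coefficients, kcal/mol.
#'   Use `"C"` (or `"(Intercept)"`) for the intercept and factor names
#'   joined by `:` for interactions (order-insensitive, e.g. `"I4:Metal"`).
#'   Unnamed terms are zero.
#' @param sigma Noise sd on the dG scale, kcal/mol (>= 0; default 0.3).
#' @param replicates Replicates per corner (default 3).
#' @param rt Energy constant.
#' @param seed Optional RNG seed; fixing it makes the dataset
#'   bit-reproducible.
#' @param response_kind Passed to [factorial_design()].
#' @return A [factorial_design()] whose `rates` element holds the
#'   generated rates and whose `"truth"` attribute records the full
#'   generating coefficient vector and settings.
#' @export
#' @examples
#' sim <- gen_factorial_dataset(c("I4", "F26", "Y33", "F37", "Metal"),
#'                              c("I4:F26:Y33:F37:Metal" = -5 / 32),
#'                              sigma = 0, replicates = 1)
#' coef(fit_coupling(sim))[["I4:F26:Y33:F37:Metal"]]
gen_factorial_dataset <- function(factor_names, coefficients = numeric(),
                                  sigma = 0.3, replicates = 3,
                                  rt = rt_constant(), seed = NULL,
                                  response_kind = "kcat") {
  stopifnot(is.character(factor_names), length(factor_names) >= 1L,
            !anyDuplicated(factor_names), sigma >= 0, replicates >= 1L)
  if (!is.null(seed)) set.seed(seed)
  n <- length(factor_names)
  grid <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  colnames(grid) <- factor_names
  X <- build_design_matrix(grid, "saturated")
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  canon <- lapply(strsplit(setdiff(colnames(X), "(Intercept)"), ":"), sort)
  for (nm in names(coefficients)) {
    if (nm %in% c("C", "(Intercept)")) {
      beta[["(Intercept)"]] <- coefficients[[nm]]
      next
    }
    parts <- sort(strsplit(nm, ":")[[1L]])
    bad <- setdiff(parts, factor_names)
    if (length(bad))
      stop("coefficient '", nm, "' references undeclared factor(s): ",
           paste(bad, collapse = ", "))
    hit <- which(vapply(canon, identical, logical(1), parts))
    beta[[hit + 1L]] <- coefficients[[nm]]
  }
  lv <- grid[rep(seq_len(nrow(grid)), each = replicates), , drop = FALSE]
  rep_id <- rep(seq_len(replicates), times = nrow(grid))
  mu <- as.numeric(X %*% beta)[rep(seq_len(nrow(grid)),
                                   each = replicates)]
  dg <- mu + stats::rnorm(length(mu), 0, sigma)
  design <- factorial_design(lv, rates = free_energy_to_rate(dg, rt),
                             replicate = rep_id,
                             response_kind = response_kind, rt = rt)
  design$rates <- free_energy_to_rate(dg, rt)
  attr(design, "truth") <- list(coefficients = beta, sigma = sigma,
                                replicates = replicates, rt = rt,
                                seed = seed)
  design
}

#' Generate a synthetic EDTA titration of enzymatic activity
#'
#' Forward model of the metal-depletion assay: at each EDTA total the free
#' Mg2+ is obtained from the coupled Mg.ATP / Mg.EDTA equilibria
#' ([solve_speciation()]) and activity follows the two-parameter depletion
#' model ([predicted_activity()]) scaled by enzyme concentration, with
#' multiplicative lognormal noise.  The default grid extends well past the
#' Mg-depletion point so the metal-free plateau is present.
#'
#' Default truth uses the depletion parameters of the TrpRS/Mg2+ cycle:
#' metal-free rate fraction 1.1e-5 and transition-state Kd 120 nM.
#'
#' @param edta_grid EDTA totals, M.  The default 12-point grid (0 to 10
#'   mM) samples densely around the Mg-depletion knee near `mg_total`,
#'   where free Mg2+ sweeps through the transition-state Kd, and extends
#'   deep enough past it that the 1e-5-scale metal-free floor is visible.
#' @param enzyme_conc Enzyme concentrations, M; every concentration gets
#'   the full grid (default two series).
#' @param f,kd_ts True depletion parameters (dimensionless; M).
#' @param k_act Activity per M enzyme at saturating Mg2+.
#' @param mg_total,atp_total Residual metal and ATP totals, M.
#' @param kd_atp,kd_edta Chelation constants, M.
#' @param sigma Lognormal noise sd on log-activity (default 0.05).
#' @param seed Optional RNG seed.
#' @return Data frame (`edta_total`, `enzyme_conc`, `mg_free`, `activity`)
#'   with a `"truth"` attribute.
#' @export
gen_edta_titration <- function(edta_grid = c(0, 1e-6, 3e-6, 6e-6, 8e-6,
                                             9e-6, 9.5e-6, 1.0e-5,
                                             1.05e-5, 1.2e-5, 1e-4, 1e-2),
                               enzyme_conc = c(5e-9, 2.5e-8),
                               f = 1.1e-5, kd_ts = 120e-9, k_act = 1e9,
                               mg_total = 1e-5, atp_total = 1e-4,
                               kd_atp = default_kd()[["ATP"]],
                               kd_edta = default_kd()[["EDTA"]],
                               sigma = 0.05, seed = NULL) {
  stopifnot(sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  df <- expand.grid(edta_total = edta_grid, enzyme_conc = enzyme_conc)
  df$mg_free <- mg_free_on_grid(df$edta_total, mg_total, atp_total,
                                kd_atp, kd_edta)
  mu <- predicted_activity(df$mg_free, f, kd_ts,
                           v_max = k_act * df$enzyme_conc)
  df$activity <- mu * exp(stats::rnorm(nrow(df), 0, sigma))
  attr(df, "truth") <- list(f = f, kd_ts = kd_ts, k_act = k_act,
                            mg_total = mg_total, atp_total = atp_total,
                            kd_atp = kd_atp, kd_edta = kd_edta,
                            sigma = sigma, seed = seed)
  df
}

#' Generate a burst (active-site titration) product time course
#'
#' Forward model P(t) = A (1 - exp(-k_chem t)) + v_ss t + C plus Gaussian
#' noise.  Defaults reproduce the reference active-site-titration
#' experiment: burst amplitude equal to the active enzyme, chemical step
#' 625-fold faster than a 5/s turnover (k_chem = 3125/s), sampled through
#' both the millisecond burst and the linear steady state.
#'
#' @param times Sampling times, s, strictly increasing.
#' @param enzyme_total,active_fraction Enzyme (product units) and its
#'   active fraction; the burst amplitude is their product.
#' @param k_chem First-order chemical rate, 1/s.
#' @param kcat Steady-state turnover, 1/s (v_ss = kcat x active enzyme).
#' @param C Baseline offset, product units.
#' @param sigma Gaussian noise sd, product units (default 0.01).
#' @param seed Optional RNG seed.
#' @return A [time_course()] with a `"truth"` attribute.
#' @export
gen_burst_course <- function(times = c(seq(5e-5, 2.5e-3,
                                           length.out = 15),
                                       seq(0.02, 1, length.out = 15)),
                             enzyme_total = 1, active_fraction = 1,
                             k_chem = 3125, kcat = 5, C = 0,
                             sigma = 0.01, seed = NULL) {
  stopifnot(k_chem > 0, kcat >= 0, sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  active <- enzyme_total * active_fraction
  v_ss <- kcat * active
  mu <- active * (1 - exp(-k_chem * times)) + v_ss * times + C
  p <- mu + stats::rnorm(length(times), 0, sigma)
  tc <- time_course(times, p, enzyme_total, active_fraction)
  attr(tc, "truth") <- list(A = active, k_chem = k_chem, v_ss = v_ss,
                            C = C, kcat = kcat, ratio = k_chem / kcat,
                            sigma = sigma, seed = seed)
  tc
}

# self-avoiding pseudo-chain: fixed-length steps, minimum separation
random_chain <- function(n, step = 3.8, min_sep = 4, max_try = 200) {
  pts <- matrix(0, n, 3L)
  for (i in 2:n) {
    for (k in seq_len(max_try)) {
      u <- stats::rnorm(3)
      cand <- pts[i - 1L, ] + step * u / sqrt(sum(u^2))
      d <- sqrt(rowSums(sweep(pts[seq_len(i - 2L), , drop = FALSE], 2L,
                              cand)^2))
      if (i == 2L || all(d >= min_sep)) break
      if (k == max_try) cand <- pts[i - 1L, ] + step * c(1, 0, 0)
    }
    pts[i, ] <- cand
  }
  pts
}

#' Generate toy multi-conformation structures with known rearrangements
#'
#' Builds a self-avoiding pseudo-protein chain (one point per residue) and
#' a second conformation in which a chosen set of residues is displaced by
#' a stated distance -- so the dynamic residues are known by construction.
#' Optionally writes the two conformations as PDB files (single C-alpha
#' per residue) plus a JSON truth sidecar naming the displaced residues.
#' These are synthetic structures for testing the tessellation filter, not
#' models of any real protein.
#'
#' @param n_residues Chain length (>= 5).
#' @param displace Integer residue numbers to move in the second
#'   conformation (default: three central residues).
#' @param displacement Displacement magnitude in Angstroms (default 3).
#' @param chain Chain identifier used in ids and PDB output.
#' @param seed Optional RNG seed (chain geometry and displacement
#'   directions).
#' @param dir If non-`NULL`, directory where `conf_open.pdb`,
#'   `conf_moved.pdb` and `truth_synthetic.json` are written.
#' @return List: `open` and `moved` ([residue_points()]),
#'   `displaced_ids`, `displacement`, and `files` (paths, when written).
#' @export
gen_toy_structures <- function(n_residues = 30, displace = NULL,
                               displacement = 3, chain = "A",
                               seed = NULL, dir = NULL) {
  stopifnot(n_residues >= 5L, displacement >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(displace))
    displace <- floor(n_residues / 2) + (-1:1)
  stopifnot(all(displace >= 1), all(displace <= n_residues))
  pts <- random_chain(n_residues)
  aa <- c("ALA", "VAL", "LEU", "ILE", "PHE", "TYR", "TRP", "GLY", "SER",
          "THR")
  resid <- sample(aa, n_residues, replace = TRUE)
  ids <- paste(chain, seq_len(n_residues), sep = ":")
  moved <- pts
  for (r in displace) {
    u <- stats::rnorm(3)
    moved[r, ] <- moved[r, ] + displacement * u / sqrt(sum(u^2))
  }
  open_ps <- residue_points(ids, pts, "open", resid)
  moved_ps <- residue_points(ids, moved, "moved", resid)
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    f1 <- file.path(dir, "conf_open.pdb")
    f2 <- file.path(dir, "conf_moved.pdb")
    ft <- file.path(dir, "truth_synthetic.json")
    write_points_pdb(open_ps, f1)
    write_points_pdb(moved_ps, f2)
    jsonlite::write_json(list(displaced_residues = ids[displace],
                              displacement_angstrom = displacement,
                              n_residues = n_residues),
                         ft, auto_unbox = TRUE, digits = NA)
    files <- c(open = f1, moved = f2, truth = ft)
  }
  list(open = open_ps, moved = moved_ps,
       displaced_ids = ids[sort(unique(displace))],
       displacement = displacement, files = files)
}

#' Write a residue point set as a one-atom-per-residue PDB file
#'
#' Each residue becomes a single C-alpha record at its representative
#' point, preserving chain and residue numbering, so the file round-trips
#' through [residue_centroids()].
#'
#' @param points A [residue_points()] set.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_points_pdb <- function(points, file) {
  stopifnot(inherits(points, "residue_points"))
  parts <- strsplit(points$ids, ":", fixed = TRUE)
  ch <- vapply(parts, `[[`, character(1), 1L)
  resno <- as.integer(vapply(parts, `[[`, character(1), 2L))
  resid <- if (is.null(points$resid)) rep("GLY", length(ch)) else
    points$resid
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(points$coords)),
                   type = rep("ATOM", length(ch)),
                   resno = resno, resid = resid, chain = ch,
                   elety = rep("CA", length(ch)),
                   o = rep(1, length(ch)), b = rep(0, length(ch)))
  invisible(file)
}
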