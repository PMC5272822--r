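#' Construct a residue point set
#'
#' One representative 3-D point per residue of one conformation, the input
#' representation for packing tessellation.  Residue ids are
#' `"chain:resno"` strings preserving the 1-based PDB numbering.
#'
#' @param ids Character vector of unique residue ids (`"A:12"`).
#' @param coords Numeric matrix (n x 3), Angstroms.
#' @param conformation Label for this conformation.
#' @param resid Optional 3-letter residue type codes (needed for
#'   [score_simplices()]).
#' @return Object of class `residue_points`.
#' @export
residue_points <- function(ids, coords, conformation = "conf",
                           resid = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  stopifnot(ncol(coords) == 3L, length(ids) == nrow(coords),
            all(is.finite(coords)))
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate residue ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(resid)) stopifnot(length(resid) == length(ids))
  rownames(coords) <- ids
  structure(list(ids = ids, coords = coords,
                 conformation = conformation, resid = resid),
            class = "residue_points")
}

#' @export
print.residue_points <- function(x, ...) {
  cat("Residue point set '", x$conformation, "': ", length(x$ids),
      " residues (", x$ids[1L], " ... ", x$ids[length(x$ids)], ")\n",
      sep = "")
  invisible(x)
}

backbone_atoms <- c("N", "CA", "C", "O", "OXT")
water_resids <- c("HOH", "WAT", "DOD", "H2O")

#' Reduce a PDB structure to one point per residue
#'
#' Each residue is represented by its side-chain heavy-atom centroid, or
#' its C-alpha when it has no side-chain heavy atoms (glycine) or when
#' `point = "ca"`.  Waters and hetero groups are excluded; alternate
#' locations are resolved to the highest occupancy; residues with neither
#' side-chain atoms nor a C-alpha are skipped with a warning.
#'
#' @param pdb Path to a PDB file, or a `bio3d` `pdb` object.
#' @param chain Chain identifier(s) to keep; `NULL` keeps all chains.
#' @param point `"centroid"` (default) or `"ca"`.
#' @param conformation Label; defaults to the file name.
#' @return A [residue_points()] set.
#' @export
residue_centroids <- function(pdb, chain = NULL,
                              point = c("centroid", "ca"),
                              conformation = NULL) {
  point <- match.arg(point)
  if (is.character(pdb)) {
    if (is.null(conformation))
      conformation <- sub("\\.pdb$", "", basename(pdb))
    pdb <- bio3d::read.pdb(pdb)
  }
  if (is.null(conformation)) conformation <- "conf"
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% water_resids), ,
           drop = FALSE]
  if (!is.null(chain)) {
    if (!any(at$chain %in% chain))
      stop("selected chain(s) ", paste(chain, collapse = ","),
           " not present in structure")
    at <- at[at$chain %in% chain, , drop = FALSE]
  }
  # drop hydrogens (element symbol if present, name heuristic otherwise)
  if (!is.null(at$elesy) && any(nzchar(at$elesy)))
    at <- at[!(at$elesy %in% c("H", "D")), , drop = FALSE]
  else
    at <- at[!grepl("^[0-9]*[HD]", at$elety), , drop = FALSE]
  # alternate locations: highest occupancy per (chain, resno, atom name);
  # file order of residues is preserved
  occ <- if (is.null(at$o)) rep(1, nrow(at)) else ifelse(is.na(at$o), 1,
                                                         at$o)
  akey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  pick <- order(akey, -occ)
  pick <- pick[!duplicated(akey[pick])]
  at <- at[sort(pick), , drop = FALSE]
  rkey <- paste(at$chain, at$resno, sep = ":")
  ids <- unique(rkey)
  out <- lapply(ids, function(id) {
    sub <- at[rkey == id, , drop = FALSE]
    xyz <- as.matrix(sub[, c("x", "y", "z")])
    ca <- xyz[sub$elety == "CA", , drop = FALSE]
    sc <- xyz[!(sub$elety %in% backbone_atoms), , drop = FALSE]
    p <- if (point == "ca") {
      if (nrow(ca)) ca[1L, ] else NULL
    } else if (nrow(sc)) colMeans(sc)
    else if (nrow(ca)) ca[1L, ]
    else NULL
    list(p = p, resid = sub$resid[1L])
  })
  keep <- !vapply(out, function(o) is.null(o$p), logical(1))
  if (any(!keep))
    warning("skipping residue(s) with no usable atoms: ",
            paste(ids[!keep], collapse = ", "))
  residue_points(ids[keep],
                 do.call(rbind, lapply(out[keep], `[[`, "p")),
                 conformation = conformation,
                 resid = vapply(out[keep], `[[`, character(1), "resid"))
}

#' Restrict several conformations to their shared residues
#'
#' Residues missing from any conformation (disordered loops, skipped
#' residues) are removed from all, with a warning naming them, so the
#' tessellations become comparable.
#'
#' @param point_sets List of [residue_points()].
#' @return List of `residue_points` over the common id set.
#' @export
align_universes <- function(point_sets) {
  ids <- Reduce(intersect, lapply(point_sets, `[[`, "ids"))
  dropped <- setdiff(unique(unlist(lapply(point_sets, `[[`, "ids"))), ids)
  if (length(dropped))
    warning("removing residue(s) absent from some conformation(s): ",
            paste(dropped, collapse = ", "))
  lapply(point_sets, function(ps) {
    i <- match(ids, ps$ids)
    residue_points(ids, ps$coords[i, , drop = FALSE], ps$conformation,
                   if (!is.null(ps$resid)) ps$resid[i])
  })
}

# deterministic symbolic-scale jitter keyed to the residue id string, so
# cospherical degeneracies break identically in every run and conformation
id_jitter <- function(ids, scale = 1e-6) {
  h <- vapply(ids, function(s)
    sum(utf8ToInt(s) * seq_along(utf8ToInt(s))), numeric(1))
  t(vapply(h, function(hi) {
    u <- sin(hi * c(12.9898, 78.233, 37.719)) * 43758.5453
    scale * (2 * (u - floor(u)) - 1)
  }, numeric(3)))
}

#' Tessellate a residue point set into packing simplices
#'
#' Delaunay tessellation of the residue points, keeping only simplices
#' whose longest edge does not exceed `max_edge` (suppressing spurious
#' surface tetrahedra).  Cospherical degeneracies are broken by a
#' deterministic jitter keyed to residue ids; edge lengths are measured on
#' the unjittered coordinates.  Every retained simplex is validated post
#' hoc against the empty-circumsphere property.
#'
#' @param points A [residue_points()] set with >= 4 residues.
#' @param max_edge Edge-length cutoff in Angstroms (default 8).
#' @param jitter_scale Degeneracy-breaking jitter amplitude, Angstroms.
#' @return Object of class `simplex_set`: residue-id quadruples (`ids`,
#'   character matrix, rows sorted), index matrix, per-simplex longest
#'   edge, and the originating point set.
#' @export
tessellate <- function(points, max_edge = 8, jitter_scale = 1e-6) {
  stopifnot(inherits(points, "residue_points"), max_edge > 0)
  n <- length(points$ids)
  if (n < 4L)
    stop("tessellation needs >= 4 residues, got ", n)
  jit <- points$coords + id_jitter(points$ids, jitter_scale)
  simp <- delaunay3d(jit)
  if (nrow(simp)) {
    viol <- circumsphere_violations(jit, simp)
    if (any(viol > 1e-9))
      warning("empty-circumsphere violation up to ",
              signif(max(viol), 3), " A after jitter")
    longest <- apply(simp, 1L, function(q) {
      max(stats::dist(points$coords[q, , drop = FALSE]))
    })
    keep <- longest <= max_edge
    simp <- simp[keep, , drop = FALSE]
    longest <- longest[keep]
  } else longest <- numeric(0)
  ids <- matrix(points$ids[simp], ncol = 4L)
  structure(list(ids = ids, indices = simp, max_edge_length = longest,
                 edge_cutoff = max_edge, points = points,
                 lambda = NULL, band = NULL),
            class = "simplex_set")
}

#' @export
print.simplex_set <- function(x, ...) {
  cat("Simplex set ('", x$points$conformation, "'): ", nrow(x$ids),
      " simplices over ", length(x$points$ids),
      " residues (edge cutoff ", x$edge_cutoff, " A)\n", sep = "")
  if (!is.null(x$lambda))
    cat("  SNAPP scores attached: ",
        sum(x$band == "high"), " high (L > 0.6), ",
        sum(x$band == "negative"), " negative (L < 0)\n", sep = "")
  invisible(x)
}

simplex_keys <- function(ss)
  apply(ss$ids, 1L, function(r) paste(sort(r), collapse = "|"))

#' Classify packing simplices as invariant or dynamic across conformations
#'
#' Simplices (residue quadruples) present in every conformation's
#' tessellation lie within rigid bodies and are invariant; those present in
#' some but not all conformations rearrange their packing partners during
#' the conformational cycle and are dynamic.  The dynamic residue set is
#' the union of residues appearing in any dynamic simplex -- the geometric
#' stage of the two-stage dynamic-contact filter.
#'
#' @param tessellations List of >= 2 [tessellate()] results over an
#'   identical residue universe.
#' @return Object of class `dynamic_report`: `invariant` (keys),
#'   `dynamic` (keys), `membership` (logical matrix: dynamic simplex x
#'   conformation), `dynamic_residues`, `universe`.
#' @export
dynamic_simplices <- function(tessellations) {
  stopifnot(is.list(tessellations), length(tessellations) >= 2L)
  stopifnot(all(vapply(tessellations, inherits, logical(1), "simplex_set")))
  universes <- lapply(tessellations, function(s) sort(s$points$ids))
  for (i in seq_along(universes)[-1L]) {
    if (!identical(universes[[1L]], universes[[i]])) {
      sd <- union(setdiff(universes[[1L]], universes[[i]]),
                  setdiff(universes[[i]], universes[[1L]]))
      stop("conformations have mismatched residue universes; ",
           "symmetric difference: ", paste(sd, collapse = ", "),
           " (use align_universes())")
    }
  }
  keysets <- lapply(tessellations, simplex_keys)
  names(keysets) <- vapply(tessellations,
                           function(s) s$points$conformation, character(1))
  all_keys <- sort(unique(unlist(keysets)))
  invariant <- sort(Reduce(intersect, keysets))
  dynamic <- setdiff(all_keys, invariant)
  membership <- vapply(keysets, function(k) dynamic %in% k,
                       logical(length(dynamic)))
  membership <- matrix(membership, nrow = length(dynamic),
                       ncol = length(keysets),
                       dimnames = list(dynamic, names(keysets)))
  dyn_res <- sort(unique(unlist(strsplit(dynamic, "|", fixed = TRUE))))
  structure(list(invariant = invariant, dynamic = dynamic,
                 membership = membership, dynamic_residues = dyn_res,
                 universe = universes[[1L]],
                 conformations = names(keysets)),
            class = "dynamic_report")
}

#' @export
print.dynamic_report <- function(x, ...) {
  cat("Dynamic-contact report over ", length(x$conformations),
      " conformations (", paste(x$conformations, collapse = ", "), ")\n",
      "  invariant simplices: ", length(x$invariant), "\n",
      "  dynamic simplices:   ", length(x$dynamic), "\n",
      "  dynamic residues:    ", length(x$dynamic_residues),
      if (length(x$dynamic_residues))
        paste0(" (", paste(x$dynamic_residues, collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

composition_key <- function(resid4) paste(sort(resid4), collapse = "-")

#' Score simplices with a residue-composition log-likelihood potential
#'
#' Attaches a packing log-likelihood score Lambda to every simplex from a
#' pluggable lookup table keyed by the sorted 4-residue-type composition
#' (e.g. `"ALA-GLY-LEU-VAL"`).  Simplices are banded as `"high"` (Lambda >
#' 0.6, well-packed core compositions), `"negative"` (Lambda < 0, typically
#' surface), or `"mid"`.  A uniform (all-zero) table scores everything 0.
#'
#' @param simplices A [tessellate()] result whose point set carries residue
#'   types.
#' @param potential Named numeric vector: composition key -> log
#'   likelihood.  Every composition present must have an entry.
#' @return The simplex set with `lambda` and `band` filled in.
#' @export
score_simplices <- function(simplices, potential) {
  stopifnot(inherits(simplices, "simplex_set"), is.numeric(potential))
  ps <- simplices$points
  if (is.null(ps$resid))
    stop("point set carries no residue types; rebuild with resid codes")
  types <- ps$resid[match(simplices$ids, ps$ids)]
  types <- matrix(types, ncol = 4L)
  comps <- apply(types, 1L, composition_key)
  miss <- setdiff(unique(comps), names(potential))
  if (length(miss))
    stop("potential table lacks composition(s): ",
         paste(miss, collapse = ", "))
  lam <- unname(potential[comps])
  simplices$lambda <- lam
  simplices$band <- ifelse(lam > 0.6, "high",
                           ifelse(lam < 0, "negative", "mid"))
  simplices
}

#' Intersect dynamic residues with an external candidate list
#'
#' The second stage of the dynamic-contact filter: keep only externally
#' proposed substitutions (e.g. a multi-state design output such as I4V,
#' F26L, Y33F, F37I) whose residue is in the dynamic residue set.
#' Suggestions at residues outside the shared universe are dropped with a
#' warning.
#'
#' @param report A [dynamic_simplices()] report.
#' @param suggestions Data frame with columns `residue` (ids matching the
#'   universe) and `substitution`.
#' @return The filtered suggestion data frame.
#' @export
candidate_intersection <- function(report, suggestions) {
  stopifnot(inherits(report, "dynamic_report"))
  suggestions <- as.data.frame(suggestions)
  if (!nrow(suggestions))
    return(suggestions[, c("residue", "substitution"), drop = FALSE])
  stopifnot(all(c("residue", "substitution") %in% names(suggestions)))
  known <- suggestions$residue %in% report$universe
  if (any(!known))
    warning("dropping suggestion(s) at unknown residue(s): ",
            paste(suggestions$residue[!known], collapse = ", "))
  out <- suggestions[known & suggestions$residue %in%
                       report$dynamic_residues, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a two-column suggestion list (residue id, substitution)
#'
#' @param file TSV path, optionally with a header line.
#' @return Data frame with columns `residue`, `substitution`.
#' @export
read_suggestions_tsv <- function(file) {
  df <- utils::read.delim(file, header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("residue", "substitution"))
  if (identical(tolower(df$residue[1L]), "residue"))
    df <- df[-1L, , drop = FALSE]
  rownames(df) <- NULL
  df
}
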