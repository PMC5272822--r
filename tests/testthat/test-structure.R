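# hand-written three-residue PDB: LEU (4 side-chain atoms), GLY (CA only),
# ALA (single CB side-chain atom)
write_mini_pdb <- function(file) {
  fmt <- function(i, name, res, resno, x, y, z)
    sprintf("ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            i, name, res, resno, x, y, z)
  writeLines(c(
    fmt(1, "N",   "LEU", 1, 0, 0, 0),
    fmt(2, "CA",  "LEU", 1, 1, 0, 0),
    fmt(3, "C",   "LEU", 1, 2, 0, 0),
    fmt(4, "O",   "LEU", 1, 3, 0, 0),
    fmt(5, "CB",  "LEU", 1, 1, 1, 0),
    fmt(6, "CG",  "LEU", 1, 1, 2, 0),
    fmt(7, "CD1", "LEU", 1, 0, 3, 1),
    fmt(8, "CD2", "LEU", 1, 2, 3, 1),
    fmt(9, "N",   "GLY", 2, 4, 0, 0),
    fmt(10, "CA", "GLY", 2, 5, 0, 0),
    fmt(11, "C",  "GLY", 2, 6, 0, 0),
    fmt(12, "N",  "ALA", 3, 7, 0, 0),
    fmt(13, "CA", "ALA", 3, 8, 0, 0),
    fmt(14, "CB", "ALA", 3, 8, 1, 1),
    "END"), file)
  file
}

test_that("residue centroids follow the side-chain/CA rules", {
  f <- write_mini_pdb(tempfile(fileext = ".pdb"))
  ps <- residue_centroids(f)
  expect_identical(ps$ids, c("A:1", "A:2", "A:3"))
  # LEU: mean of CB, CG, CD1, CD2
  expect_equal(unname(ps$coords["A:1", ]),
               colMeans(rbind(c(1, 1, 0), c(1, 2, 0), c(0, 3, 1),
                              c(2, 3, 1))), tolerance = 1e-6)
  # GLY: CA; ALA: its lone CB
  expect_equal(unname(ps$coords["A:2", ]), c(5, 0, 0), tolerance = 1e-6)
  expect_equal(unname(ps$coords["A:3", ]), c(8, 1, 1), tolerance = 1e-6)
  # CA representation on request
  ca <- residue_centroids(f, point = "ca")
  expect_equal(unname(ca$coords["A:1", ]), c(1, 0, 0), tolerance = 1e-6)
  expect_identical(ps$resid, c("LEU", "GLY", "ALA"))
  unlink(f)
})

test_that("incremental tessellation agrees with the brute-force oracle", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(6:12, 1)
    p <- matrix(runif(3 * n) * 10, n, 3)
    expect_identical(delaunay3d(p), delaunay3d_bruteforce(p))
  }
})

test_that("tessellation handles the canonical small configurations", {
  # 4 non-coplanar points: the single tetrahedron
  expect_equal(nrow(delaunay3d(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                     c(0, 0, 1)))), 1L)
  # triangular bipyramid: two tetrahedra sharing the equatorial face
  bp <- rbind(c(0, 0, 1), c(0, 0, -1), c(1, 0, 0),
              c(-0.5, 0.866, 0), c(-0.5, -0.866, 0))
  ids <- paste0("A:", 1:5)
  ss <- tessellate(residue_points(ids, bp * 3), max_edge = 100)
  expect_equal(nrow(ss$ids), 2L)
  jit <- bp * 3 + cyclenet:::id_jitter(ids)
  expect_identical(ss$indices, delaunay3d_bruteforce(jit))
  # degenerate cube + center resolved by deterministic jitter
  cube <- rbind(as.matrix(expand.grid(0:1, 0:1, 0:1)) * 4, c(2, 2, 2))
  ids9 <- paste0("A:", 1:9)
  sc <- tessellate(residue_points(ids9, cube), max_edge = 100)
  jit9 <- cube + cyclenet:::id_jitter(ids9)
  expect_identical(sc$indices, delaunay3d_bruteforce(jit9))
  expect_error(tessellate(residue_points("A:1", matrix(0, 1, 3))),
               ">= 4")
})

test_that("every retained simplex satisfies the empty-circumsphere property", {
  ts <- gen_toy_structures(n_residues = 25, seed = 21)
  ss <- tessellate(ts$open)
  jit <- ts$open$coords + cyclenet:::id_jitter(ts$open$ids)
  expect_lt(max(circumsphere_violations(jit, ss$indices)), 1e-9)
  # edge filter: all retained edges within the cutoff, some were removed
  expect_true(all(ss$max_edge_length <= ss$edge_cutoff))
  unfiltered <- tessellate(ts$open, max_edge = 1e6)
  expect_gt(nrow(unfiltered$ids), nrow(ss$ids))
})

test_that("identical conformations yield no dynamic simplices", {
  ts <- gen_toy_structures(n_residues = 20, seed = 5)
  rep0 <- dynamic_simplices(list(tessellate(ts$open), tessellate(ts$open)))
  expect_length(rep0$dynamic, 0L)
  expect_length(rep0$dynamic_residues, 0L)
  expect_gt(length(rep0$invariant), 0L)
})

test_that("dynamic classification matches brute-force set algebra on small sets", {
  set.seed(77)
  n <- 10
  p1 <- matrix(runif(3 * n) * 12, n, 3)
  p2 <- p1
  p2[4, ] <- p2[4, ] + c(5, 2, -3)   # one point displaced
  ids <- paste0("A:", 1:n)
  s1 <- tessellate(residue_points(ids, p1, "a"), max_edge = 1e6)
  s2 <- tessellate(residue_points(ids, p2, "b"), max_edge = 1e6)
  rep <- dynamic_simplices(list(s1, s2))
  # oracle: brute-force tessellations of the jittered coordinates
  key <- function(m) apply(matrix(ids[m], ncol = 4), 1,
                           function(r) paste(sort(r), collapse = "|"))
  k1 <- key(delaunay3d_bruteforce(p1 + cyclenet:::id_jitter(ids)))
  k2 <- key(delaunay3d_bruteforce(p2 + cyclenet:::id_jitter(ids)))
  expect_setequal(rep$invariant, intersect(k1, k2))
  expect_setequal(rep$dynamic, setdiff(union(k1, k2), intersect(k1, k2)))
  expect_setequal(rep$dynamic_residues,
                  unique(unlist(strsplit(rep$dynamic, "|", fixed = TRUE))))
})

test_that("three-conformation invariant set is the triple intersection", {
  set.seed(33)
  n <- 12
  p <- matrix(runif(3 * n) * 10, n, 3)
  ids <- paste0("A:", 1:n)
  mv <- function(p, i, d) { p[i, ] <- p[i, ] + d; p }
  confs <- list(p, mv(p, 3, c(4, 0, 0)), mv(p, 9, c(0, -4, 2)))
  tess <- lapply(seq_along(confs), function(i)
    tessellate(residue_points(ids, confs[[i]], paste0("c", i)),
               max_edge = 1e6))
  rep3 <- dynamic_simplices(tess)
  keys <- lapply(tess, cyclenet:::simplex_keys)
  expect_setequal(rep3$invariant, Reduce(intersect, keys))
  # symmetric in conformation order
  repr <- dynamic_simplices(rev(tess))
  expect_setequal(repr$invariant, rep3$invariant)
  expect_setequal(repr$dynamic, rep3$dynamic)
})

test_that("mismatched residue universes are rejected with the difference", {
  ts <- gen_toy_structures(n_residues = 12, seed = 2)
  sub <- residue_points(ts$open$ids[-3], ts$open$coords[-3, ],
                        "partial", ts$open$resid[-3])
  expect_error(dynamic_simplices(list(tessellate(ts$open),
                                      tessellate(sub))),
               "A:3")
  expect_warning(aligned <- align_universes(list(ts$open, sub)), "A:3")
  expect_identical(aligned[[1]]$ids, aligned[[2]]$ids)
})

test_that("rigid motion of all conformations leaves the report unchanged", {
  ts <- gen_toy_structures(n_residues = 24, seed = 11)
  rep1 <- dynamic_simplices(list(tessellate(ts$open),
                                 tessellate(ts$moved)))
  rep2 <- dynamic_simplices(list(tessellate(rigid_move(ts$open)),
                                 tessellate(rigid_move(ts$moved))))
  expect_identical(rep1$invariant, rep2$invariant)
  expect_identical(rep1$dynamic, rep2$dynamic)
  expect_identical(rep1$dynamic_residues, rep2$dynamic_residues)
})

test_that("simplex scoring looks up compositions and bands correctly", {
  ts <- gen_toy_structures(n_residues = 18, seed = 6)
  ss <- tessellate(ts$open)
  types <- matrix(ts$open$resid[match(ss$ids, ts$open$ids)], ncol = 4)
  comps <- apply(types, 1, function(r) paste(sort(r), collapse = "-"))
  # uniform table: all lambda zero, no band hits
  uni <- setNames(rep(0, length(unique(comps))), unique(comps))
  s0 <- score_simplices(ss, uni)
  expect_true(all(s0$lambda == 0))
  expect_true(all(s0$band == "mid"))
  # single high-likelihood composition
  one <- uni; one[comps[1]] <- 1.0
  s1 <- score_simplices(ss, one)
  expect_equal(s1$lambda[1], 1.0)
  expect_identical(s1$band[1], "high")
  # random table: band counts equal an independent recount
  set.seed(1)
  rnd <- setNames(runif(length(uni), -1, 1), names(uni))
  sr <- score_simplices(ss, rnd)
  expect_identical(sum(sr$band == "high"), sum(rnd[comps] > 0.6))
  expect_identical(sum(sr$band == "negative"), sum(rnd[comps] < 0))
  # missing composition is named in the error
  expect_error(score_simplices(ss, rnd[-1]), names(rnd)[1], fixed = TRUE)
})

test_that("candidate intersection filters on the dynamic residue set", {
  set.seed(55)
  n <- 10
  p1 <- matrix(runif(3 * n) * 12, n, 3)
  p2 <- p1
  p2[c(3, 7), ] <- p2[c(3, 7), ] + 6
  ids <- paste0("A:", 1:n)
  rep <- dynamic_simplices(list(
    tessellate(residue_points(ids, p1, "a"), max_edge = 1e6),
    tessellate(residue_points(ids, p2, "b"), max_edge = 1e6)))
  expect_true(all(c("A:3", "A:7") %in% rep$dynamic_residues))
  sug <- data.frame(residue = c("A:3", "A:7", "A:99"),
                    substitution = c("I4V", "F26L", "Y33F"))
  expect_warning(out <- candidate_intersection(rep, sug), "A:99")
  expect_setequal(out$residue, c("A:3", "A:7"))
  expect_identical(out$substitution[out$residue == "A:3"], "I4V")
  # empty suggestion list and invariant-only suggestions give empty output
  empty <- candidate_intersection(rep, data.frame(residue = character(),
                                                  substitution = character()))
  expect_equal(nrow(empty), 0L)
  # identical conformations: every residue invariant, all suggestions drop
  rep_id <- dynamic_simplices(list(
    tessellate(residue_points(ids, p1, "a"), max_edge = 1e6),
    tessellate(residue_points(ids, p1, "b"), max_edge = 1e6)))
  none <- candidate_intersection(rep_id, data.frame(residue = "A:3",
                                                    substitution = "X1Y"))
  expect_equal(nrow(none), 0L)
})

test_that("suggestion TSV reader returns residue/substitution pairs", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("A:4\tI4V", "A:26\tF26L"), f)
  sug <- read_suggestions_tsv(f)
  expect_identical(sug$residue, c("A:4", "A:26"))
  expect_identical(sug$substitution, c("I4V", "F26L"))
  unlink(f)
})
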