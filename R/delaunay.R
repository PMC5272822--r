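# 3-D Delaunay tessellation via incremental (Bowyer-Watson) insertion.
# Points are expected in general position; tessellate() guarantees this by
# deterministic symbolic-scale jitter before calling in here.

# circumsphere of a tetrahedron: center and squared radius.
# Returns NULL when the four points are (nearly) coplanar.
circumsphere <- function(p) {
  a <- 2 * sweep(p[1:3, , drop = FALSE], 2L, p[4L, ])
  b <- rowSums(p[1:3, , drop = FALSE]^2) - sum(p[4L, ]^2)
  cc <- tryCatch(solve(a, b), error = function(e) NULL)
  if (is.null(cc) || any(!is.finite(cc))) return(NULL)
  list(center = cc, r2 = sum((p[1L, ] - cc)^2))
}

#' Delaunay tessellation of 3-D points
#'
#' Incremental Bowyer-Watson construction: points are inserted one at a
#' time into a super-tetrahedron; every tetrahedron whose circumsphere
#' contains the new point is removed and the resulting cavity re-faced to
#' the point.  Input must be in general position (no 5 cospherical, no 4
#' coplanar points); degenerate inputs should be jittered first, as
#' [tessellate()] does.
#'
#' @param points Numeric matrix (n x 3), n >= 4.
#' @return Integer matrix (m x 4) of point indices, each row one simplex,
#'   sorted within rows and by row.
#' @seealso [tessellate()] for the residue-level interface with edge
#'   filtering, [circumsphere_violations()] for post-hoc validation.
#' @export
delaunay3d <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  stopifnot(ncol(points) == 3L, all(is.finite(points)))
  if (n < 4L) stop("need >= 4 points for a 3-D tessellation, got ", n)
  ctr <- colMeans(points)
  span <- max(sqrt(rowSums(sweep(points, 2L, ctr)^2)), 1)
  r <- 1e3 * span
  super <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  super <- sweep(3 * r * super, 2L, ctr, `+`)
  pts <- rbind(points, super)
  verts <- matrix(n + 1:4, nrow = 1L)
  cs <- circumsphere(pts[verts[1L, ], ])
  centers <- matrix(cs$center, nrow = 1L)
  r2 <- cs$r2
  for (i in seq_len(n)) {
    p <- pts[i, ]
    d2 <- (centers[, 1L] - p[1L])^2 + (centers[, 2L] - p[2L])^2 +
      (centers[, 3L] - p[3L])^2
    bad <- which(d2 < r2)
    if (!length(bad))
      stop("point ", i, " fell outside every circumsphere; ",
           "input is degenerate beyond jitter repair")
    # boundary of the cavity: faces of bad tetrahedra seen exactly once
    faces <- do.call(rbind, lapply(bad, function(b) {
      v <- verts[b, ]
      rbind(v[-1L], v[-2L], v[-3L], v[-4L])
    }))
    faces <- t(apply(faces, 1L, sort))
    key <- paste(faces[, 1L], faces[, 2L], faces[, 3L])
    keep <- key %in% names(which(table(key) == 1L))
    boundary <- faces[keep, , drop = FALSE]
    verts <- verts[-bad, , drop = FALSE]
    centers <- centers[-bad, , drop = FALSE]
    r2 <- r2[-bad]
    for (j in seq_len(nrow(boundary))) {
      tet <- c(boundary[j, ], i)
      cs <- circumsphere(pts[tet, ])
      if (is.null(cs)) next   # sliver against a super-vertex face
      verts <- rbind(verts, tet)
      centers <- rbind(centers, cs$center)
      r2 <- c(r2, cs$r2)
    }
  }
  keep <- rowSums(verts > n) == 0L
  out <- verts[keep, , drop = FALSE]
  if (nrow(out)) {
    out <- t(apply(out, 1L, sort))
    out <- out[do.call(order, as.data.frame(out)), , drop = FALSE]
  }
  dimnames(out) <- NULL
  out
}

#' Brute-force Delaunay simplices by exhaustive circumsphere test
#'
#' Enumerates every 4-point subset and keeps those whose circumsphere
#' contains no other point strictly inside (up to `tol`).  Exponential in
#' n; intended as an independent oracle for small point sets.
#'
#' @param points Numeric matrix (n x 3), points in general position.
#' @param tol Containment slack (squared-distance, absolute).
#' @return Integer matrix (m x 4), same format as [delaunay3d()].
#' @export
delaunay3d_bruteforce <- function(points, tol = 1e-9) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n >= 4L, ncol(points) == 3L)
  quads <- utils::combn(n, 4L)
  keep <- apply(quads, 2L, function(q) {
    cs <- circumsphere(points[q, ])
    if (is.null(cs)) return(FALSE)
    others <- setdiff(seq_len(n), q)
    if (!length(others)) return(TRUE)
    d2 <- rowSums(sweep(points[others, , drop = FALSE], 2L, cs$center)^2)
    all(d2 > cs$r2 - tol)
  })
  out <- t(quads[, keep, drop = FALSE])
  out[do.call(order, as.data.frame(out)), , drop = FALSE]
}

#' Post-hoc empty-circumsphere validation
#'
#' For each simplex, the largest penetration of any foreign point into the
#' simplex circumsphere, measured as sqrt(r2) - sqrt(d2) in the input's
#' length units (0 when empty).
#'
#' @param points Numeric matrix (n x 3).
#' @param simplices Integer matrix (m x 4) of row indices into `points`.
#' @return Numeric vector of per-simplex worst penetrations (>= 0).
#' @export
circumsphere_violations <- function(points, simplices) {
  points <- as.matrix(points)
  apply(simplices, 1L, function(q) {
    cs <- circumsphere(points[q, ])
    if (is.null(cs)) return(Inf)
    others <- setdiff(seq_len(nrow(points)), q)
    if (!length(others)) return(0)
    d <- sqrt(rowSums(sweep(points[others, , drop = FALSE], 2L,
                            cs$center)^2))
    max(0, sqrt(cs$r2) - min(d))
  })
}
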