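#' Closed triangulated surface mesh
#'
#' Constructs a `tri_mesh`, the geometric carrier used throughout the
#' package for torso, organ and ventricular (candidate-source) surfaces.
#' Vertices are 3-D points in millimetres, triangles are 1-based vertex
#' index triplets.  A valid `tri_mesh` is closed (every undirected edge
#' shared by exactly two triangles), consistently oriented with outward
#' normals (positive signed volume) and free of degenerate triangles.
#'
#' Coordinates are right-handed with the torso long axis along z.
#'
#' @param vertices numeric matrix (n x 3), mm.
#' @param triangles integer matrix (m x 3) of 1-based vertex indices.
#' @param name label carried through downstream objects.
#' @param repair logical; attempt automatic orientation repair by
#'   breadth-first flip propagation before validation (default `TRUE`).
#' @return An object of class `tri_mesh` with elements `vertices`,
#'   `triangles`, `name`.
#' @seealso [read_mesh()], [signed_volume()], [solid_angle()]
#' @export
tri_mesh <- function(vertices, triangles, name = "mesh", repair = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  if (anyNA(vertices) || any(!is.finite(vertices)))
    stop("non-finite vertex coordinates")
  n <- nrow(vertices)
  if (any(triangles < 1L) || any(triangles > n))
    stop("triangle index out of range")
  if (any(triangles[, 1L] == triangles[, 2L] |
          triangles[, 2L] == triangles[, 3L] |
          triangles[, 1L] == triangles[, 3L]))
    stop("degenerate triangle: repeated vertex index")

  mesh <- structure(list(vertices = vertices, triangles = triangles,
                         name = as.character(name)[1L]),
                    class = "tri_mesh")

  ## zero-area check relative to the mesh scale
  a <- triangle_areas(mesh)
  if (any(a <= 1e-12 * max(a)))
    stop("degenerate triangle: zero area")

  check_closed(mesh)
  if (repair) mesh <- repair_orientation(mesh)
  check_oriented(mesh)
  if (signed_volume(mesh) <= 0)
    stop("inconsistent orientation: negative signed volume after repair")
  mesh
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh '%s': %d vertices, %d triangles, volume %.6g mm^3\n",
              x$name, nrow(x$vertices), nrow(x$triangles),
              signed_volume(x)))
  invisible(x)
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  e1 <- v[tr[, 2L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  e2 <- v[tr[, 3L], , drop = FALSE] - v[tr[, 1L], , drop = FALSE]
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

edge_table <- function(triangles) {
  m <- nrow(triangles)
  from <- c(triangles[, 1L], triangles[, 2L], triangles[, 3L])
  to   <- c(triangles[, 2L], triangles[, 3L], triangles[, 1L])
  data.frame(from = from, to = to,
             tri = rep.int(seq_len(m), 3L),
             key = paste(pmin(from, to), pmax(from, to)),
             stringsAsFactors = FALSE)
}

check_closed <- function(mesh) {
  ed <- edge_table(mesh$triangles)
  cnt <- table(ed$key)
  if (any(cnt != 2L))
    stop("open surface: ", sum(cnt != 2L),
         " edge(s) not shared by exactly two triangles")
  invisible(TRUE)
}

check_oriented <- function(mesh) {
  ed <- edge_table(mesh$triangles)
  dkey <- paste(ed$from, ed$to)
  if (anyDuplicated(dkey))
    stop("inconsistent orientation: duplicated directed edge")
  invisible(TRUE)
}

## Breadth-first flip propagation: neighbours across a shared edge must
## traverse it in opposite directions; afterwards each connected
## component is flipped wholesale if its signed volume is negative.
repair_orientation <- function(mesh) {
  tr <- mesh$triangles
  m <- nrow(tr)
  ed <- edge_table(tr)
  adj <- split(ed$tri, ed$key)           # 2 triangles per undirected edge
  tri_edges <- split(ed$key, ed$tri)
  flipped <- rep(FALSE, m)
  visited <- rep(FALSE, m)
  comp_id <- rep(NA_integer_, m)
  comp <- 0L
  dir_of <- function(t, key) {
    ## +1 if triangle t (possibly flipped) traverses edge key low->high
    idx <- tr[t, ]
    if (flipped[t]) idx <- idx[c(1L, 3L, 2L)]
    pts <- as.integer(strsplit(key, " ", fixed = TRUE)[[1L]])
    e <- rbind(idx[c(1L, 2L)], idx[c(2L, 3L)], idx[c(3L, 1L)])
    hit <- which((e[, 1L] == pts[1L] & e[, 2L] == pts[2L]) |
                 (e[, 1L] == pts[2L] & e[, 2L] == pts[1L]))[1L]
    if (e[hit, 1L] == pts[1L]) 1L else -1L
  }
  for (start in seq_len(m)) {
    if (visited[start]) next
    comp <- comp + 1L
    queue <- start
    visited[start] <- TRUE
    comp_id[start] <- comp
    while (length(queue)) {
      t <- queue[[1L]]; queue <- queue[-1L]
      for (key in tri_edges[[as.character(t)]]) {
        nb <- setdiff(adj[[key]], t)
        for (u in nb) {
          if (visited[u]) next
          ## consistent orientation: opposite traversal of the shared edge
          if (dir_of(u, key) == dir_of(t, key)) flipped[u] <- TRUE
          visited[u] <- TRUE
          comp_id[u] <- comp
          queue <- c(queue, u)
        }
      }
    }
  }
  if (any(flipped))
    tr[flipped, ] <- tr[flipped, c(1L, 3L, 2L), drop = FALSE]
  mesh$triangles <- tr
  ## outward convention per component
  for (cc in seq_len(comp)) {
    sel <- comp_id == cc
    sub <- mesh
    sub$triangles <- tr[sel, , drop = FALSE]
    if (signed_volume(sub) < 0)
      tr[sel, ] <- tr[sel, c(1L, 3L, 2L), drop = FALSE]
  }
  mesh$triangles <- tr
  mesh
}

#' Signed enclosed volume of a triangulated surface
#'
#' Divergence-theorem volume; positive for a closed surface with
#' outward-oriented triangles.
#'
#' @param mesh a [tri_mesh()] (or a compatible list).
#' @return volume in mm^3.
#' @export
signed_volume <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1L], , drop = FALSE]
  b <- v[tr[, 2L], , drop = FALSE]
  c3 <- v[tr[, 3L], , drop = FALSE]
  d <- a[, 1L] * (b[, 2L] * c3[, 3L] - b[, 3L] * c3[, 2L]) -
       a[, 2L] * (b[, 1L] * c3[, 3L] - b[, 3L] * c3[, 1L]) +
       a[, 3L] * (b[, 1L] * c3[, 2L] - b[, 2L] * c3[, 1L])
  sum(d) / 6
}

mesh_diameter <- function(mesh) {
  rg <- apply(mesh$vertices, 2L, range)
  sqrt(sum((rg[2L, ] - rg[1L, ])^2))
}

mean_edge_length <- function(mesh) {
  ed <- edge_table(mesh$triangles)
  ed <- ed[!duplicated(ed$key), ]
  d <- mesh$vertices[ed$from, , drop = FALSE] -
       mesh$vertices[ed$to, , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Signed solid angle of an oriented triangle
#'
#' Analytic plane-triangle solid angle (van Oosterom-Strackee) at an
#' observation point, with the sign convention that a closed
#' outward-oriented surface subtends -4*pi at an interior point and 0 at
#' an exterior point.
#'
#' @param tri 3 x 3 matrix, one triangle vertex per row (mm).
#' @param obs observation point, length-3 numeric (mm).
#' @param tol singular tolerance on the observer-to-plane distance,
#'   relative to the triangle scale.
#' @return solid angle in steradians.
#' @export
solid_angle <- function(tri, obs, tol = 1e-9) {
  tri <- as.matrix(tri)
  r1 <- tri[1L, ] - obs
  r2 <- tri[2L, ] - obs
  r3 <- tri[3L, ] - obs
  n1 <- sqrt(sum(r1^2)); n2 <- sqrt(sum(r2^2)); n3 <- sqrt(sum(r3^2))
  scale <- max(n1, n2, n3, mesh_scale_of(tri))
  num <- r1[1L] * (r2[2L] * r3[3L] - r2[3L] * r3[2L]) -
         r1[2L] * (r2[1L] * r3[3L] - r2[3L] * r3[1L]) +
         r1[3L] * (r2[1L] * r3[2L] - r2[2L] * r3[1L])
  den <- n1 * n2 * n3 + sum(r1 * r2) * n3 + sum(r1 * r3) * n2 +
         sum(r2 * r3) * n1
  ## plane distance = |num| / (2 * area)
  area2 <- 2 * triangle_areas(list(vertices = tri,
                                   triangles = matrix(1:3, 1L)))
  if (abs(num) < tol * scale * area2 && den <= 0)
    stop("singular geometry: observation point lies on the triangle")
  -2 * atan2(num, den)
}

mesh_scale_of <- function(tri) {
  max(sqrt(rowSums((tri - tri[c(2L, 3L, 1L), , drop = FALSE])^2)))
}

## Vectorised solid angles of all triangles of a mesh at one observation
## point (package sign convention).  `skip` marks triangles whose angle
## is taken as 0 (e.g. triangles incident to the observation vertex,
## handled by the BEM auto term).
mesh_solid_angles <- function(mesh, obs, skip = NULL, tol = 1e-9) {
  v <- mesh$vertices; tr <- mesh$triangles
  r1 <- v[tr[, 1L], , drop = FALSE] - rep(obs, each = nrow(tr))
  r2 <- v[tr[, 2L], , drop = FALSE] - rep(obs, each = nrow(tr))
  r3 <- v[tr[, 3L], , drop = FALSE] - rep(obs, each = nrow(tr))
  n1 <- sqrt(rowSums(r1^2)); n2 <- sqrt(rowSums(r2^2)); n3 <- sqrt(rowSums(r3^2))
  num <- r1[, 1L] * (r2[, 2L] * r3[, 3L] - r2[, 3L] * r3[, 2L]) -
         r1[, 2L] * (r2[, 1L] * r3[, 3L] - r2[, 3L] * r3[, 1L]) +
         r1[, 3L] * (r2[, 1L] * r3[, 2L] - r2[, 2L] * r3[, 1L])
  den <- n1 * n2 * n3 + rowSums(r1 * r2) * n3 + rowSums(r1 * r3) * n2 +
         rowSums(r2 * r3) * n1
  omega <- -2 * atan2(num, den)
  if (!is.null(skip)) omega[skip] <- 0
  live <- if (is.null(skip)) rep(TRUE, nrow(tr)) else !skip
  bad <- live & abs(num) < tol * mesh_diameter(mesh) *
           pmax(n1, n2, n3) & den <= 0
  if (any(bad))
    stop("singular geometry: observation point on a surface triangle")
  omega
}

## Interior test by the Gauss solid-angle identity.
points_inside <- function(mesh, pts) {
  pts <- matrix(pts, ncol = 3L)
  vapply(seq_len(nrow(pts)), function(i) {
    tot <- sum(mesh_solid_angles(mesh, pts[i, ]))
    abs(tot + 4 * pi) < 1e-6
  }, logical(1L))
}

#' Unit icosphere
#'
#' Subdivided icosahedron projected to the unit sphere; refinement level
#' `n` has `10 * 4^n + 2` vertices and `20 * 4^n` triangles.
#'
#' @param refine non-negative integer subdivision level.
#' @return a [tri_mesh()] of the unit sphere.
#' @export
icosphere <- function(refine = 2L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(refine)) {
    midcache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- list(v)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      got <- midcache[[key]]
      if (!is.null(got)) return(got)
      p <- (v[i, ] + v[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- p
      midcache[[key]] <- nv
      nv
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    k <- 0L
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1L]; b <- f[t, 2L]; c3 <- f[t, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf[k + 1L, ] <- c(a, ab, ca)
      newf[k + 2L, ] <- c(b, bc, ab)
      newf[k + 3L, ] <- c(c3, ca, bc)
      newf[k + 4L, ] <- c(ab, bc, ca)
      k <- k + 4L
    }
    v <- do.call(rbind, vlist)
    f <- newf
  }
  tri_mesh(v, f, name = sprintf("icosphere_%d", refine))
}

#' Ellipsoid surface mesh
#'
#' Axis-aligned ellipsoid built by anisotropic scaling of an icosphere.
#'
#' @param center length-3 centre (mm).
#' @param semi_axes length-3 semi-axes (mm).
#' @param refine icosphere refinement level.
#' @param name mesh label.
#' @return a [tri_mesh()].
#' @export
ellipsoid_mesh <- function(center = c(0, 0, 0), semi_axes = c(1, 1, 1),
                           refine = 2L, name = "ellipsoid") {
  s <- icosphere(refine)
  v <- sweep(s$vertices, 2L, semi_axes, `*`)
  v <- sweep(v, 2L, center, `+`)
  tri_mesh(v, s$triangles, name = name)
}
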