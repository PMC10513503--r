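#' Infinite-medium dipole potential
#'
#' Potential of a current dipole in an unbounded homogeneous medium,
#' `phi = p . (r - src) / (4 pi sigma |r - src|^3)`; the source term of
#' the boundary element formulation.
#'
#' @param src dipole position, length-3 (mm).
#' @param moment dipole moment, length-3 (mA mm).
#' @param field_pts matrix of field points (n x 3, mm).
#' @param sigma medium conductivity (S/m).
#' @return numeric vector of potentials at `field_pts`.
#' @export
infinite_potential <- function(src, moment, field_pts, sigma) {
  field_pts <- matrix(field_pts, ncol = 3L)
  R <- sweep(field_pts, 2L, src, `-`)
  r3 <- rowSums(R^2)^1.5
  if (any(r3 == 0)) stop("singular source: field point coincides with src")
  as.numeric(R %*% moment) / (4 * pi * sigma * r3)
}

#' Assemble and factorize the BEM system of a volume conductor
#'
#' Vertex-collocation boundary element discretization of the surface
#' potential integral equation for a piecewise-homogeneous conductor:
#' potentials live at mesh vertices, each triangle's analytic solid
#' angle is split equally among its three vertices, and the singular
#' auto (diagonal) term is fixed by the row-sum identity (the angles a
#' closed surface subtends at a point on it total 2 pi).  The rank-one
#' null space of the insulated problem (potential defined up to a
#' constant) is removed by deflation: `(1/N) ones %*% t(ones)` is added
#' on the outermost-surface block, and every solution is subsequently
#' re-referenced to zero mean over torso vertices.
#'
#' The factorized system is reused across all source positions.
#'
#' @param vc a [volume_conductor()].
#' @return object of class `bem_system` carrying the QR factorization
#'   and vertex bookkeeping.
#' @export
bem_system <- function(vc) {
  surfaces <- vc$surfaces
  L <- length(surfaces)
  nvert <- vapply(surfaces, function(s) nrow(s$vertices), integer(1L))
  offset <- cumsum(c(0L, nvert[-L]))
  N <- sum(nvert)
  allv <- do.call(rbind, lapply(surfaces, `[[`, "vertices"))
  coef <- (vc$sigma_in - vc$sigma_out) / (4 * pi)

  ## triangles incident to each vertex, per surface (for the auto term)
  incident <- lapply(surfaces, function(s) {
    tr <- s$triangles
    split(rep(seq_len(nrow(tr)), 3L), as.vector(tr))
  })

  A <- matrix(0, N, N)
  for (k in seq_len(L)) {
    sk <- surfaces[[k]]
    for (i_local in seq_len(nvert[k])) {
      i <- offset[k] + i_local
      obs <- sk$vertices[i_local, ]
      for (l in seq_len(L)) {
        sl <- surfaces[[l]]
        skip <- NULL
        if (l == k) {
          skip <- rep(FALSE, nrow(sl$triangles))
          skip[incident[[k]][[as.character(i_local)]]] <- TRUE
        }
        omega <- mesh_solid_angles(sl, obs, skip = skip)
        wtri <- -omega / 3                     # standard-sign angles / 3
        w <- rowsum(rep(wtri, 3L), as.vector(sl$triangles))
        wv <- numeric(nvert[l])
        wv[as.integer(rownames(w))] <- w
        if (l == k)                            # auto term via row-sum identity
          wv[i_local] <- 2 * pi - sum(wv)
        A[i, offset[l] + seq_len(nvert[l])] <-
          A[i, offset[l] + seq_len(nvert[l])] - coef[l] * wv
      }
      A[i, i] <- A[i, i] + (vc$sigma_in[k] + vc$sigma_out[k]) / 2
    }
  }

  torso_idx <- seq_len(nvert[1L])
  A[torso_idx, torso_idx] <- A[torso_idx, torso_idx] + 1 / nvert[1L]
  fac <- qr(A)
  if (fac$rank < N)
    stop(sprintf(
      "BEM system singular beyond deflation: rank %d of %d", fac$rank, N))
  structure(list(qr = fac, n_vertices = nvert, offset = offset,
                 torso_idx = torso_idx, all_vertices = allv,
                 vc = vc),
            class = "bem_system")
}

#' @export
print.bem_system <- function(x, ...) {
  cat(sprintf("bem_system: %d surfaces, %d vertices total\n",
              length(x$n_vertices), sum(x$n_vertices)))
  invisible(x)
}

## deflated solve + zero-mean re-referencing over torso vertices
bem_solve <- function(sys, B) {
  phi <- solve(sys$qr, B)
  sweep(phi, 2L, colMeans(phi[sys$torso_idx, , drop = FALSE]), `-`)
}

## RHS columns for unit dipoles along X, Y, Z at each source (the
## source conductivity cancels against the sigma_s factor of the
## integral equation, so the term is purely geometric)
bem_rhs <- function(sys, sources) {
  sources <- matrix(sources, ncol = 3L)
  J <- nrow(sources)
  B <- matrix(0, sum(sys$n_vertices), 3L * J)
  for (j in seq_len(J)) {
    R <- sweep(sys$all_vertices, 2L, sources[j, ], `-`)
    r3 <- rowSums(R^2)^1.5
    if (any(r3 == 0)) stop("singular source: source on a surface vertex")
    B[, 3L * (j - 1L) + 1:3] <- R / (4 * pi * r3)
  }
  B
}

#' Transfer matrix for a single dipole position
#'
#' Solves the BEM system for three unit dipoles along the X, Y and Z
#' axes at `src` and returns the potentials at the montage electrodes:
#' the M x 3 transfer matrix mapping dipole moment components to
#' electrode potentials (zero-mean common reference over torso
#' vertices).
#'
#' @param vc a [volume_conductor()].
#' @param src source position, length-3 (mm), strictly interior.
#' @param system optional pre-assembled [bem_system()] (reused when
#'   computing many positions).
#' @return numeric matrix (M x 3), columns ordered X, Y, Z.
#' @export
transfer_matrix <- function(vc, src, system = NULL) {
  if (is.null(system)) system <- bem_system(vc)
  phi <- bem_solve(system, bem_rhs(system, src))
  phi[system$torso_idx, , drop = FALSE][vc$montage$vertex_ids, , drop = FALSE]
}

#' Transfer matrices at every candidate source vertex
#'
#' Builds the per-position M x 3 transfer matrices for all vertices of
#' the candidate-source (endo-epicardial) surface, reusing one
#' factorized BEM system.  Every candidate must lie strictly inside the
#' torso and outside all internal interfaces.
#'
#' @param vc a [volume_conductor()].
#' @param heart a [tri_mesh()] whose vertices are the candidate dipole
#'   positions.
#' @param system optional pre-assembled [bem_system()].
#' @param check verify candidate containment (solid-angle test).
#' @return object of class `transfer_stack`: `positions` (J x 3),
#'   `blocks` (list of J M x 3 matrices), `labels`, `conductor_id`.
#' @export
transfer_stack <- function(vc, heart, system = NULL, check = TRUE) {
  pos <- heart$vertices
  if (check) {
    if (!all(points_inside(vc$surfaces[[1L]], pos)))
      stop("candidate source vertex outside the torso surface")
    if (length(vc$surfaces) > 1L)
      for (l in 2:length(vc$surfaces))
        if (any(points_inside(vc$surfaces[[l]], pos)))
          stop("candidate source vertex inside internal surface ", l)
  }
  if (is.null(system)) system <- bem_system(vc)
  phi <- bem_solve(system, bem_rhs(system, pos))
  el <- system$torso_idx[vc$montage$vertex_ids]
  J <- nrow(pos)
  blocks <- lapply(seq_len(J), function(j)
    phi[el, 3L * (j - 1L) + 1:3, drop = FALSE])
  for (j in seq_len(J)) {
    sv <- svd(blocks[[j]], nu = 0L, nv = 0L)$d
    if (sv[3L] <= 1e-12 * sv[1L])
      stop("transfer block ", j, " is rank deficient (sigma3 ~ 0)")
  }
  structure(list(positions = pos, blocks = blocks,
                 labels = vc$montage$labels,
                 conductor_id = conductor_id(vc)),
            class = "transfer_stack")
}

conductor_id <- function(vc) {
  paste0(length(vc$surfaces), "s-",
         paste(signif(vc$sigma_in, 6), collapse = "/"), "-M",
         length(vc$montage$vertex_ids))
}

#' @export
print.transfer_stack <- function(x, ...) {
  M <- nrow(x$blocks[[1L]])
  cond <- vapply(x$blocks, function(b) {
    d <- svd(b, nu = 0L, nv = 0L)$d; d[1L] / d[3L]
  }, numeric(1L))
  cat(sprintf(
    "transfer_stack: %d positions, %d electrodes; conditioning %.2f +/- %.2f\n",
    length(x$blocks), M, mean(cond), stats::sd(cond)))
  invisible(x)
}

#' Forward body-surface potential map
#'
#' `Phi = T %*% moments`: potentials at the electrodes produced by a
#' dipole moment trajectory at the position of the given transfer
#' block.
#'
#' @param block M x 3 transfer matrix.
#' @param moments 3 x T moment trajectory (mA mm).
#' @param sample_rate sampling rate (Hz).
#' @param labels optional electrode labels.
#' @return a [bsp_map()].
#' @export
forward_bsp <- function(block, moments, sample_rate = 1000,
                        labels = NULL) {
  block <- as.matrix(block); moments <- as.matrix(moments)
  if (ncol(block) != 3L || nrow(moments) != 3L)
    stop("shape mismatch: block must be M x 3 and moments 3 x T")
  bsp_map(block %*% moments, sample_rate = sample_rate,
          electrode_labels = labels)
}

#' Serialize a transfer stack to CSV
#'
#' Long format: one row per (position, electrode) with columns
#' `position`, `electrode`, `Tx`, `Ty`, `Tz`, preceded by a positions
#' table `<path>_positions.csv`.
#'
#' @param stack a `transfer_stack`.
#' @param path base CSV path.
#' @return `path` (write) or a `transfer_stack` (read).
#' @export
write_transfer_stack <- function(stack, path) {
  J <- length(stack$blocks); M <- nrow(stack$blocks[[1L]])
  long <- do.call(rbind, lapply(seq_len(J), function(j)
    data.frame(position = j, electrode = seq_len(M),
               Tx = stack$blocks[[j]][, 1L],
               Ty = stack$blocks[[j]][, 2L],
               Tz = stack$blocks[[j]][, 3L])))
  utils::write.csv(long, path, row.names = FALSE)
  ppath <- sub("(\\.csv)?$", "_positions.csv", path)
  utils::write.csv(data.frame(x = stack$positions[, 1L],
                              y = stack$positions[, 2L],
                              z = stack$positions[, 3L]),
                   ppath, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transfer_stack
#' @export
read_transfer_stack <- function(path) {
  long <- utils::read.csv(path)
  ppath <- sub("(\\.csv)?$", "_positions.csv", path)
  pos <- as.matrix(utils::read.csv(ppath))
  blocks <- lapply(split(long, long$position), function(d)
    unname(as.matrix(d[order(d$electrode), c("Tx", "Ty", "Tz")])))
  blocks <- blocks[order(as.integer(names(blocks)))]
  names(blocks) <- NULL
  structure(list(positions = unname(pos), blocks = blocks,
                 labels = NULL, conductor_id = "file"),
            class = "transfer_stack")
}
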