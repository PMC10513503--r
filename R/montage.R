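#' Strip electrode montage on a torso surface
#'
#' Emulates a multi-lead strip montage (default 16 vertical strips of 8
#' electrodes, 128 electrodes total): nominal sites are laid out on
#' equally spaced azimuthal lines around the torso long axis (z) at
#' equally spaced axial levels inside `z_range`, then snapped to the
#' nearest torso mesh vertex.  If two nominal sites snap to the same
#' vertex, the later site takes the nearest unused vertex so the
#' electrode count is preserved exactly.
#'
#' Nominal 3-D sites are obtained by casting a horizontal ray from the
#' torso axis at each (azimuth, level) pair and taking its outermost
#' intersection with the surface.
#'
#' @param torso a [tri_mesh()].
#' @param n_strips number of azimuthal strips.
#' @param per_strip electrodes per strip.
#' @param z_range axial extent as fractions of the torso bounding box,
#'   length-2 in `[0, 1]`.
#' @return An object of class `electrode_montage`: list with
#'   `vertex_ids` (1-based torso vertex indices), `labels`
#'   (`"S<strip>E<level>"`), `strip_of`, `level_of`, and the nominal
#'   sites used for snapping.
#' @export
electrode_strips <- function(torso, n_strips = 16L, per_strip = 8L,
                             z_range = c(0.25, 0.75)) {
  stopifnot(length(z_range) == 2L, all(z_range >= 0), all(z_range <= 1),
            z_range[1L] < z_range[2L])
  M <- n_strips * per_strip
  v <- torso$vertices
  if (nrow(v) < M)
    stop("torso mesh has fewer vertices than requested electrodes")
  zr <- range(v[, 3L])
  zs <- zr[1L] + (z_range[1L] + (z_range[2L] - z_range[1L]) *
                    (seq_len(per_strip) - 0.5) / per_strip) * diff(zr)
  az <- 2 * pi * (seq_len(n_strips) - 1L) / n_strips
  axis_xy <- colMeans(v[, 1:2, drop = FALSE])

  nominal <- matrix(NA_real_, M, 3L)
  strip_of <- integer(M); level_of <- integer(M)
  k <- 0L
  for (s in seq_len(n_strips)) {
    dir <- c(cos(az[s]), sin(az[s]), 0)
    for (l in seq_len(per_strip)) {
      k <- k + 1L
      origin <- c(axis_xy, zs[l])
      hit <- ray_mesh_intersect(torso, origin, dir)
      nominal[k, ] <- if (is.null(hit)) origin else hit
      strip_of[k] <- s; level_of[k] <- l
    }
  }

  vertex_ids <- integer(M)
  used <- rep(FALSE, nrow(v))
  for (k in seq_len(M)) {
    d2 <- rowSums(sweep(v, 2L, nominal[k, ], `-`)^2)
    j <- which.min(d2)
    if (used[j]) {                       # conflict: nearest unused vertex
      d2[used] <- Inf
      j <- which.min(d2)
      if (!is.finite(d2[j]))
        stop("electrode snapping exhausted distinct torso vertices")
    }
    used[j] <- TRUE
    vertex_ids[k] <- j
  }
  structure(list(vertex_ids = vertex_ids,
                 labels = sprintf("S%02dE%d", strip_of, level_of),
                 strip_of = strip_of, level_of = level_of,
                 nominal = nominal),
            class = "electrode_montage")
}

#' @export
print.electrode_montage <- function(x, ...) {
  cat(sprintf("electrode_montage: %d electrodes (%d strips x %d levels)\n",
              length(x$vertex_ids), max(x$strip_of), max(x$level_of)))
  invisible(x)
}

## Moeller-Trumbore over all triangles; returns the farthest intersection
## along the (positive) ray, or NULL.
ray_mesh_intersect <- function(mesh, origin, dir) {
  v <- mesh$vertices; tr <- mesh$triangles
  p0 <- v[tr[, 1L], , drop = FALSE]
  e1 <- v[tr[, 2L], , drop = FALSE] - p0
  e2 <- v[tr[, 3L], , drop = FALSE] - p0
  h <- cbind(dir[2L] * e2[, 3L] - dir[3L] * e2[, 2L],
             dir[3L] * e2[, 1L] - dir[1L] * e2[, 3L],
             dir[1L] * e2[, 2L] - dir[2L] * e2[, 1L])
  a <- rowSums(e1 * h)
  ok <- abs(a) > 1e-12
  s <- sweep(p0, 2L, origin, function(p, o) o - p)   # origin - p0
  u <- rowSums(s * h) / a
  q <- cbind(s[, 2L] * e1[, 3L] - s[, 3L] * e1[, 2L],
             s[, 3L] * e1[, 1L] - s[, 1L] * e1[, 3L],
             s[, 1L] * e1[, 2L] - s[, 2L] * e1[, 1L])
  vv <- (q[, 1L] * dir[1L] + q[, 2L] * dir[2L] + q[, 3L] * dir[3L]) / a
  t <- rowSums(e2 * q) / a
  hit <- ok & u >= -1e-9 & vv >= -1e-9 & (u + vv) <= 1 + 1e-9 & t > 1e-9
  if (!any(hit)) return(NULL)
  origin + max(t[hit]) * dir
}

#' Write / read an electrode montage as CSV
#'
#' Columns: `label`, `strip`, `level`, `vertex_id` (1-based).
#'
#' @param montage an `electrode_montage`.
#' @param path CSV file path.
#' @return `path` (write) or an `electrode_montage` (read).
#' @export
write_montage <- function(montage, path) {
  utils::write.csv(data.frame(label = montage$labels,
                              strip = montage$strip_of,
                              level = montage$level_of,
                              vertex_id = montage$vertex_ids),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  d <- utils::read.csv(path)
  structure(list(vertex_ids = as.integer(d$vertex_id),
                 labels = as.character(d$label),
                 strip_of = as.integer(d$strip),
                 level_of = as.integer(d$level),
                 nominal = NULL),
            class = "electrode_montage")
}
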