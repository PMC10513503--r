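#' Piecewise-homogeneous volume conductor
#'
#' Bundles an ordered set of nested closed surfaces (outermost torso
#' first) with inside/outside conductivities and the electrode montage
#' on the torso surface.  The exterior of the torso is insulating
#' (`sigma_out[1] == 0`).  The standard inhomogeneous cardiac model uses
#' lungs at 0.25x and intracavitary blood at 3x the torso conductivity.
#'
#' @param surfaces list of [tri_mesh()], torso first.
#' @param sigma_in,sigma_out per-surface conductivities (S/m): the
#'   conductivity just inside / just outside each surface.
#' @param montage an `electrode_montage` on `surfaces[[1]]`.
#' @param check verify nesting (inner surfaces strictly inside the
#'   torso) by a solid-angle interior test on a vertex sample.
#' @return object of class `volume_conductor`.
#' @export
volume_conductor <- function(surfaces, sigma_in, sigma_out, montage,
                             check = TRUE) {
  stopifnot(is.list(surfaces), length(surfaces) >= 1L)
  L <- length(surfaces)
  sigma_in <- as.numeric(sigma_in); sigma_out <- as.numeric(sigma_out)
  if (length(sigma_in) != L || length(sigma_out) != L)
    stop("sigma_in/sigma_out must have one value per surface")
  if (sigma_out[1L] != 0)
    stop("torso exterior must be insulating (sigma_out[1] == 0)")
  if (any(sigma_in + sigma_out <= 0))
    stop("sigma_in + sigma_out must be positive for every surface")
  if (!inherits(montage, "electrode_montage"))
    stop("montage must be an electrode_montage")
  if (max(montage$vertex_ids) > nrow(surfaces[[1L]]$vertices))
    stop("montage vertex ids exceed torso vertex count")
  if (check && L > 1L) {
    for (l in 2:L) {
      samp <- unique(round(seq(1L, nrow(surfaces[[l]]$vertices), length.out = 8L)))
      ins <- points_inside(surfaces[[1L]], surfaces[[l]]$vertices[samp, , drop = FALSE])
      if (!all(ins))
        stop("surface ", l, " is not strictly inside the torso surface")
    }
  }
  structure(list(surfaces = surfaces, sigma_in = sigma_in,
                 sigma_out = sigma_out, montage = montage),
            class = "volume_conductor")
}

#' @export
print.volume_conductor <- function(x, ...) {
  cat(sprintf("volume_conductor: %d surface(s), %d electrodes\n",
              length(x$surfaces), length(x$montage$vertex_ids)))
  for (l in seq_along(x$surfaces))
    cat(sprintf("  [%d] %-16s sigma_in %.3g  sigma_out %.3g S/m\n", l,
                x$surfaces[[l]]$name, x$sigma_in[l], x$sigma_out[l]))
  invisible(x)
}

## conductivity of the region containing a point: sigma_in of the
## innermost (smallest-volume) surface that contains it
conductivity_at <- function(vc, point) {
  containing <- which(vapply(vc$surfaces, function(s)
    points_inside(s, point), logical(1L)))
  if (!length(containing))
    stop("point lies outside the torso surface")
  vols <- vapply(vc$surfaces[containing], signed_volume, numeric(1L))
  vc$sigma_in[containing[which.min(vols)]]
}
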