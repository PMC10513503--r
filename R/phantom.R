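#' Specification of a synthetic torso phantom
#'
#' Collects every knob of the synthetic-data generator: nested
#' ellipsoid geometry (torso, candidate-source heart surface, optional
#' lungs and blood cavities), the strip electrode montage, the
#' ground-truth dipole, and the noise model.  Defaults emulate a
#' 128-electrode (16 strips x 8) recording of an averaged ectopic
#' beat's first 30 ms at 1 kHz on an adult-sized torso.
#'
#' The moment trajectory is a fixed unit direction with linearly
#' ramping magnitude (an early-activation growth proxy).  The direction
#' is drawn from `direction_seed` so that the clean (noise-free) map is
#' identical across noise seeds; `seed` drives only the additive noise.
#' `snr_db` is defined on the vectorized clean map:
#' `10 * log10(signal power / noise power)`; `Inf` means noise-free.
#'
#' @param torso_semi_axes,torso_center torso ellipsoid (mm).
#' @param heart_semi_axes,heart_center candidate-source surface (mm).
#' @param organs `"none"` (homogeneous conductor) or `"lungs+cavities"`
#'   (two lungs at `ratio_lungs` x torso conductivity, two blood
#'   cavities at `ratio_cavities` x).
#' @param refine_torso,refine_heart,refine_organs icosphere refinement
#'   levels.
#' @param n_strips,per_strip,z_range electrode montage layout (see
#'   [electrode_strips()]).
#' @param sigma_torso torso conductivity (S/m).
#' @param ratio_lungs,ratio_cavities conductivity ratios to torso.
#' @param true_vertex ground-truth candidate vertex index on the heart
#'   surface.
#' @param snr_db signal-to-noise ratio (dB), `Inf` for noise-free.
#' @param seed RNG seed for the additive noise.
#' @param direction_seed RNG seed for the (fixed) moment direction.
#' @param moment_peak peak moment magnitude (mA mm).
#' @param n_samples,sample_rate map length and rate (default 30
#'   samples at 1000 Hz).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(torso_semi_axes = c(150, 100, 300),
                         torso_center = c(0, 0, 0),
                         heart_semi_axes = c(35, 35, 40),
                         heart_center = c(0, 40, 30),
                         organs = c("none", "lungs+cavities"),
                         refine_torso = 3L, refine_heart = 2L,
                         refine_organs = 2L,
                         n_strips = 16L, per_strip = 8L,
                         z_range = c(0.25, 0.75),
                         sigma_torso = 0.2, ratio_lungs = 0.25,
                         ratio_cavities = 3,
                         true_vertex = 1L, snr_db = 20,
                         seed = 1L, direction_seed = 101L,
                         moment_peak = 10, n_samples = 30L,
                         sample_rate = 1000) {
  organs <- match.arg(organs)
  spec <- list(torso_semi_axes = torso_semi_axes,
               torso_center = torso_center,
               heart_semi_axes = heart_semi_axes,
               heart_center = heart_center, organs = organs,
               refine_torso = as.integer(refine_torso),
               refine_heart = as.integer(refine_heart),
               refine_organs = as.integer(refine_organs),
               n_strips = as.integer(n_strips),
               per_strip = as.integer(per_strip), z_range = z_range,
               sigma_torso = sigma_torso, ratio_lungs = ratio_lungs,
               ratio_cavities = ratio_cavities,
               true_vertex = as.integer(true_vertex), snr_db = snr_db,
               seed = as.integer(seed),
               direction_seed = as.integer(direction_seed),
               moment_peak = moment_peak,
               n_samples = as.integer(n_samples),
               sample_rate = sample_rate)
  stopifnot(all(spec$torso_semi_axes > 0), all(spec$heart_semi_axes > 0),
            is.finite(spec$snr_db) || is.infinite(spec$snr_db))
  class(spec) <- "phantom_spec"
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom_spec: torso (%s) mm, heart (%s) mm at (%s), %s,\n  %dx%d electrodes, true vertex %d, SNR %g dB, seed %d\n",
    paste(x$torso_semi_axes, collapse = "x"),
    paste(x$heart_semi_axes, collapse = "x"),
    paste(x$heart_center, collapse = ", "), x$organs,
    x$n_strips, x$per_strip, x$true_vertex, x$snr_db, x$seed))
  invisible(x)
}

#' Build the phantom volume conductor and candidate-source surface
#'
#' Deterministically generates the meshes of a [phantom_spec()]
#' (subdivided-icosphere ellipsoids), places the strip montage, and
#' checks containment: heart strictly inside the torso, organs inside
#' the torso, pairwise disjoint, and not intersecting the
#' candidate-source surface region.
#'
#' @param spec a [phantom_spec()].
#' @return list with `conductor` (a [volume_conductor()]) and `heart`
#'   (a [tri_mesh()] of candidate source positions).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  torso <- ellipsoid_mesh(spec$torso_center, spec$torso_semi_axes,
                          spec$refine_torso, name = "torso")
  heart <- ellipsoid_mesh(spec$heart_center, spec$heart_semi_axes,
                          spec$refine_heart, name = "heart")
  if (!all(points_inside(torso, heart$vertices)))
    stop("containment violation: heart not strictly inside torso")

  surfaces <- list(torso)
  sT <- spec$sigma_torso
  sigma_in <- sT; sigma_out <- 0
  if (spec$organs == "lungs+cavities") {
    lungs <- list(
      ellipsoid_mesh(c(-80, -20, 80), c(40, 45, 110), spec$refine_organs,
                     name = "lung_right"),
      ellipsoid_mesh(c(80, -20, 80), c(40, 45, 110), spec$refine_organs,
                     name = "lung_left"))
    cavities <- list(
      ellipsoid_mesh(spec$heart_center + c(-12, 0, 0), c(10, 18, 22),
                     spec$refine_organs, name = "cavity_right"),
      ellipsoid_mesh(spec$heart_center + c(12, 0, 0), c(10, 18, 22),
                     spec$refine_organs, name = "cavity_left"))
    organs <- c(lungs, cavities)
    for (a in seq_along(organs)) {
      if (!all(points_inside(torso, organs[[a]]$vertices)))
        stop("containment violation: organ ", organs[[a]]$name,
             " not inside torso")
      for (b in seq_along(organs)) {
        if (a == b) next
        samp <- unique(round(seq(1L, nrow(organs[[b]]$vertices),
                                 length.out = 16L)))
        if (any(points_inside(organs[[a]],
                              organs[[b]]$vertices[samp, , drop = FALSE])))
          stop("containment violation: ", organs[[b]]$name,
               " intersects ", organs[[a]]$name)
      }
    }
    for (lg in lungs)
      if (any(points_inside(lg, heart$vertices)))
        stop("containment violation: heart surface intersects ", lg$name)
    surfaces <- c(surfaces, organs)
    sigma_in <- c(sT, rep(spec$ratio_lungs * sT, 2L),
                  rep(spec$ratio_cavities * sT, 2L))
    sigma_out <- c(0, rep(sT, 4L))
  }
  montage <- electrode_strips(torso, spec$n_strips, spec$per_strip,
                              spec$z_range)
  vc <- volume_conductor(surfaces, sigma_in, sigma_out, montage,
                         check = FALSE)
  list(conductor = vc, heart = heart)
}

#' Simulate a noisy ectopic-beat potential map with known ground truth
#'
#' Forward-computes the clean map of a ramping fixed-direction dipole
#' at the spec's true vertex through the phantom's BEM transfer matrix,
#' then adds zero-mean Gaussian noise scaled to the requested global
#' SNR.  The noise draw is governed by `spec$seed`; the clean component
#' is seed-independent.
#'
#' @param vc a [volume_conductor()] from [make_phantom()].
#' @param heart the candidate-source [tri_mesh()].
#' @param spec the [phantom_spec()].
#' @param stack optional precomputed [transfer_stack()] for `vc` and
#'   `heart` (avoids re-assembling the BEM system).
#' @return list: `map` (a [bsp_map()]), `truth` (length-3 mm),
#'   `moments` (3 x T, mA mm).
#' @export
simulate_pvc_map <- function(vc, heart, spec, stack = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  J <- nrow(heart$vertices)
  if (spec$true_vertex < 1L || spec$true_vertex > J)
    stop("invalid true_vertex: must be in 1..", J)
  block <- if (!is.null(stack)) stack$blocks[[spec$true_vertex]] else
    transfer_matrix(vc, heart$vertices[spec$true_vertex, ])

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(list = ".Random.seed",
                                   envir = globalenv())))
  set.seed(spec$direction_seed)
  u <- stats::rnorm(3L)
  u <- u / sqrt(sum(u^2))
  mags <- spec$moment_peak * seq_len(spec$n_samples) / spec$n_samples
  moments <- outer(u, mags)

  clean <- block %*% moments
  if (is.infinite(spec$snr_db)) {
    noisy <- clean
  } else {
    sig_pow <- mean(clean^2)
    noise_sd <- sqrt(sig_pow / 10^(spec$snr_db / 10))
    if (!is.finite(noise_sd) || noise_sd <= 0)
      stop("non-positive noise scaling from snr_db = ", spec$snr_db)
    set.seed(spec$seed)
    noisy <- clean + matrix(stats::rnorm(length(clean), sd = noise_sd),
                            nrow(clean))
  }
  list(map = bsp_map(noisy, sample_rate = spec$sample_rate,
                     electrode_labels = vc$montage$labels),
       truth = heart$vertices[spec$true_vertex, ],
       moments = moments)
}

#' Read / write a phantom spec as YAML
#'
#' @param spec a [phantom_spec()].
#' @param path YAML file path.
#' @return `path` (write) or a [phantom_spec()] (read).
#' @export
write_phantom_spec <- function(spec, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for YAML phantom specs")
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required for YAML phantom specs")
  vals <- yaml::read_yaml(path)
  if (is.null(vals$snr_db)) vals$snr_db <- Inf
  if (is.character(vals$snr_db)) vals$snr_db <- as.numeric(vals$snr_db)
  do.call(phantom_spec, vals)
}
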