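#' Least-squares dipole fit at a fixed position
#'
#' Fits dipole moments at one candidate position by the Moore-Penrose
#' pseudoinverse of its transfer block, sample by sample, and scores the
#' fit with the relative residual error
#' `RRE(t) = ||Phi_B(,t) - Phi_C(,t)|| / ||Phi_B(,t)||`, where
#' `Phi_C = T %*% moments` is the map predicted by the fitted dipole.
#' Both the block and the map are re-referenced to a zero-mean common
#' reference over the electrodes used before fitting, so the fit is
#' independent of the recording reference.
#'
#' The pseudoinverse uses an SVD with singular values below
#' `1e-12 * sigma1` treated as zero; transfer blocks are 3-column and in
#' practice well conditioned, so the cutoff only guards degenerate
#' geometries (a rank-deficient block raises a warning recorded in the
#' result).
#'
#' @param block M x 3 transfer matrix.
#' @param map a [bsp_map()] or M x T matrix.
#' @return list with `moments` (3 x T), `rre` (length T), and
#'   `rank_deficient` flag.
#' @export
dipole_lsq <- function(block, map) {
  pot <- if (inherits(map, "bsp_map")) map$potentials else as.matrix(map)
  block <- as.matrix(block)
  if (nrow(pot) != nrow(block))
    stop("map has ", nrow(pot), " rows but block has ", nrow(block))
  B <- rereference(block)
  P <- rereference(pot)
  nrm <- sqrt(colSums(P^2))
  if (any(nrm == 0))
    stop("undefined RRE: zero-norm map column at sample ",
         which(nrm == 0)[1L])
  sv <- svd(B)
  keep <- sv$d > 1e-12 * sv$d[1L]
  rank_deficient <- !all(keep)
  if (rank_deficient)
    warning("rank-deficient transfer block: sigma3 below pinv cutoff")
  dinv <- ifelse(keep, 1 / sv$d, 0)
  moments <- sv$v %*% (dinv * (t(sv$u) %*% P))
  resid <- P - B %*% moments
  rre <- sqrt(colSums(resid^2)) / nrm
  list(moments = moments, rre = rre, rank_deficient = rank_deficient)
}

#' Single-dipole inverse solution by candidate-position scanning
#'
#' The first-step inverse solution: fits a dipole at every candidate
#' position of a transfer stack (one per ventricular-surface vertex) via
#' [dipole_lsq()] and selects the position/time pair with the globally
#' minimal relative residual error.  Ties are broken deterministically
#' (smallest sample index, then smallest position index).
#'
#' @param stack a [transfer_stack()].
#' @param map a [bsp_map()] (or M x T matrix) with one row per stack
#'   electrode.
#' @param electrodes optional integer subset of electrode (row) indices
#'   to use; both the blocks and the map are restricted and
#'   re-referenced over this subset (used by the second-step solution).
#' @param truth optional length-3 ground-truth position (mm); when
#'   supplied the Euclidean localization error is stored.
#' @return An object of class `dipole_fit` with components
#'   `position_index`, `position`, `moments` (3 x T at the winning
#'   position), `rre_min`, `rre_curve`, `t_star`, `rre_by_position`
#'   (per-candidate minimum RRE), `flatness` (5th percentile / median of
#'   `rre_by_position`), `le` (mm, if `truth` given), plus the fitting
#'   inputs needed by its methods.
#' @seealso [two_step()], [greedy_order()]
#' @export
fit_dipole <- function(stack, map, electrodes = NULL, truth = NULL) {
  if (!inherits(stack, "transfer_stack")) stop("stack must be a transfer_stack")
  pot <- if (inherits(map, "bsp_map")) map$potentials else as.matrix(map)
  sample_rate <- if (inherits(map, "bsp_map")) map$sample_rate else 1000
  J <- length(stack$blocks)
  if (J == 0L) stop("empty transfer stack")
  M_full <- nrow(stack$blocks[[1L]])
  if (nrow(pot) != M_full)
    stop("map has ", nrow(pot), " rows but stack electrodes are ", M_full)
  if (is.null(electrodes)) electrodes <- seq_len(M_full)
  electrodes <- as.integer(electrodes)
  if (anyDuplicated(electrodes) || any(electrodes < 1L | electrodes > M_full))
    stop("invalid electrode subset")
  pot <- pot[electrodes, , drop = FALSE]

  best <- list(rre = Inf, t = Inf, j = Inf)
  rre_by_position <- numeric(J)
  warn_rank <- FALSE
  for (j in seq_len(J)) {
    fit <- withCallingHandlers(
      dipole_lsq(stack$blocks[[j]][electrodes, , drop = FALSE], pot),
      warning = function(w) {
        warn_rank <<- TRUE
        invokeRestart("muffleWarning")
      })
    tj <- which.min(fit$rre)            # smallest t among equal minima
    rj <- fit$rre[tj]
    rre_by_position[j] <- rj
    if (rj < best$rre ||
        (rj == best$rre && (tj < best$t || (tj == best$t && j < best$j)))) {
      best <- list(rre = rj, t = tj, j = j, fit = fit)
    }
  }
  if (warn_rank)
    warning("one or more transfer blocks were rank deficient during the scan")

  j_star <- best$j
  out <- structure(list(
    position_index = j_star,
    position = stack$positions[j_star, ],
    moments = best$fit$moments,
    rre_min = best$rre,
    rre_curve = best$fit$rre,
    t_star = best$t,
    rre_by_position = rre_by_position,
    flatness = unname(stats::quantile(rre_by_position, 0.05) /
                        stats::median(rre_by_position)),
    electrodes = electrodes,
    n_electrodes = length(electrodes),
    sample_rate = sample_rate,
    block = stack$blocks[[j_star]][electrodes, , drop = FALSE],
    map = pot,
    truth = truth,
    le = if (is.null(truth)) NULL else
      localization_error(stack$positions[j_star, ], truth),
    rank_deficient = warn_rank),
    class = "dipole_fit")
  out
}

#' Euclidean localization error
#'
#' Distance in mm between an estimated and a ground-truth source
#' position.
#'
#' @param estimated,truth length-3 positions (mm).
#' @return distance in mm.
#' @export
localization_error <- function(estimated, truth) {
  estimated <- as.numeric(estimated); truth <- as.numeric(truth)
  if (length(estimated) != 3L || length(truth) != 3L ||
      any(!is.finite(c(estimated, truth))))
    stop("positions must be finite length-3 coordinates")
  sqrt(sum((estimated - truth)^2))
}

#' Export a dipole solution report as JSON
#'
#' @param fit a [fit_dipole()] result.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_solution <- function(fit, path) {
  rep <- list(position_index = fit$position_index,
              position = as.numeric(fit$position),
              rre_min = fit$rre_min,
              t_star = fit$t_star,
              n_electrodes = fit$n_electrodes,
              flatness = fit$flatness)
  if (!is.null(fit$le)) rep$localization_error_mm <- fit$le
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
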