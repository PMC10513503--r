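#' @export
print.dipole_fit <- function(x, digits = 4L, ...) {
  cat("Single-dipole inverse solution\n")
  cat(sprintf("  position index : %d\n", x$position_index))
  cat(sprintf("  position (mm)  : %s\n",
              paste(formatC(x$position, digits = digits, format = "g"),
                    collapse = ", ")))
  cat(sprintf("  min RRE        : %.4g (sample %d of %d)\n",
              x$rre_min, x$t_star, length(x$rre_curve)))
  cat(sprintf("  electrodes     : %d\n", x$n_electrodes))
  if (!is.null(x$le))
    cat(sprintf("  localization error : %.2f mm\n", x$le))
  invisible(x)
}

#' @export
summary.dipole_fit <- function(object, ...) {
  rbp <- object$rre_by_position
  s <- list(
    position_index = object$position_index,
    position = object$position,
    rre_min = object$rre_min,
    t_star = object$t_star,
    n_electrodes = object$n_electrodes,
    n_positions = length(rbp),
    rre_quartiles = stats::quantile(rbp, c(0, .25, .5, .75, 1)),
    flatness = object$flatness,
    moment_magnitude = sqrt(colSums(object$moments^2)),
    le = object$le,
    rank_deficient = object$rank_deficient)
  class(s) <- "summary.dipole_fit"
  s
}

#' @export
print.summary.dipole_fit <- function(x, ...) {
  cat("Single-dipole inverse solution (candidate scan)\n\n")
  cat(sprintf("Winning position %d of %d candidates, using %d electrodes\n",
              x$position_index, x$n_positions, x$n_electrodes))
  cat(sprintf("  coordinates (mm): %s\n",
              paste(formatC(x$position, digits = 4, format = "g"),
                    collapse = ", ")))
  cat(sprintf("  min RRE %.4g at sample %d\n", x$rre_min, x$t_star))
  cat("\nRRE over candidate positions:\n")
  print(signif(x$rre_quartiles, 4))
  cat(sprintf("RRE-surface flatness (p5/median): %.3f\n", x$flatness))
  if (!is.null(x$le))
    cat(sprintf("\nLocalization error vs ground truth: %.2f mm\n", x$le))
  if (x$rank_deficient)
    cat("\nNote: rank-deficient transfer block(s) encountered.\n")
  invisible(x)
}

#' Fitted dipole moment trajectory
#'
#' @param object a [fit_dipole()] result.
#' @param ... unused.
#' @return 3 x T matrix of moments (mA mm) at the winning position.
#' @export
coef.dipole_fit <- function(object, ...) object$moments

#' @export
fitted.dipole_fit <- function(object, ...) {
  rereference(object$block) %*% object$moments
}

#' @export
residuals.dipole_fit <- function(object, ...) {
  rereference(object$map) - fitted(object)
}

#' Predict electrode potentials from a fitted dipole
#'
#' Forward-computes the map produced at the fitted position by a moment
#' trajectory (default: the fitted moments).
#'
#' @param object a [fit_dipole()] result.
#' @param moments optional 3 x T moment trajectory (mA mm).
#' @param ... unused.
#' @return matrix of predicted potentials (electrodes x samples, in the
#'   zero-mean common reference of the fit).
#' @export
predict.dipole_fit <- function(object, moments = NULL, ...) {
  if (is.null(moments)) moments <- object$moments
  rereference(object$block) %*% as.matrix(moments)
}

#' Simulate maps from a fitted dipole
#'
#' Draws noisy replicates of the map predicted by the fitted dipole,
#' with Gaussian noise whose standard deviation matches the residual
#' root-mean-square of the fit.
#'
#' @param object a [fit_dipole()] result.
#' @param nsim number of replicates.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list of `nsim` [bsp_map()] objects.
#' @export
simulate.dipole_fit <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  clean <- fitted(object)
  sd_noise <- sqrt(mean(residuals(object)^2))
  lapply(seq_len(nsim), function(i)
    bsp_map(clean + matrix(stats::rnorm(length(clean), sd = sd_noise),
                           nrow(clean)),
            sample_rate = object$sample_rate))
}

#' Diagnostic plot of a dipole fit
#'
#' Left: minimum RRE per candidate position (the RRE surface the scan
#' minimizes, winner marked).  Right: RRE over time at the winning
#' position.
#'
#' @param x a [fit_dipole()] result.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.dipole_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$rre_by_position, type = "h", xlab = "candidate position",
       ylab = "min RRE", main = "RRE over candidates", ...)
  graphics::points(x$position_index, x$rre_min, col = 2, pch = 19)
  tms <- (seq_along(x$rre_curve) - 1L) / x$sample_rate * 1000
  plot(tms, x$rre_curve, type = "b", xlab = "time (ms)", ylab = "RRE",
       main = "RRE at winning position", ...)
  graphics::points(tms[x$t_star], x$rre_min, col = 2, pch = 19)
  invisible(x)
}
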