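#' Two-step inverse solution with significance-ranked electrode subsets
#'
#' Orchestrates the full pipeline: (1) a first inverse solution using
#' all electrodes ([fit_dipole()]); (2) greedy significance ranking of
#' the electrodes ([greedy_order()]) computed on the transfer block of
#' the first solution's position, per criterion; (3) second inverse
#' solutions restricted to the `k` most significant electrodes for each
#' requested `k` (the candidate set is the full ventricular surface,
#' re-scanned); (4) localization errors against ground truth when
#' supplied.
#'
#' Reduced-electrode fits re-reference both the map and the transfer
#' rows to zero mean over the retained subset.  An RRE-surface flatness
#' metric (5th percentile / median of the per-position RRE) is attached
#' to each k; values near 1 flag the small-k regime where no clear RRE
#' minimum exists and the solution is unreliable.
#'
#' @param stack a [transfer_stack()].
#' @param map a [bsp_map()] conforming to the stack.
#' @param criteria character vector from `c("A", "B", "C")`.
#' @param truth optional length-3 ground-truth position (mm).
#' @param k_values electrode counts for the second step; default every
#'   k from 4 to M.
#' @param k_report subset of `k_values` summarized in `deltas`
#'   (default 32, 64 and M, intersected with `k_values`).
#' @return Object of class `two_step`: `first` (the full-montage
#'   [fit_dipole()]), `orders` (per-criterion [greedy_order()]),
#'   `le_by_k` (data frame: criterion, k, position_index, rre_min,
#'   flatness, le), `le_all`, `deltas` (LE(k) - LE(all) at `k_report`),
#'   `truth`.
#' @export
two_step <- function(stack, map, criteria = c("A", "B", "C"),
                     truth = NULL, k_values = NULL, k_report = NULL) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  M <- nrow(stack$blocks[[1L]])
  if (is.null(k_values)) k_values <- 4:M
  k_values <- sort(unique(as.integer(k_values)))
  if (any(k_values < 4L | k_values > M))
    stop("k_values must lie in [4, M]")
  if (is.null(k_report)) k_report <- intersect(c(32L, 64L, M), k_values)

  first <- fit_dipole(stack, map, truth = truth)
  block_star <- stack$blocks[[first$position_index]]

  orders <- lapply(criteria, function(cr) greedy_order(block_star, cr))
  names(orders) <- criteria

  rows <- list()
  for (cr in criteria) {
    ord <- orders[[cr]]$order
    for (k in k_values) {
      f <- fit_dipole(stack, map, electrodes = sort(ord[seq_len(k)]),
                      truth = truth)
      rows[[length(rows) + 1L]] <- data.frame(
        criterion = cr, k = k,
        position_index = f$position_index,
        rre_min = f$rre_min, flatness = f$flatness,
        le = if (is.null(truth)) NA_real_ else f$le)
    }
  }
  le_by_k <- do.call(rbind, rows)
  le_all <- first$le

  deltas <- NULL
  if (!is.null(truth) && length(k_report)) {
    deltas <- le_by_k[le_by_k$k %in% k_report, c("criterion", "k", "le")]
    deltas$delta <- deltas$le - le_all
    rownames(deltas) <- NULL
  }
  structure(list(first = first, orders = orders, le_by_k = le_by_k,
                 le_all = le_all, deltas = deltas, truth = truth,
                 k_values = k_values, M = M),
            class = "two_step")
}

#' @export
print.two_step <- function(x, digits = 3L, ...) {
  cat(sprintf("Two-step inverse solution (M = %d electrodes)\n", x$M))
  cat(sprintf("  first solution: position %d, min RRE %.4g\n",
              x$first$position_index, x$first$rre_min))
  if (!is.null(x$le_all))
    cat(sprintf("  LE (all electrodes): %.2f mm\n", x$le_all))
  if (!is.null(x$deltas)) {
    cat("  second solutions (delta = LE(k) - LE(all), mm):\n")
    d <- x$deltas
    for (i in seq_len(nrow(d)))
      cat(sprintf("    criterion %s, k = %3d: LE %6.2f  delta %+.2f\n",
                  d$criterion[i], d$k[i], d$le[i], d$delta[i]))
  }
  invisible(x)
}

#' @export
summary.two_step <- function(object, ...) {
  agg <- stats::aggregate(cbind(rre_min, flatness) ~ criterion,
                          object$le_by_k, stats::median)
  s <- list(M = object$M, first = summary(object$first),
            le_all = object$le_all, deltas = object$deltas,
            median_by_criterion = agg)
  class(s) <- "summary.two_step"
  s
}

#' @export
print.summary.two_step <- function(x, ...) {
  print(x$first)
  cat("\nMedian over k of min RRE and RRE flatness, per criterion:\n")
  print(x$median_by_criterion)
  if (!is.null(x$deltas)) {
    cat("\nReduced-electrode localization (mm):\n")
    print(x$deltas, row.names = FALSE)
  }
  invisible(x)
}

#' Localization error versus electrode count
#'
#' Plots LE (or min RRE when no truth is known) against the number of
#' significance-ranked electrodes used, one line per criterion.
#'
#' @param x a [two_step()] result.
#' @param ... passed to [matplot()].
#' @return `x`, invisibly.
#' @export
plot.two_step <- function(x, ...) {
  d <- x$le_by_k
  ycol <- if (all(is.na(d$le))) "rre_min" else "le"
  wide <- stats::reshape(d[, c("criterion", "k", ycol)],
                         idvar = "k", timevar = "criterion",
                         direction = "wide")
  ks <- wide$k
  graphics::matplot(ks, as.matrix(wide[, -1L, drop = FALSE]), type = "b",
                    pch = 1, lty = 1,
                    xlab = "electrodes used (greedy order)",
                    ylab = if (ycol == "le") "localization error (mm)"
                           else "min RRE", ...)
  if (ycol == "le" && !is.null(x$le_all))
    graphics::abline(h = x$le_all, lty = 2)
  graphics::legend("topright", legend = sub("^[a-z_]+\\.", "",
                                            names(wide)[-1L]),
                   col = seq_len(ncol(wide) - 1L), lty = 1, bty = "n")
  invisible(x)
}

#' Summarize localization errors over repeated pipeline runs
#'
#' Aggregates a list of [two_step()] results (all with ground truth):
#' per criterion and electrode count, the mean and SD of LE, the mean
#' difference to the full-montage LE, and the number of cases improved
#' (negative delta), worsened (positive) or unchanged.
#'
#' @param results list of `two_step` objects carrying LE.
#' @param k_values electrode counts to summarize (default: those in
#'   `deltas`).
#' @param tol absolute tolerance below which a delta counts as "no
#'   change" (mm).
#' @return data frame: criterion, k, n, mean_le, sd_le, mean_delta,
#'   improved, worsened, unchanged.
#' @export
summarize_le <- function(results, k_values = NULL, tol = 1e-9) {
  if (!length(results)) stop("empty result list")
  if (any(vapply(results, function(r) is.null(r$truth), logical(1L))))
    stop("all results must carry ground-truth localization errors")
  tabs <- lapply(results, function(r) {
    d <- r$le_by_k
    d$delta <- d$le - r$le_all
    d
  })
  all_d <- do.call(rbind, tabs)
  if (is.null(k_values)) k_values <- unique(results[[1L]]$deltas$k)
  all_d <- all_d[all_d$k %in% k_values, ]
  out <- do.call(rbind, lapply(split(all_d, list(all_d$criterion, all_d$k),
                                     drop = TRUE), function(g) {
    data.frame(criterion = g$criterion[1L], k = g$k[1L], n = nrow(g),
               mean_le = mean(g$le), sd_le = stats::sd(g$le),
               mean_delta = mean(g$delta),
               improved = sum(g$delta < -tol),
               worsened = sum(g$delta > tol),
               unchanged = sum(abs(g$delta) <= tol))
  }))
  out <- out[order(out$criterion, out$k), ]
  rownames(out) <- NULL
  out
}
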