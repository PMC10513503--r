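#' Electrode-significance criteria
#'
#' Three scalar criteria on the singular values `sigma1 >= sigma2 >=
#' sigma3` of an electrode-subset transfer matrix:
#'
#' * `"A"` — condition number `sigma1 / sigma3`, to be **minimized**
#'   (least distortion of the dipole-to-electrode mapping);
#' * `"B"` — product `sigma1 * sigma2 * sigma3`, to be **maximized**
#'   (volume of the image of the unit moment ball);
#' * `"C"` — nuclear norm `sigma1 + sigma2 + sigma3`, to be
#'   **maximized** (total represented variation).
#'
#' `criterion_sense()` returns `"min"` or `"max"`.  When `sigma3 <
#' 1e-12 * sigma1` criterion A receives a `+Inf` sentinel (worst
#' possible) so the ordering stays total on degenerate subsets.
#'
#' @param svals length-3 numeric, descending singular values.
#' @param criterion `"A"`, `"B"` or `"C"`.
#' @return `criterion_score()`: scalar score; `criterion_sense()`:
#'   `"min"` or `"max"`.
#' @export
criterion_score <- function(svals, criterion = c("A", "B", "C")) {
  criterion <- match.arg(criterion)
  stopifnot(length(svals) == 3L, all(is.finite(svals)),
            svals[1L] >= svals[2L], svals[2L] >= svals[3L], svals[3L] >= 0)
  switch(criterion,
         A = if (svals[3L] < 1e-12 * svals[1L] || svals[1L] == 0) Inf
             else svals[1L] / svals[3L],
         B = svals[1L] * svals[2L] * svals[3L],
         C = sum(svals))
}

#' @rdname criterion_score
#' @export
criterion_sense <- function(criterion = c("A", "B", "C")) {
  criterion <- match.arg(criterion)
  if (criterion == "A") "min" else "max"
}

crit_int <- function(criterion) match(criterion, c("A", "B", "C"))

#' Singular values of an electrode-subset transfer matrix
#'
#' The three singular values (descending) of the row subset of an
#' M x 3 transfer block.  Two routes are available: direct SVD, or
#' square roots of the eigenvalues of the 3 x 3 Gram matrix
#' `t(Ts) %*% Ts` (the fast path used by the exhaustive and greedy
#' searches); the two agree to high relative accuracy on non-degenerate
#' subsets, which the test suite asserts.
#'
#' @param block M x 3 transfer matrix.
#' @param subset integer electrode (row) indices, at least 3, distinct.
#' @param method `"gram"` or `"svd"`.
#' @return length-3 numeric, descending.
#' @export
subset_singular_values <- function(block, subset,
                                   method = c("gram", "svd")) {
  method <- match.arg(method)
  block <- as.matrix(block)
  subset <- as.integer(subset)
  if (length(subset) < 3L) stop("subset must contain at least 3 electrodes")
  if (anyDuplicated(subset) || any(subset < 1L | subset > nrow(block)))
    stop("invalid electrode subset")
  Bs <- block[subset, , drop = FALSE]
  if (method == "svd") return(svd(Bs, nu = 0L, nv = 0L)$d)
  ev <- eigen(crossprod(Bs), symmetric = TRUE, only.values = TRUE)$values
  sqrt(pmax(ev, 0))
}

gram_svals <- function(G) {
  sqrt(pmax(eigen(G, symmetric = TRUE, only.values = TRUE)$values, 0))
}

#' Exhaustive search over all 4-electrode subsets
#'
#' Enumerates all `choose(M, 4)` quadruples of electrode rows and
#' returns the optimum of the chosen significance criterion (the
#' initialization of the greedy electrode ranking).  Ties resolve to
#' the lexicographically smallest index set.  With `keep_scores =
#' TRUE` the full score list (lexicographic enumeration order) is
#' retained for occurrence analysis.
#'
#' For M = 128 this enumerates 10,668,000 combinations.
#'
#' @param block M x 3 transfer matrix, `M >= 4`.
#' @param criterion `"A"`, `"B"` or `"C"` (see [criterion_score()]).
#' @param keep_scores retain the per-combination scores.
#' @return list of class `quad_search`: `subset` (4 indices), `score`,
#'   `n_combinations`, `criterion`, `M`, and `scores` when requested.
#' @export
best_quadruple <- function(block, criterion = c("A", "B", "C"),
                           keep_scores = FALSE) {
  criterion <- match.arg(criterion)
  block <- as.matrix(block)
  M <- nrow(block)
  if (M < 4L) stop("need at least 4 electrodes")
  G6 <- cpp_row_gram(block)
  minimize <- criterion_sense(criterion) == "min"
  out <- if (keep_scores) {
    scores <- cpp_quad_scores(G6, crit_int(criterion))
    b <- if (minimize) which.min(scores) else which.max(scores)
    list(subset = unrank_quadruple(b, M), score = scores[b],
         n_combinations = length(scores), scores = scores)
  } else {
    cpp_quad_best(G6, crit_int(criterion), minimize)
  }
  out$criterion <- criterion
  out$M <- M
  class(out) <- "quad_search"
  out
}

#' @export
print.quad_search <- function(x, ...) {
  cat(sprintf(
    "quad_search: criterion %s over %s combinations; best {%s} score %.6g\n",
    x$criterion, format(x$n_combinations, big.mark = ","),
    paste(x$subset, collapse = ","), x$score))
  invisible(x)
}

## lexicographic index (1-based) -> quadruple of 1-based electrode ids
unrank_quadruple <- function(idx, M) {
  idx <- idx - 1
  combo <- integer(4L)
  start <- 0L
  for (pos in 1:3) {
    i <- start
    repeat {
      rest <- choose(M - 1L - i, 4L - pos)
      if (idx < rest) break
      idx <- idx - rest
      i <- i + 1L
    }
    combo[pos] <- i
    start <- i + 1L
  }
  combo[4L] <- start + idx
  combo + 1L
}

#' Electrode occurrence in the top fraction of quadruples
#'
#' Ranks all 4-electrode combinations by their criterion score, keeps
#' the best `floor(fraction * choose(M, 4))`, and counts how often each
#' electrode appears among them (the occurrence analysis behind
#' top-1%-of-combinations maps).
#'
#' @param search a [best_quadruple()] result with `keep_scores = TRUE`.
#' @param fraction proportion of combinations to retain, in `(0, 1]`.
#' @return list: `counts` (length M), `n_retained`.
#' @export
top_occurrence <- function(search, fraction = 0.01) {
  stopifnot(inherits(search, "quad_search"))
  if (is.null(search$scores))
    stop("run best_quadruple() with keep_scores = TRUE first")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n_keep <- floor(fraction * length(search$scores))
  if (n_keep < 1L) stop("empty selection: fraction too small")
  res <- cpp_top_occurrence(search$scores, search$M, n_keep,
                            criterion_sense(search$criterion) == "min")
  list(counts = as.integer(res$counts), n_retained = res$n_retained)
}

#' Greedy significance ordering of electrodes
#'
#' Ranks all M electrodes of a transfer block in descending
#' significance for one criterion: the seed is the exhaustive best
#' 4-subset ([best_quadruple()]); each subsequent step adds the single
#' remaining electrode that best improves (or least degrades) the
#' criterion at that step, until all electrodes are used.  Scores are
#' evaluated on the 3 x 3 Gram matrix with rank-1 row updates.
#' Augmentation ties resolve to the smallest electrode index.
#'
#' Adding a row can never decrease a singular value, so criterion B and
#' C score sequences are non-decreasing along the greedy path; this is
#' asserted on every run.
#'
#' @param block M x 3 transfer matrix, `M >= 4`.
#' @param criterion `"A"`, `"B"` or `"C"`.
#' @return object of class `greedy_order`: `order` (permutation of
#'   `1:M`, most significant first), `seed_set` (first 4), `scores`
#'   (criterion value after each step, length `M - 3`), `criterion`.
#' @export
greedy_order <- function(block, criterion = c("A", "B", "C")) {
  criterion <- match.arg(criterion)
  block <- as.matrix(block)
  M <- nrow(block)
  seed <- best_quadruple(block, criterion)
  sel <- as.integer(seed$subset)
  scores <- numeric(M - 3L)
  scores[1L] <- seed$score
  G <- crossprod(block[sel, , drop = FALSE])
  remaining <- setdiff(seq_len(M), sel)
  minimize <- criterion_sense(criterion) == "min"
  step <- 1L
  while (length(remaining)) {
    cand <- vapply(remaining, function(e) {
      criterion_score(gram_svals(G + tcrossprod(block[e, ])), criterion)
    }, numeric(1L))
    pick <- if (minimize) which.min(cand) else which.max(cand)
    e <- remaining[pick]
    G <- G + tcrossprod(block[e, ])
    sel <- c(sel, e)
    remaining <- remaining[-pick]
    step <- step + 1L
    scores[step] <- cand[pick]
  }
  if (criterion %in% c("B", "C")) {
    tol <- 1e-9 * max(abs(scores), 1)
    if (any(diff(scores) < -tol))
      stop("internal error: criterion ", criterion,
           " scores decreased along the greedy path")
  }
  structure(list(order = sel, seed_set = sel[1:4], scores = scores,
                 criterion = criterion),
            class = "greedy_order")
}

#' @export
print.greedy_order <- function(x, ...) {
  cat(sprintf("greedy_order (criterion %s): %d electrodes\n",
              x$criterion, length(x$order)))
  cat("  seed set:", paste(x$seed_set, collapse = ", "), "\n")
  cat(sprintf("  score %s from %.6g (4 el.) to %.6g (all)\n",
              if (criterion_sense(x$criterion) == "min") "path" else "rises",
              x$scores[1L], x$scores[length(x$scores)]))
  invisible(x)
}

#' Serialize a greedy order to CSV
#'
#' Columns: `rank`, `electrode`, `label`, `vertex_id`, `score` (the
#' criterion value when the electrode entered the selected set; the
#' four seed electrodes share the seed score).
#'
#' @param x a [greedy_order()].
#' @param path CSV path.
#' @param labels,vertex_ids optional per-electrode annotations.
#' @return `path`, invisibly.
#' @export
write_greedy_order <- function(x, path, labels = NULL, vertex_ids = NULL) {
  M <- length(x$order)
  step_score <- c(rep(x$scores[1L], 4L), x$scores[-1L])
  d <- data.frame(rank = seq_len(M), electrode = x$order,
                  label = if (is.null(labels)) NA else labels[x$order],
                  vertex_id = if (is.null(vertex_ids)) NA else
                    vertex_ids[x$order],
                  score = step_score)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
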