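test_that("subset singular values match constructed cases", {
  # rows 2*e1, e2, e3: singular values (2, 1, 1)
  blk <- rbind(c(2, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0))
  expect_equal(subset_singular_values(blk, 1:3), c(2, 1, 1),
               tolerance = 1e-12)
  expect_equal(subset_singular_values(blk, 1:3, method = "svd"),
               c(2, 1, 1), tolerance = 1e-12)

  # three identical rows are rank one
  blk1 <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  sv <- subset_singular_values(blk1, 1:3)
  expect_equal(sv[2:3], c(0, 0), tolerance = 1e-7)

  expect_error(subset_singular_values(blk, 1:2), "at least 3")
  expect_error(subset_singular_values(blk, c(1, 1, 2)), "invalid")
})

test_that("Gram fast path agrees with direct SVD on random subsets", {
  set.seed(10)
  max_dev <- 0
  for (i in 1:1000) {
    blk <- matrix(rnorm(16 * 3), 16L)
    subset <- sample(16L, sample(4:16, 1L))
    a <- subset_singular_values(blk, subset, method = "gram")
    b <- subset_singular_values(blk, subset, method = "svd")
    max_dev <- max(max_dev, abs(a - b) / b[1L])
  }
  expect_lt(max_dev, 1e-8)
})

test_that("criterion scores follow the three definitions", {
  expect_equal(criterion_score(c(1, 1, 1), "A"), 1)
  expect_equal(criterion_score(c(1, 1, 1), "B"), 1)
  expect_equal(criterion_score(c(1, 1, 1), "C"), 3)
  expect_equal(criterion_score(c(2, 1, 0), "A"), Inf)
  expect_equal(criterion_score(c(2, 1, 0), "B"), 0)
  expect_equal(criterion_score(c(2, 1, 0), "C"), 3)
  expect_equal(criterion_score(c(3, 2, 1), "A"), 3)
  expect_equal(criterion_score(c(3, 2, 1), "B"), 6)
  expect_equal(criterion_score(c(3, 2, 1), "C"), 6)
  expect_identical(criterion_sense("A"), "min")
  expect_identical(criterion_sense("B"), "max")
  expect_identical(criterion_sense("C"), "max")
})

test_that("exhaustive quadruple search matches a naive brute force", {
  # C(5,4) = 5 subsets
  blk5 <- rand_block(5L, seed = 20L)
  q <- best_quadruple(blk5, "B")
  expect_equal(q$n_combinations, 5)
  combos <- utils::combn(5L, 4L)
  scores <- apply(combos, 2L, function(s) svd_score(blk5, s, "B"))
  expect_equal(sort(q$subset), combos[, which.max(scores)])
  expect_equal(q$score, max(scores), tolerance = 1e-10)

  # M = 10, all criteria, against an SVD-only double loop
  blk <- rand_block(10L, seed = 21L)
  combos <- utils::combn(10L, 4L)
  for (cr in c("A", "B", "C")) {
    q <- best_quadruple(blk, cr)
    expect_equal(q$n_combinations, choose(10, 4))
    scores <- apply(combos, 2L, function(s) svd_score(blk, s, cr))
    pick <- if (cr == "A") which.min(scores) else which.max(scores)
    expect_equal(sort(q$subset), combos[, pick],
                 info = paste("criterion", cr))
    expect_equal(q$score, scores[pick], tolerance = 1e-8)
  }
})

test_that("top-fraction occurrence counting satisfies the combinatorial identities", {
  blk <- rand_block(10L, seed = 22L)
  q <- best_quadruple(blk, "C", keep_scores = TRUE)
  # fraction 1: every electrode appears in C(M-1, 3) subsets
  occ <- top_occurrence(q, 1)
  expect_equal(occ$n_retained, choose(10, 4))
  expect_equal(occ$counts, rep(choose(9, 3), 10L))
  # counts always sum to 4 x retained
  occ2 <- top_occurrence(q, 0.25)
  expect_equal(occ2$n_retained, floor(0.25 * choose(10, 4)))
  expect_equal(sum(occ2$counts), 4L * occ2$n_retained)
  # the retained set really is the best-scoring one
  ord <- order(q$scores, decreasing = TRUE)
  manual <- tabulate(utils::combn(10L, 4L)[, ord[seq_len(occ2$n_retained)]],
                     nbins = 10L)
  expect_equal(occ2$counts, manual)
  expect_error(top_occurrence(q, 0), "fraction")
})

test_that("greedy augmentation is locally optimal at every step", {
  for (cr in c("A", "B", "C")) {
    blk <- rand_block(12L, seed = 30L)
    go <- greedy_order(blk, cr)
    expect_equal(sort(go$order), 1:12)
    expect_equal(go$seed_set, go$order[1:4])
    expect_length(go$scores, 9L)
    # seed equals the exhaustive optimum
    expect_equal(sort(go$seed_set), sort(best_quadruple(blk, cr)$subset))
    # every augmentation step beats (or ties) all alternatives, by
    # independent SVD re-evaluation
    for (step in 5:12) {
      sel <- go$order[seq_len(step - 1L)]
      remaining <- setdiff(1:12, sel)
      cand <- vapply(remaining, function(e)
        svd_score(blk, c(sel, e), cr), numeric(1L))
      chosen <- svd_score(blk, go$order[seq_len(step)], cr)
      if (cr == "A") {
        expect_lte(chosen, min(cand) + 1e-8 * abs(min(cand)))
      } else {
        expect_gte(chosen, max(cand) - 1e-8 * abs(max(cand)))
      }
    }
  }
})

test_that("criterion B and C scores are monotone along the greedy path", {
  for (seed in 31:33) {
    blk <- rand_block(14L, seed = seed)
    for (cr in c("B", "C")) {
      go <- greedy_order(blk, cr)
      expect_true(all(diff(go$scores) >= -1e-9 * max(go$scores)))
    }
    goA <- greedy_order(blk, "A")
    expect_true(all(goA$scores >= 1))
    # full-set score identical to direct computation
    for (cr in c("A", "B", "C")) {
      go <- greedy_order(blk, cr)
      direct <- criterion_score(subset_singular_values(blk, 1:14), cr)
      expect_equal(go$scores[length(go$scores)], direct,
                   tolerance = 1e-8)
    }
  }
})

test_that("an all-zero electrode row is ranked last under B and C", {
  blk <- rand_block(10L, seed = 40L)
  blk[6L, ] <- 0
  for (cr in c("B", "C")) {
    go <- greedy_order(blk, cr)
    expect_equal(go$order[10L], 6L)
  }
})

test_that("greedy order CSV export carries ranks and scores", {
  blk <- rand_block(8L, seed = 41L)
  go <- greedy_order(blk, "C")
  path <- withr::local_tempfile(fileext = ".csv")
  write_greedy_order(go, path, labels = sprintf("E%d", 1:8))
  d <- utils::read.csv(path)
  expect_equal(d$electrode, go$order)
  expect_equal(d$score[4:8], c(go$scores[1L], go$scores[2:5]))
})
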