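test_that("pseudoinverse fitting recovers exact forward data", {
  blk <- ref_phantom()$stack$blocks[[25L]]
  set.seed(1)
  m_true <- matrix(rnorm(3 * 30), 3L)
  fit <- dipole_lsq(blk, blk %*% m_true)
  expect_equal(fit$moments, m_true, tolerance = 1e-8)
  expect_true(all(fit$rre < 1e-10))
})

test_that("maps orthogonal to the block column space give RRE = 1", {
  set.seed(2)
  blk <- rand_block(16L, seed = 2L)
  Bref <- sweep(blk, 2L, colMeans(blk))
  y <- rnorm(16L); y <- y - mean(y)
  y_perp <- y - Bref %*% qr.solve(Bref, y)
  fit <- dipole_lsq(blk, cbind(y_perp))
  expect_equal(fit$rre, 1, tolerance = 1e-10)
})

test_that("fitting agrees with explicit normal-equations least squares", {
  set.seed(3)
  blk <- rand_block(8L, seed = 3L)
  pot <- matrix(rnorm(8 * 5), 8L)
  fit <- dipole_lsq(blk, pot)
  B <- sweep(blk, 2L, colMeans(blk))
  P <- sweep(pot, 2L, colMeans(pot))
  m_ne <- solve(crossprod(B), crossprod(B, P))
  rre_ne <- sqrt(colSums((P - B %*% m_ne)^2)) / sqrt(colSums(P^2))
  expect_equal(fit$moments, m_ne, tolerance = 1e-10)
  expect_equal(fit$rre, rre_ne, tolerance = 1e-10)
})

test_that("zero-norm map columns are reported by sample", {
  blk <- rand_block(6L)
  pot <- matrix(1, 6L, 3L)  # constant columns vanish after referencing
  expect_error(dipole_lsq(blk, pot), "sample 1")
})

test_that("position scanning matches a brute-force double loop", {
  set.seed(4)
  J <- 20L; M <- 16L; Tn <- 6L
  blocks <- lapply(seq_len(J), function(j) rand_block(M, seed = 100L + j))
  stk <- structure(list(positions = matrix(rnorm(J * 3), J),
                        blocks = blocks, labels = NULL,
                        conductor_id = "synthetic"),
                   class = "transfer_stack")
  pot <- matrix(rnorm(M * Tn), M)
  fit <- fit_dipole(stk, pot)

  # independent exhaustive recomputation over all (t, j)
  best <- c(Inf, NA, NA)
  for (j in seq_len(J)) {
    B <- sweep(blocks[[j]], 2L, colMeans(blocks[[j]]))
    P <- sweep(pot, 2L, colMeans(pot))
    rre <- sqrt(colSums((P - B %*% qr.solve(B, P))^2)) / sqrt(colSums(P^2))
    for (t in seq_len(Tn))
      if (rre[t] < best[1L]) best <- c(rre[t], t, j)
  }
  expect_equal(fit$position_index, best[3L])
  expect_equal(fit$t_star, best[2L])
  expect_equal(fit$rre_min, best[1L], tolerance = 1e-12)

  # J = 1 degenerate scan returns that position regardless of fit
  stk1 <- stk; stk1$positions <- stk$positions[1L, , drop = FALSE]
  stk1$blocks <- stk$blocks[1L]
  expect_equal(fit_dipole(stk1, pot)$position_index, 1L)
})

test_that("RRE lies in [0, 1] and is invariant to map rescaling", {
  set.seed(5)
  stk <- ref_phantom()$stack
  for (i in 1:5) {
    pot <- matrix(rnorm(128 * 10), 128L)
    fit <- fit_dipole(stk, pot)
    expect_true(all(fit$rre_by_position >= 0))
    expect_true(all(fit$rre_by_position <= 1 + 1e-12))
    fit2 <- fit_dipole(stk, 17.3 * pot)
    expect_equal(fit2$position_index, fit$position_index)
    expect_equal(fit2$rre_min, fit$rre_min, tolerance = 1e-12)
  }
})

test_that("localization error is a Euclidean metric in mm", {
  expect_equal(localization_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(localization_error(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(6)
  a <- rnorm(3L); b <- rnorm(3L)
  d0 <- localization_error(a, b)
  for (i in 1:100) {
    Q <- random_rotation()
    expect_equal(localization_error(Q %*% a, Q %*% b), d0,
                 tolerance = 1e-9)
  }
  expect_error(localization_error(c(1, 2), c(1, 2, 3)), "length-3")
})

test_that("electrode power is the squared RMS of each signal", {
  sig <- matrix(3, 4L, 10L)
  expect_equal(electrode_power(sig), rep(9, 4L))
  t <- seq(0, 2 * pi, length.out = 1001L)[-1001L]
  expect_equal(electrode_power(rbind(sin(t))), 0.5, tolerance = 1e-3)
  set.seed(7)
  x <- matrix(rnorm(40), 4L)
  expect_equal(electrode_power(2.5 * x), 2.5^2 * electrode_power(x))
})

test_that("dipole_fit methods are mutually consistent", {
  rp <- ref_phantom()
  spec <- phantom_spec(snr_db = 25, true_vertex = 77L, seed = 11L)
  sim <- simulate_pvc_map(rp$conductor, rp$heart, spec, stack = rp$stack)
  fit <- fit_dipole(rp$stack, sim$map, truth = sim$truth)
  expect_s3_class(fit, "dipole_fit")
  expect_identical(coef(fit), fit$moments)
  # fitted + residuals reconstruct the referenced map
  P <- sweep(sim$map$potentials, 2L, colMeans(sim$map$potentials))
  expect_equal(fitted(fit) + residuals(fit), P, tolerance = 1e-12)
  # rre_min is the minimum of the winning position's curve
  expect_equal(fit$rre_min, min(fit$rre_curve))
  expect_true(fit$rre_min >= 0 && fit$rre_min <= 1)
  expect_output(print(fit), "Single-dipole")
  expect_output(print(summary(fit)), "flatness")
  sims <- simulate(fit, nsim = 2L, seed = 1L)
  expect_length(sims, 2L)
  expect_equal(dim(sims[[1L]]$potentials), dim(sim$map$potentials))
  # JSON report
  path <- withr::local_tempfile(fileext = ".json")
  write_solution(fit, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$position_index, fit$position_index)
  expect_equal(rep$localization_error_mm, fit$le, tolerance = 1e-9)
})
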