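test_that("infinite-medium dipole potential has the analytic form", {
  pts <- matrix(rnorm(30), 10L)
  expect_equal(infinite_potential(c(0, 0, 0), c(0, 0, 0), pts, 0.2),
               rep(0, 10L))

  # points on the moment axis at distance d: +-|p| / (4 pi sigma d^2)
  d <- 7; p <- 3; sigma <- 0.4
  phi <- infinite_potential(c(0, 0, 0), c(0, 0, p),
                            rbind(c(0, 0, d), c(0, 0, -d)), sigma)
  expect_equal(phi, c(p, -p) / (4 * pi * sigma * d^2), tolerance = 1e-12)

  # doubling sigma halves every potential
  phi1 <- infinite_potential(c(1, 2, 3), c(1, -1, 2), pts + 10, sigma)
  phi2 <- infinite_potential(c(1, 2, 3), c(1, -1, 2), pts + 10, 2 * sigma)
  expect_equal(phi1, 2 * phi2, tolerance = 1e-12)

  expect_error(infinite_potential(c(0, 0, 0), c(1, 0, 0),
                                  rbind(c(0, 0, 0)), 0.2), "singular")
})

test_that("BEM matches the central-dipole sphere closed form", {
  sc <- sphere_conductor(2L)
  Tm <- transfer_matrix(sc$vc, c(0, 0, 0), system = sc$system)
  # zero-mean reference across all surface vertices
  expect_equal(colMeans(Tm), rep(0, 3L), tolerance = 1e-15)

  costh <- sc$mesh$vertices[, 3L] / sc$R
  phi_an <- 3 * costh / (4 * pi * sc$sigma * sc$R^2)
  phi_an <- phi_an - mean(phi_an)
  rel_rms <- sqrt(mean((Tm[, 3L] - phi_an)^2)) / sqrt(mean(phi_an^2))
  expect_lt(rel_rms, 0.05)
})

test_that("BEM matches the eccentric-dipole Legendre series", {
  sc <- sphere_conductor(2L)
  b <- 0.5 * sc$R
  Tm <- transfer_matrix(sc$vc, c(0, 0, b), system = sc$system)
  costh <- sc$mesh$vertices[, 3L] / sc$R
  # axial dipole at z = b in an insulated sphere:
  # phi(R, theta) = p / (4 pi sigma R^2) * sum (2n+1) (b/R)^(n-1) P_n
  nmax <- 60L
  P <- matrix(0, length(costh), nmax)
  P[, 1L] <- costh
  P[, 2L] <- (3 * costh^2 - 1) / 2
  for (k in 3:nmax)
    P[, k] <- ((2 * k - 1) * costh * P[, k - 1L] -
                 (k - 1) * P[, k - 2L]) / k
  coefs <- (2 * (1:nmax) + 1) * (b / sc$R)^(0:(nmax - 1L))
  phi_an <- as.numeric(P %*% coefs) / (4 * pi * sc$sigma * sc$R^2)
  phi_an <- phi_an - mean(phi_an)
  rel_rms <- sqrt(mean((Tm[, 3L] - phi_an)^2)) / sqrt(mean(phi_an^2))
  expect_lt(rel_rms, 0.05)
})

test_that("inner surfaces with conductivity ratio 1 reproduce the homogeneous solution", {
  sc <- sphere_conductor(2L)
  inner <- ellipsoid_mesh(c(10, 0, -5), c(30, 30, 30), 1L, "inner")
  vc2 <- volume_conductor(list(sc$mesh, inner),
                          sigma_in = c(sc$sigma, sc$sigma),
                          sigma_out = c(0, sc$sigma),
                          montage = sc$vc$montage)
  T_hom <- transfer_matrix(sc$vc, c(0, 0, 40), system = sc$system)
  T_inh <- transfer_matrix(vc2, c(0, 0, 40))
  expect_lt(norm(T_inh - T_hom, "F") / norm(T_hom, "F"), 1e-6)
})

test_that("transfer stacks have the contracted shapes and ordering", {
  sc <- sphere_conductor(2L)
  ids <- round(seq(1L, 162L, length.out = 32L))
  vc <- volume_conductor(list(sc$mesh), sc$sigma, 0, montage_of(ids))
  heart <- ellipsoid_mesh(c(0, 0, 0), c(20, 20, 20), 0L, "h12")
  stk <- transfer_stack(vc, heart, system = sc$system)
  expect_length(stk$blocks, 12L)
  expect_true(all(vapply(stk$blocks, function(b)
    identical(dim(b), c(32L, 3L)), logical(1L))))

  # full 128-electrode phantom block is 128 x 3
  rp <- ref_phantom()
  expect_identical(dim(rp$stack$blocks[[1L]]), c(128L, 3L))

  # permuting candidate vertex order permutes blocks identically
  perm <- rev(seq_len(nrow(heart$vertices)))
  heart2 <- heart
  heart2$vertices <- heart$vertices[perm, ]
  remap <- order(perm)
  heart2$triangles <- matrix(remap[heart$triangles],
                             ncol = 3L)
  stk2 <- transfer_stack(vc, heart2, system = sc$system)
  for (j in seq_along(perm))
    expect_equal(stk2$blocks[[j]], stk$blocks[[perm[j]]],
                 tolerance = 1e-12)

  # candidates outside the torso are rejected
  far <- heart
  far$vertices <- far$vertices * 10
  expect_error(transfer_stack(vc, far, system = sc$system), "outside")

  # every block has full column rank (sigma3 > 0)
  s3 <- vapply(rp$stack$blocks, function(b)
    min(svd(b, nu = 0, nv = 0)$d), numeric(1L))
  expect_true(all(s3 > 0))
})

test_that("forward maps are linear in the moments", {
  blk <- ref_phantom()$stack$blocks[[10L]]
  m1 <- matrix(rnorm(9), 3L); m2 <- matrix(rnorm(9), 3L)
  f <- function(m) forward_bsp(blk, m)$potentials
  expect_equal(f(2 * m1 - 3 * m2), 2 * f(m1) - 3 * f(m2),
               tolerance = 1e-12)
  expect_equal(f(matrix(0, 3L, 5L)), matrix(0, 128L, 5L))
  # identity moments probe the block columns
  expect_equal(f(diag(3)), blk, tolerance = 1e-15, ignore_attr = TRUE)
  expect_error(forward_bsp(blk, matrix(0, 2L, 3L)), "shape")
})

test_that("transfer stacks round-trip through CSV", {
  sc <- sphere_conductor(2L)
  ids <- c(1L, 5L, 9L, 20L, 50L, 100L)
  vc <- volume_conductor(list(sc$mesh), sc$sigma, 0, montage_of(ids))
  heart <- ellipsoid_mesh(c(0, 0, 0), c(15, 15, 15), 0L, "h")
  stk <- transfer_stack(vc, heart, system = sc$system)
  path <- withr::local_tempfile(fileext = ".csv")
  write_transfer_stack(stk, path)
  back <- read_transfer_stack(path)
  expect_equal(back$positions, unname(stk$positions), tolerance = 1e-12,
               ignore_attr = TRUE)
  for (j in seq_along(stk$blocks))
    expect_equal(back$blocks[[j]], unname(stk$blocks[[j]]),
                 tolerance = 1e-12)
})
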