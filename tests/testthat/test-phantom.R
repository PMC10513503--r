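test_that("phantom construction matches its specification", {
  rp <- ref_phantom()
  # refinement-3 torso: 642 vertices, 1280 triangles
  torso <- rp$conductor$surfaces[[1L]]
  expect_equal(nrow(torso$vertices), 642L)
  expect_equal(nrow(torso$triangles), 1280L)
  # homogeneous spec: a single surface
  expect_length(rp$conductor$surfaces, 1L)
  expect_length(rp$conductor$montage$vertex_ids, 128L)

  # inhomogeneous spec: torso + 2 lungs + 2 cavities, torso first
  spec <- phantom_spec(organs = "lungs+cavities", refine_torso = 2L,
                       refine_organs = 1L)
  ph <- make_phantom(spec)
  expect_length(ph$conductor$surfaces, 5L)
  expect_equal(ph$conductor$surfaces[[1L]]$name, "torso")
  expect_equal(ph$conductor$sigma_in,
               c(0.2, 0.05, 0.05, 0.6, 0.6))
  expect_equal(ph$conductor$sigma_out, c(0, 0.2, 0.2, 0.2, 0.2))

  # containment violations are caught geometrically
  bad <- phantom_spec(heart_semi_axes = c(200, 200, 200))
  expect_error(make_phantom(bad), "containment")
})

test_that("phantom generation is pure (same spec, identical meshes)", {
  spec <- phantom_spec()
  a <- make_phantom(spec)
  b <- make_phantom(spec)
  expect_identical(a$heart$vertices, b$heart$vertices)
  expect_identical(a$conductor$surfaces[[1L]]$triangles,
                   b$conductor$surfaces[[1L]]$triangles)
  expect_identical(a$conductor$montage$vertex_ids,
                   b$conductor$montage$vertex_ids)
})

test_that("simulated maps honor the seeding contract", {
  rp <- ref_phantom()
  spec_inf <- phantom_spec(snr_db = Inf, true_vertex = 50L)
  clean <- simulate_pvc_map(rp$conductor, rp$heart, spec_inf,
                            stack = rp$stack)
  # noise-free simulation equals the forward map exactly
  blk <- rp$stack$blocks[[50L]]
  expect_identical(clean$map$potentials, blk %*% clean$moments)
  expect_equal(clean$truth, rp$heart$vertices[50L, ], ignore_attr = TRUE)

  s1 <- phantom_spec(snr_db = 20, true_vertex = 50L, seed = 1L)
  s1b <- phantom_spec(snr_db = 20, true_vertex = 50L, seed = 1L)
  s2 <- phantom_spec(snr_db = 20, true_vertex = 50L, seed = 2L)
  m1 <- simulate_pvc_map(rp$conductor, rp$heart, s1, stack = rp$stack)
  m1b <- simulate_pvc_map(rp$conductor, rp$heart, s1b, stack = rp$stack)
  m2 <- simulate_pvc_map(rp$conductor, rp$heart, s2, stack = rp$stack)
  expect_identical(m1$map$potentials, m1b$map$potentials)
  expect_false(identical(m1$map$potentials, m2$map$potentials))
  # different seeds share the clean component
  expect_identical(m1$moments, m2$moments)
  n1 <- m1$map$potentials - clean$map$potentials
  n2 <- m2$map$potentials - clean$map$potentials
  expect_false(identical(n1, n2))

  expect_error(simulate_pvc_map(rp$conductor, rp$heart,
                                phantom_spec(true_vertex = 999L),
                                stack = rp$stack), "true_vertex")
})

test_that("realized SNR matches the requested level", {
  rp <- ref_phantom()
  spec_inf <- phantom_spec(snr_db = Inf, true_vertex = 10L)
  clean <- simulate_pvc_map(rp$conductor, rp$heart, spec_inf,
                            stack = rp$stack)$map$potentials
  sig_pow <- mean(clean^2)
  realized <- vapply(1:100, function(sd) {
    spec <- phantom_spec(snr_db = 20, true_vertex = 10L, seed = sd)
    noisy <- simulate_pvc_map(rp$conductor, rp$heart, spec,
                              stack = rp$stack)$map$potentials
    10 * log10(sig_pow / mean((noisy - clean)^2))
  }, numeric(1L))
  expect_lt(abs(mean(realized) - 20), 0.5)
})

test_that("noise-free maps are recovered exactly through the full loop", {
  rp <- ref_phantom()
  # sweep a spread of candidate vertices (the exhaustive sweep over all
  # vertices runs in the acceptance suite)
  for (tv in seq(1L, 162L, by = 23L)) {
    spec <- phantom_spec(snr_db = Inf, true_vertex = tv)
    sim <- simulate_pvc_map(rp$conductor, rp$heart, spec, stack = rp$stack)
    fit <- fit_dipole(rp$stack, sim$map, truth = sim$truth)
    expect_equal(fit$position_index, tv)
    expect_equal(fit$le, 0)
    expect_lt(fit$rre_min, 1e-10)
  }
})

test_that("recovery persists under moderate noise", {
  rp <- ref_phantom()
  hits <- vapply(1:20, function(sd) {
    spec <- phantom_spec(snr_db = 30, true_vertex = 88L, seed = sd)
    sim <- simulate_pvc_map(rp$conductor, rp$heart, spec, stack = rp$stack)
    fit_dipole(rp$stack, sim$map, truth = sim$truth)$le == 0
  }, logical(1L))
  expect_gte(mean(hits), 0.9)
})

test_that("phantom specs round-trip through YAML", {
  spec <- phantom_spec(snr_db = 15, seed = 42L, true_vertex = 7L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_phantom_spec(spec, path)
  back <- read_phantom_spec(path)
  expect_equal(back, spec)
  spec_inf <- phantom_spec(snr_db = Inf)
  write_phantom_spec(spec_inf, path)
  expect_equal(read_phantom_spec(path)$snr_db, Inf)
})
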