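# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# unit cube surface (12 triangles); vertex order as expand.grid(0:1,0:1,0:1)
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  tr <- rbind(c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
              c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
              c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  tri_mesh(v, tr, name = "cube")
}

montage_of <- function(vertex_ids) {
  structure(list(vertex_ids = as.integer(vertex_ids),
                 labels = sprintf("E%03d", seq_along(vertex_ids)),
                 strip_of = rep(1L, length(vertex_ids)),
                 level_of = seq_along(vertex_ids), nominal = NULL),
            class = "electrode_montage")
}

# homogeneous sphere conductor with electrodes at every vertex
sphere_conductor <- function(refine = 2L, R = 100, sigma = 0.2) {
  cached(sprintf("sphere_%d", refine), {
    sph <- ellipsoid_mesh(c(0, 0, 0), c(R, R, R), refine, "sphere")
    vc <- volume_conductor(list(sph), sigma, 0,
                           montage_of(seq_len(nrow(sph$vertices))))
    list(vc = vc, system = bem_system(vc), R = R, sigma = sigma,
         mesh = sph)
  })
}

# the reference homogeneous phantom: 128 electrodes, 162 candidates
ref_phantom <- function() {
  cached("ref_phantom", {
    spec <- phantom_spec(snr_db = Inf, true_vertex = 1L)
    ph <- make_phantom(spec)
    sys <- bem_system(ph$conductor)
    stk <- transfer_stack(ph$conductor, ph$heart, system = sys)
    list(spec = spec, conductor = ph$conductor, heart = ph$heart,
         system = sys, stack = stk)
  })
}

rand_block <- function(M, seed = 1L) {
  set.seed(seed)
  matrix(rnorm(M * 3L), M, 3L)
}

# independent slow-path criterion evaluation (direct SVD, no Gram)
svd_score <- function(block, subset, criterion) {
  sv <- svd(block[subset, , drop = FALSE], nu = 0, nv = 0)$d
  switch(criterion,
         A = if (sv[3] < 1e-12 * sv[1] || sv[1] == 0) Inf else sv[1] / sv[3],
         B = prod(sv),
         C = sum(sv))
}

random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9L), 3L))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}
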