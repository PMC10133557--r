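# Hexahedral element machinery, assembly, boundary conditions, recovery.

test_that("element stiffness matches an independent quadrature oracle", {
  h <- 1
  coords <- cdmbone:::hex_corner_offsets * h
  C <- isotropic_stiffness_oracle(200, 0.3)
  K <- element_stiffness(coords, C)
  expect_equal(K, hex8_stiffness_oracle(coords, C), tolerance = 1e-12)
  expect_equal(K, t(K))
  # anisotropic material too
  Ct <- stiffness_matrix(elastic_constants())
  expect_equal(element_stiffness(coords, Ct),
               hex8_stiffness_oracle(coords, Ct), tolerance = 1e-12)
})

test_that("element stiffness has exactly 6 rigid-body modes", {
  K <- element_stiffness(cdmbone:::hex_corner_offsets * 0.5,
                         stiffness_matrix(elastic_constants()))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_identical(sum(abs(ev) < max(ev) * 1e-10), 6L)
})

test_that("cube stiffness scales linearly with edge length", {
  C <- stiffness_matrix(elastic_constants())
  K1 <- element_stiffness(cdmbone:::hex_corner_offsets * 1.0, C)
  K2 <- element_stiffness(cdmbone:::hex_corner_offsets * 2.0, C)
  expect_equal(K2, 2 * K1, tolerance = 1e-12)
})

test_that("inverted elements are reported with their id", {
  coords <- cdmbone:::hex_corner_offsets * 1.0
  coords[, 3] <- -coords[, 3]   # flip -> negative Jacobian
  expect_error(element_stiffness(coords, diag(6), element_id = 17),
               "element 17")
})

test_that("single-cube frictionless compression gives the closed-form reaction", {
  mesh <- voxels_to_mesh(block_specimen(1, 1, 1, h = 1))
  bc <- boundary_conditions(top = "frictionless_platen",
                            applied_axial_displacement = -0.001)
  sol <- assemble_and_solve(mesh, elastic_constants(), bc)
  expect_equal(sol$reaction_top, 13498 * 1 * 0.001 / 1, tolerance = 1e-9)
  expect_equal(sol$reaction_bottom, sol$reaction_top, tolerance = 1e-9)
  expect_lt(sol$residual, 1e-10)
})

test_that("zero applied displacement gives zero response", {
  mesh <- voxels_to_mesh(block_specimen(2, 2, 2, h = 0.5))
  bc <- boundary_conditions(top = "stick_platen",
                            applied_axial_displacement = 0)
  sol <- assemble_and_solve(mesh, elastic_constants(), bc)
  expect_equal(max(abs(sol$u)), 0)
  expect_equal(sol$reaction_top, 0)
})

test_that("patch test: refined block matches the single element exactly", {
  d <- -0.001
  bc <- boundary_conditions(top = "frictionless_platen",
                            applied_axial_displacement = d)
  m1 <- voxels_to_mesh(block_specimen(1, 1, 1, h = 1))
  m8 <- voxels_to_mesh(block_specimen(2, 2, 2, h = 0.5))
  r1 <- assemble_and_solve(m1, elastic_constants(), bc)$reaction_top
  r8 <- assemble_and_solve(m8, elastic_constants(), bc)$reaction_top
  expect_equal(r8, r1, tolerance = 1e-10)
  # uniform strain reproduced in every element of the refined mesh
  sol <- assemble_and_solve(m8, elastic_constants(), bc)
  E <- recover_centroid_strains(m8, sol)
  expect_equal(unname(E[3, ]), rep(d / 1, 8), tolerance = 1e-10)
  expect_equal(unname(E[1, ]), rep(-0.3 * d, 8), tolerance = 1e-10)
})

test_that("centroid strain recovery is exact for linear displacement fields", {
  mesh <- voxels_to_mesh(block_specimen(3, 2, 2, h = 0.5))
  a <- 0.004
  u <- numeric(3 * nrow(mesh$nodes))
  u[seq(3, length(u), by = 3)] <- a * mesh$nodes[, 3]   # u_z = a z
  E <- recover_centroid_strains(mesh, u)
  expect_equal(unname(E[3, ]), rep(a, nrow(mesh$elements)), tolerance = 1e-12)
  expect_equal(max(abs(E[c(1, 2, 4, 5, 6), ])), 0)
})

test_that("small rigid rotations produce only second-order strains", {
  mesh <- voxels_to_mesh(block_specimen(2, 2, 2, h = 1))
  th <- 1e-5
  u <- numeric(3 * nrow(mesh$nodes))
  u[seq(1, length(u), by = 3)] <- -th * mesh$nodes[, 2]
  u[seq(2, length(u), by = 3)] <- th * mesh$nodes[, 1]
  E <- recover_centroid_strains(mesh, u)
  expect_lt(max(abs(E)), th^2)
})

test_that("recovered strains match finite differences of the interpolant", {
  mesh <- voxels_to_mesh(block_specimen(2, 1, 1, h = 0.5))
  set.seed(8)
  u <- rnorm(3 * nrow(mesh$nodes), 0, 1e-3)
  E <- recover_centroid_strains(mesh, u)
  # finite-difference gradient of the trilinear interpolant at a centroid
  interp <- function(x, elem) {
    nodes <- mesh$nodes[mesh$elements[elem, ], ]
    xi <- 2 * (x - nodes[1, ]) / mesh$spacing - 1
    g <- cdmbone:::hex_natural_corners
    N <- (1 + g[, 1] * xi[1]) * (1 + g[, 2] * xi[2]) * (1 + g[, 3] * xi[3]) / 8
    Ue <- t(vapply(mesh$elements[elem, ],
                   function(n) u[(3 * n - 2):(3 * n)], numeric(3)))  # 8 x 3
    as.vector(N %*% Ue)
  }
  h <- 1e-6
  for (elem in 1:2) {
    centroid <- colMeans(mesh$nodes[mesh$elements[elem, ], ])
    G <- matrix(0, 3, 3)
    for (j in 1:3) {
      dx <- numeric(3); dx[j] <- h
      G[, j] <- (interp(centroid + dx, elem) - interp(centroid - dx, elem)) /
        (2 * h)
    }
    sym <- (G + t(G)) / 2
    expect_equal(unname(E[, elem]),
                 c(sym[1, 1], sym[2, 2], sym[3, 3],
                   sym[1, 2], sym[1, 3], sym[2, 3]), tolerance = 1e-6)
  }
})

test_that("top and bottom reactions balance on an irregular specimen", {
  mesh <- test_tube_mesh(voxel_size = 0.25)
  bc <- boundary_conditions(top = "stick_platen",
                            applied_axial_displacement = -0.01)
  sol <- assemble_and_solve(mesh, elastic_constants(), bc)
  expect_equal(sol$reaction_top, sol$reaction_bottom,
               tolerance = 1e-8)
})

test_that("frictionless tube compression matches the closed-form stiffness", {
  # prismatic voxel tube: uniform uniaxial stress, reaction = E_L A_net d / h
  spec <- generate_hollow_cylinder(voxel_size = 0.25, eccentricity = 0,
                                   thickness_noise_sd = 0, seed = 1)
  mesh <- voxels_to_mesh(spec)
  d <- 0.005
  bc <- boundary_conditions(top = "frictionless_platen",
                            applied_axial_displacement = -d)
  sol <- assemble_and_solve(mesh, elastic_constants(), bc)
  A_net <- sum(spec$occupancy[, , 1]) * spec$spacing^2
  h <- dim(spec$occupancy)[3] * spec$spacing
  expect_equal(sol$reaction_top, 13498 * A_net * d / h, tolerance = 0.005)
})
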