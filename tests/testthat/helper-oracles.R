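# Independent oracles and small fixtures used across the test files.
# These deliberately avoid the package's own code paths: the hex stiffness
# oracle integrates with a different quadrature and its own B-matrix code,
# the eigenvalue oracle uses polynomial root finding, etc.

# closed-form isotropic stiffness, Voigt (11,22,33,12,13,23), engineering shear
isotropic_stiffness_oracle <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  C <- matrix(0, 6, 6)
  C[1:3, 1:3] <- lam
  diag(C)[1:3] <- lam + 2 * mu
  diag(C)[4:6] <- mu
  C
}

# hex8 element stiffness by 3x3x3 Gauss with independently written
# shape-function handling (scalar loops, no shared helpers)
hex8_stiffness_oracle <- function(coords, C) {
  signs <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1,  -1, 1, -1,
                    -1, -1,  1,  1, -1,  1,  1, 1,  1,  -1, 1,  1),
                  ncol = 3, byrow = TRUE)
  g <- c(-sqrt(3 / 5), 0, sqrt(3 / 5))
  w <- c(5 / 9, 8 / 9, 5 / 9)
  K <- matrix(0, 24, 24)
  for (a in 1:3) for (b in 1:3) for (cq in 1:3) {
    xi <- c(g[a], g[b], g[cq])
    dN <- matrix(0, 8, 3)
    for (n in 1:8) {
      s <- signs[n, ]
      dN[n, 1] <- s[1] * (1 + s[2] * xi[2]) * (1 + s[3] * xi[3]) / 8
      dN[n, 2] <- s[2] * (1 + s[1] * xi[1]) * (1 + s[3] * xi[3]) / 8
      dN[n, 3] <- s[3] * (1 + s[1] * xi[1]) * (1 + s[2] * xi[2]) / 8
    }
    J <- t(dN) %*% coords
    dNdx <- dN %*% solve(J)
    B <- matrix(0, 6, 24)
    for (n in 1:8) {
      cc <- 3 * (n - 1)
      B[1, cc + 1] <- dNdx[n, 1]
      B[2, cc + 2] <- dNdx[n, 2]
      B[3, cc + 3] <- dNdx[n, 3]
      B[4, cc + 1] <- dNdx[n, 2]; B[4, cc + 2] <- dNdx[n, 1]
      B[5, cc + 1] <- dNdx[n, 3]; B[5, cc + 3] <- dNdx[n, 1]
      B[6, cc + 2] <- dNdx[n, 3]; B[6, cc + 3] <- dNdx[n, 2]
    }
    K <- K + w[a] * w[b] * w[cq] * t(B) %*% C %*% B * det(J)
  }
  K
}

# eigenvalues of a symmetric 3x3 matrix via its characteristic polynomial
eig3_poly_oracle <- function(A) {
  c2 <- -sum(diag(A))
  c1 <- A[1, 1] * A[2, 2] + A[1, 1] * A[3, 3] + A[2, 2] * A[3, 3] -
    A[1, 2]^2 - A[1, 3]^2 - A[2, 3]^2
  c0 <- -det(A)
  sort(Re(polyroot(c(c0, c1, c2, 1))))
}

# random symmetric strain tensor with entries of magnitude ~ scale
random_strain <- function(scale = 0.05) {
  v <- stats::rnorm(6, 0, scale)
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

# random 3x3 rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# solid block specimen: nx x ny x nz voxels of edge h
block_specimen <- function(nx, ny, nz, h = 1) {
  voxel_specimen(array(TRUE, c(nx, ny, nz)), h)
}

# small tube fixture shared by the slower solver/fracture tests
test_tube_mesh <- function(voxel_size = 0.25, eccentricity = 0.25,
                           thickness_noise_sd = 0.03, seed = 1) {
  voxels_to_mesh(generate_hollow_cylinder(
    voxel_size = voxel_size, eccentricity = eccentricity,
    thickness_noise_sd = thickness_noise_sd, seed = seed))
}

# single-element ramp driver used by the damage-threshold checks:
# unit cube, frictionless platens, displacement ramp in `step`-strain
# increments up to `total` strain
single_element_ramp <- function(criterion, total = 0.2, step = 0.001,
                                law = damage_law()) {
  mesh <- voxels_to_mesh(block_specimen(1, 1, 1, h = 1))
  cfg <- simulation_config(total_displacement = total,
                           n_increments = round(total / step),
                           criterion = criterion,
                           load_drop_fraction = NULL,
                           percolation_check = FALSE,
                           bisection_fraction = 1)  # keep the nominal steps
  run_compression(mesh, elastic_constants(), law, criterion, cfg,
                  boundary_conditions(top = "frictionless_platen"))
}
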