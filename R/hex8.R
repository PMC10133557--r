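# Trilinear 8-node hexahedron (C3D8-style): shape functions, full 2x2x2
# Gauss stiffness, and the centroid strain-displacement operator.
#
# Local corner order follows the VTK hexahedron convention used by
# voxels_to_mesh(); degrees of freedom are node-major (ux, uy, uz per node).

# natural corner coordinates (8 x 3), matching hex_corner_offsets
hex_natural_corners <- 2 * hex_corner_offsets - 1

# dN/dxi at a natural point: 8 x 3 matrix
hex_shape_derivs <- function(xi) {
  g <- hex_natural_corners
  cbind(
    g[, 1] * (1 + g[, 2] * xi[2]) * (1 + g[, 3] * xi[3]) / 8,
    g[, 2] * (1 + g[, 1] * xi[1]) * (1 + g[, 3] * xi[3]) / 8,
    g[, 3] * (1 + g[, 1] * xi[1]) * (1 + g[, 2] * xi[2]) / 8)
}

# strain-displacement matrix (6 x 24, engineering Voigt 11,22,33,12,13,23)
# from physical shape-function gradients dNdx (8 x 3)
hex_B_from_grads <- function(dNdx) {
  B <- matrix(0, 6, 24)
  for (a in 1:8) {
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- dNdx[a, 1]
    B[2, c0 + 2] <- dNdx[a, 2]
    B[3, c0 + 3] <- dNdx[a, 3]
    B[4, c0 + 1] <- dNdx[a, 2]; B[4, c0 + 2] <- dNdx[a, 1]
    B[5, c0 + 1] <- dNdx[a, 3]; B[5, c0 + 3] <- dNdx[a, 1]
    B[6, c0 + 2] <- dNdx[a, 3]; B[6, c0 + 3] <- dNdx[a, 2]
  }
  B
}

#' Element stiffness of an 8-node hexahedron
#'
#' Full 2x2x2 Gauss integration of `B' C B` over the element.  Degrees of
#' freedom are node-major (`ux, uy, uz` for node 1, then node 2, ...).
#'
#' @param node_coords 8 x 3 matrix of corner coordinates, mm, in the mesh's
#'   hexahedron corner order.
#' @param secant_matrix 6 x 6 stiffness (MPa) acting on engineering-Voigt
#'   strain, order (11, 22, 33, 12, 13, 23).
#' @param element_id Optional id used in error messages.
#' @return Symmetric 24 x 24 matrix, N/mm.
#' @export
element_stiffness <- function(node_coords, secant_matrix, element_id = NULL) {
  stopifnot(is.matrix(node_coords), nrow(node_coords) == 8)
  gp <- 1 / sqrt(3)
  pts <- as.matrix(expand.grid(c(-gp, gp), c(-gp, gp), c(-gp, gp)))
  K <- matrix(0, 24, 24)
  for (q in seq_len(nrow(pts))) {
    dNdxi <- hex_shape_derivs(pts[q, ])
    J <- t(dNdxi) %*% node_coords          # 3 x 3
    detJ <- det(J)
    if (detJ <= 0) {
      stop("inverted or degenerate hexahedron",
           if (!is.null(element_id)) paste0(" (element ", element_id, ")"),
           ": Jacobian determinant ", signif(detJ, 4), call. = FALSE)
    }
    dNdx <- dNdxi %*% solve(J)
    B <- hex_B_from_grads(dNdx)
    K <- K + t(B) %*% secant_matrix %*% B * detJ
  }
  (K + t(K)) / 2
}

#' Centroid strain-displacement operator for a cube element
#'
#' For the axis-aligned cubic elements of a voxel mesh the operator is
#' identical for every element.  Returns the 6 x 24 matrix mapping the
#' element displacement vector to the engineering-Voigt strain at the
#' element centroid.
#'
#' @param h Element edge length, mm.
#' @return 6 x 24 matrix.
#' @export
hex_centroid_B <- function(h) {
  dNdxi <- hex_shape_derivs(c(0, 0, 0))
  hex_B_from_grads(dNdxi * (2 / h))   # J = (h/2) I for an axis-aligned cube
}
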