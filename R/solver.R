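# Global assembly, platen boundary conditions and sparse solution.
#
# The rigid platens of the physical test are modelled by nodal constraints:
# the bottom platen is frictionless (axial displacement fixed, lateral free),
# the top platen either sticks (lateral fixed -- the default stand-in for the
# penalty-friction contact of the experiment, transmitting shear into the
# specimen) or is frictionless (for analytic verification).  When both
# platens are frictionless the in-plane rigid-body modes are removed by
# pinning two bottom nodes on a common lattice line, which is stress-free for
# the uniform uniaxial states those runs are used to verify.

#' Platen boundary conditions
#'
#' @param top `"stick_platen"` (axial displacement prescribed, lateral fixed;
#'   default) or `"frictionless_platen"` (lateral free).
#' @param bottom Only `"frictionless_platen"` is supported (axial fixed,
#'   lateral free).
#' @param applied_axial_displacement Axial displacement of the top platen in
#'   mm; negative = compression.
#' @return Object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(top = c("stick_platen", "frictionless_platen"),
                                bottom = "frictionless_platen",
                                applied_axial_displacement = -0.5) {
  top <- match.arg(top)
  bottom <- match.arg(bottom, "frictionless_platen")
  structure(list(top = top, bottom = bottom,
                 applied_axial_displacement = applied_axial_displacement),
            class = "boundary_conditions")
}

# constrained dofs for a mesh: list(dofs, unit_values)
# prescribed displacements scale linearly with the load factor lambda in
# [0, 1]; fixed-zero dofs stay zero at any lambda.
bc_constraints <- function(mesh, bcs) {
  topn <- mesh$node_sets$top_surface
  botn <- mesh$node_sets$bottom_surface
  dof <- function(nodes, dir) 3L * (nodes - 1L) + dir
  cons <- dof(botn, 3L)
  vals <- rep(0, length(botn))
  cons <- c(cons, dof(topn, 3L))
  vals <- c(vals, rep(bcs$applied_axial_displacement, length(topn)))
  if (bcs$top == "stick_platen") {
    cons <- c(cons, dof(topn, 1L), dof(topn, 2L))
    vals <- c(vals, rep(0, 2 * length(topn)))
  } else {
    # frictionless top and bottom: pin in-plane rigid modes at the bottom.
    # Node A fixes both lateral translations; node B, chosen on the same
    # y-lattice line, fixes the rotation about the loading axis.  For a
    # uniform lateral-expansion field centred at A these pins carry no load.
    xy <- mesh$nodes[botn, 1:2, drop = FALSE]
    A <- which.min(xy[, 1] + 1e-9 * xy[, 2])
    same_y <- which(abs(xy[, 2] - xy[A, 2]) < mesh$spacing * 1e-9)
    same_y <- setdiff(same_y, A)
    if (length(same_y) == 0) {
      stop("cannot pin in-plane rigid modes: no second bottom node on the ",
           "pin line", call. = FALSE)
    }
    B <- same_y[which.max(abs(xy[same_y, 1] - xy[A, 1]))]
    cons <- c(cons, dof(botn[A], 1L), dof(botn[A], 2L), dof(botn[B], 2L))
    vals <- c(vals, 0, 0, 0)
  }
  o <- order(cons)
  list(dofs = cons[o], unit_values = vals[o])
}

#' Precompute the linear-system machinery for repeated damage solves
#'
#' All elements of a voxel mesh are congruent cubes, and the damaged secant
#' stiffness of every element is a scalar multiple `f_e` of the undamaged
#' element stiffness `K0`.  This routine builds, once: the sparsity pattern
#' of the constrained global stiffness, a sparse map `M` such that the
#' nonzero values of `K(f)` are `M %*% f`, the analogous map for the
#' prescribed-displacement load vector, and a Cholesky symbolic factorisation
#' that later solves update numerically.
#'
#' @param mesh A [voxels_to_mesh()] mesh.
#' @param constants [elastic_constants()].
#' @param bcs [boundary_conditions()].
#' @param material_axis Coordinate carrying the longitudinal (osteon)
#'   material axis; `"z"` (the loading axis) unless a transverse loading
#'   configuration is being measured.
#' @return Object of class `fe_system`.
#' @export
fe_system <- function(mesh, constants, bcs, material_axis = "z") {
  nel <- nrow(mesh$elements)
  nnode <- nrow(mesh$nodes)
  ndof <- 3L * nnode
  h <- mesh$spacing
  C <- stiffness_matrix(constants, axis = material_axis)
  cube <- hex_corner_offsets * h
  K0 <- element_stiffness(cube, C)

  # element dof table (24 x nel)
  Ed <- matrix(0L, 24, nel)
  for (a in 1:8) {
    Ed[3 * a - 2, ] <- 3L * (mesh$elements[, a] - 1L) + 1L
    Ed[3 * a - 1, ] <- 3L * (mesh$elements[, a] - 1L) + 2L
    Ed[3 * a, ]     <- 3L * (mesh$elements[, a] - 1L) + 3L
  }

  cc <- bc_constraints(mesh, bcs)
  is_cons <- rep(FALSE, ndof)
  is_cons[cc$dofs] <- TRUE
  free <- which(!is_cons)
  nf <- length(free)
  free_idx <- integer(ndof); free_idx[free] <- seq_len(nf)
  cons_val <- numeric(ndof); cons_val[cc$dofs] <- cc$unit_values

  iiloc <- rep(1:24, times = 24)
  jjloc <- rep(1:24, each = 24)
  k0v <- as.vector(K0)
  I <- Ed[iiloc, , drop = FALSE]          # 576 x nel
  J <- Ed[jjloc, , drop = FALSE]
  Iv <- as.vector(I); Jv <- as.vector(J)
  vals <- rep(k0v, nel)
  eid <- rep(seq_len(nel), each = 576L)

  ff <- !is_cons[Iv] & !is_cons[Jv]
  fc <- !is_cons[Iv] & is_cons[Jv]

  i_f <- free_idx[Iv[ff]]; j_f <- free_idx[Jv[ff]]
  Kff <- Matrix::sparseMatrix(i = i_f, j = j_f, x = vals[ff],
                              dims = c(nf, nf))
  # map each (i, j, value) triplet to its slot in Kff@x
  pcol <- rep(seq_len(nf), diff(Kff@p))
  pkey <- (as.numeric(pcol) - 1) * nf + (Kff@i + 1)
  tkey <- (as.numeric(j_f) - 1) * nf + i_f
  slot <- match(tkey, pkey)
  Mff <- Matrix::sparseMatrix(i = slot, j = eid[ff], x = vals[ff],
                              dims = c(length(Kff@x), nel))

  # load map: rhs(f, lambda) = lambda * (Mfc %*% f)
  bvals <- -vals[fc] * cons_val[Jv[fc]]
  keep <- bvals != 0
  Mfc <- Matrix::sparseMatrix(i = free_idx[Iv[fc]][keep],
                              j = eid[fc][keep], x = bvals[keep],
                              dims = c(nf, nel))

  Kff@x <- as.numeric(Mff %*% rep(1, nel))
  Ksym <- Matrix::forceSymmetric(Kff, "U")
  chol0 <- Matrix::Cholesky(Ksym, LDL = FALSE, perm = TRUE, super = TRUE)

  dofz <- function(nodes) 3L * (nodes - 1L)
  top_z <- dofz(mesh$node_sets$top_surface) + 3L
  bot_z <- dofz(mesh$node_sets$bottom_surface) + 3L
  mask_top <- matrix(Ed %in% top_z, 24, nel)
  mask_bot <- matrix(Ed %in% bot_z, 24, nel)

  structure(list(mesh = mesh, constants = constants, bcs = bcs,
                 K0 = K0, Ed = Ed, free = free, nf = nf,
                 cons_dofs = cc$dofs, cons_unit = cc$unit_values,
                 cons_val_full = cons_val,
                 Kff = Kff, Mff = Mff, Mfc = Mfc, chol = chol0,
                 mask_top = mask_top, mask_bot = mask_bot,
                 Bc = hex_centroid_B(h), ndof = ndof,
                 cache = new.env(parent = emptyenv())),
            class = "fe_system")
}

#' Solve the constrained system for given element stiffness factors
#'
#' @param sys An [fe_system()].
#' @param factors Per-element secant factors (each element's secant stiffness
#'   is `factor * C`); length nel, values in `(0, 1]` (failed elements carry
#'   the stiffness floor).
#' @param lambda Load factor scaling the prescribed platen displacement.
#' @return List with the full displacement vector `u` (mm), `reaction_top`
#'   and `reaction_bottom` (axial platen forces, N, positive in compression),
#'   and the relative equilibrium residual.
#' @export
solve_system <- function(sys, factors, lambda = 1) {
  stopifnot(length(factors) == ncol(sys$Mff))
  cache <- sys$cache
  if (!is.null(cache$factors) && identical(cache$factors, factors) &&
      !is.null(cache$lambda) && cache$lambda != 0) {
    # same secant field: the solution scales linearly with the load factor
    uf <- cache$uf * (lambda / cache$lambda)
    rel_res <- cache$rel_res
  } else {
    Kff <- sys$Kff
    Kff@x <- as.numeric(sys$Mff %*% factors)
    Ksym <- Matrix::forceSymmetric(Kff, "U")
    ch <- Matrix::update(sys$chol, Ksym)
    rhs <- lambda * as.numeric(sys$Mfc %*% factors)
    uf <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
    res <- as.numeric(Ksym %*% uf) - rhs
    scale <- max(sqrt(sum(rhs^2)), 1e-30)
    rel_res <- sqrt(sum(res^2)) / scale
    if (lambda != 0) {
      cache$factors <- factors
      cache$lambda <- lambda
      cache$uf <- uf
      cache$rel_res <- rel_res
    }
  }

  u <- numeric(sys$ndof)
  u[sys$free] <- uf
  u[sys$cons_dofs] <- lambda * sys$cons_unit

  # internal element forces: f_e * K0 %*% u_e, summed over platen dofs
  Ue <- matrix(u[sys$Ed], 24)
  Fe <- (sys$K0 %*% Ue) * rep(factors, each = 24)
  r_top <- sum(Fe[sys$mask_top])
  r_bot <- sum(Fe[sys$mask_bot])
  list(u = u, reaction_top = -r_top, reaction_bottom = r_bot,
       residual = rel_res)
}

#' Assemble and solve one linear equilibrium problem
#'
#' One-shot convenience wrapper: builds the system for the given per-element
#' secant description, solves, and checks the equilibrium residual.
#'
#' @param mesh A [voxels_to_mesh()] mesh.
#' @param secant Either a list with entries `constants`
#'   ([elastic_constants()]) and `factors` (per-element scalars, default all
#'   1), or `NULL` with `constants` given separately via `...` — every
#'   element's secant stiffness is `factor * C`.
#' @param bcs [boundary_conditions()].
#' @param material_axis Coordinate of the longitudinal material axis.
#' @return List with `u` (displacement vector, mm), `reaction_top`,
#'   `reaction_bottom` (N, positive compression) and `residual`.
#' @export
assemble_and_solve <- function(mesh, secant, bcs, material_axis = "z") {
  if (inherits(secant, "elastic_constants")) {
    secant <- list(constants = secant, factors = rep(1, nrow(mesh$elements)))
  }
  if (is.null(secant$factors)) secant$factors <- rep(1, nrow(mesh$elements))
  sys <- fe_system(mesh, secant$constants, bcs, material_axis = material_axis)
  out <- solve_system(sys, secant$factors, lambda = 1)
  if (!is.finite(out$residual) || out$residual > 1e-8) {
    stop("equilibrium residual ", signif(out$residual, 3),
         " exceeds tolerance: system nearly singular -- consider the ",
         "stiffness floor or isolated-voxel cleanup", call. = FALSE)
  }
  out
}

#' Recover element-centroid strain tensors
#'
#' Evaluates the symmetric gradient of the trilinear displacement interpolant
#' at each element centroid.
#'
#' @param mesh A [voxels_to_mesh()] mesh.
#' @param displacements Full displacement vector (3 dofs per node, mm), or
#'   the list returned by [solve_system()] / [assemble_and_solve()].
#' @return 6 x nel matrix of tensorial strain components, rows
#'   `e11, e22, e33, e12, e13, e23`.
#' @export
recover_centroid_strains <- function(mesh, displacements) {
  if (is.list(displacements)) displacements <- displacements$u
  nel <- nrow(mesh$elements)
  Ed <- matrix(0L, 24, nel)
  for (a in 1:8) {
    Ed[3 * a - 2, ] <- 3L * (mesh$elements[, a] - 1L) + 1L
    Ed[3 * a - 1, ] <- 3L * (mesh$elements[, a] - 1L) + 2L
    Ed[3 * a, ]     <- 3L * (mesh$elements[, a] - 1L) + 3L
  }
  E <- hex_centroid_B(mesh$spacing) %*% matrix(displacements[Ed], 24)
  E[4:6, ] <- E[4:6, ] / 2   # engineering gammas -> tensorial components
  rownames(E) <- c("e11", "e22", "e33", "e12", "e13", "e23")
  E
}
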