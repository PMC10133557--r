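# Synthetic voxel specimens and voxel-conforming hexahedral meshing.
#
# The k-axis of the occupancy grid is the loading axis and the longitudinal
# (osteon) material axis.  All voxels are cubes; node merging is exact
# (integer lattice arithmetic, no floating-point tolerance).

#' Voxel specimen container
#'
#' @param occupancy 3-D logical array `(i, j, k)`; `k` is the loading axis.
#' @param spacing Voxel edge length, mm (> 0, isotropic).
#' @param origin Coordinates of the node at lattice position `(1, 1, 1)`
#'   (i.e. the lower corner of voxel `(1, 1, 1)`), mm.
#' @return Object of class `voxel_specimen`.
#' @export
voxel_specimen <- function(occupancy, spacing, origin = c(0, 0, 0)) {
  if (!is.array(occupancy) || length(dim(occupancy)) != 3) {
    stop("occupancy must be a 3-D array", call. = FALSE)
  }
  storage.mode(occupancy) <- "logical"
  if (!(spacing > 0)) stop("spacing must be > 0", call. = FALSE)
  if (!any(occupancy)) stop("occupancy is empty: no occupied voxels", call. = FALSE)
  structure(list(occupancy = occupancy, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "voxel_specimen")
}

#' @export
print.voxel_specimen <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf(
    "Voxel specimen: %d occupied voxels on a %d x %d x %d grid, spacing %g mm\n",
    sum(x$occupancy), d[1], d[2], d[3], x$spacing))
  cat(sprintf("  extent: %g x %g x %g mm (k = loading / osteon axis)\n",
              d[1] * x$spacing, d[2] * x$spacing, d[3] * x$spacing))
  invisible(x)
}

# 26-connected component labelling by breadth-first flood fill.
# Returns integer array of labels (0 = background) and component sizes.
label_components_26 <- function(occ) {
  d <- dim(occ)
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(off != 0) > 0, , drop = FALSE]
  labels <- array(0L, d)
  todo <- which(occ)
  sizes <- integer(0)
  lab <- 0L
  remaining <- array(occ, d)
  while (length(todo) > 0) {
    lab <- lab + 1L
    seed <- todo[1]
    frontier <- seed
    remaining[seed] <- FALSE
    labels[seed] <- lab
    n <- 0L
    while (length(frontier) > 0) {
      n <- n + length(frontier)
      ijk <- arrayInd(frontier, d)
      nb <- ijk[rep(seq_len(nrow(ijk)), each = nrow(off)), , drop = FALSE] +
        off[rep(seq_len(nrow(off)), times = nrow(ijk)), , drop = FALSE]
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
        nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique(nb[, 1] + (nb[, 2] - 1L) * d[1] +
                      (nb[, 3] - 1L) * d[1] * d[2])
      lin <- lin[remaining[lin]]
      remaining[lin] <- FALSE
      labels[lin] <- lab
      frontier <- lin
    }
    sizes <- c(sizes, n)
    todo <- todo[remaining[todo]]
  }
  list(labels = labels, sizes = sizes)
}

# keep the largest 26-connected component; warn about discarded voxels
keep_largest_component <- function(occ, context = "specimen") {
  cc <- label_components_26(occ)
  if (length(cc$sizes) > 1) {
    keep <- which.max(cc$sizes)
    dropped <- sum(cc$sizes[-keep])
    warning(sprintf(
      "%s: %d voxel(s) outside the largest 26-connected component discarded (%d component(s))",
      context, dropped, length(cc$sizes)), call. = FALSE)
    occ <- cc$labels == keep
  }
  occ
}

#' Generate a synthetic hollow-cylinder cortical specimen
#'
#' Emulates a mid-diaphysis cortical bone segment (a hollow, roughly tubular
#' shell) as the stand-in for micro-CT derived geometry.  The medullary canal
#' may be offset from the outer centre (`eccentricity`, as a fraction of the
#' wall thickness, toward +x), and both surfaces may undulate smoothly: the
#' radius perturbations are low-order Fourier series in circumferential angle
#' and height whose coefficients are drawn once from `seed`, so the underlying
#' surface is independent of `voxel_size` and the same specimen can be meshed
#' at several resolutions for mesh-sensitivity studies.
#'
#' @param outer_diameter Outer diameter, mm.
#' @param wall_thickness Nominal cortical wall thickness, mm.
#' @param height Specimen height along the loading axis, mm.
#' @param voxel_size Cubic voxel edge, mm; must not exceed half the wall
#'   thickness (coarser grids cannot resolve the shell).
#' @param eccentricity Canal-centre offset as a fraction of `wall_thickness`.
#' @param thickness_noise_sd Standard deviation of the smooth surface
#'   undulation, mm (0 disables noise).
#' @param seed Integer seed controlling the surface perturbations.
#' @return A [voxel_specimen()]; a single 26-connected component.
#' @export
generate_hollow_cylinder <- function(outer_diameter = 3.5, wall_thickness = 0.5,
                                     height = 5.0, voxel_size = 0.08,
                                     eccentricity = 0.25,
                                     thickness_noise_sd = 0.03,
                                     seed = 1L) {
  if (!(outer_diameter > 2 * wall_thickness && wall_thickness > 0)) {
    stop("need outer_diameter > 2 * wall_thickness > 0", call. = FALSE)
  }
  if (!(height >= voxel_size)) stop("height must be >= voxel_size", call. = FALSE)
  if (voxel_size > wall_thickness / 2) {
    stop(sprintf(
      "voxel_size %g mm too coarse to resolve a %g mm wall (need <= %g mm)",
      voxel_size, wall_thickness, wall_thickness / 2), call. = FALSE)
  }
  if (!(eccentricity >= 0 && eccentricity < 1)) {
    stop("eccentricity must lie in [0, 1)", call. = FALSE)
  }

  R0 <- outer_diameter / 2
  r0 <- R0 - wall_thickness
  cx <- eccentricity * wall_thickness   # canal centre offset toward +x

  # Fourier surface perturbation: fixed number of coefficient draws so the
  # surface does not depend on the sampling grid
  modes <- expand.grid(m = 1:3, n = 0:2)
  nm <- nrow(modes)
  draw <- local({
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(as.integer(seed))
    list(a_out = rnorm(nm, 0, thickness_noise_sd * sqrt(2 / nm)),
         p_out = runif(nm, 0, 2 * pi), q_out = runif(nm, 0, 2 * pi),
         a_in = rnorm(nm, 0, thickness_noise_sd * sqrt(2 / nm)),
         p_in = runif(nm, 0, 2 * pi), q_in = runif(nm, 0, 2 * pi))
  })
  perturb <- function(theta, zn, a, p, q) {
    if (thickness_noise_sd == 0) return(rep(0, length(theta)))
    d <- rep(0, length(theta))
    for (r in seq_len(nm)) {
      d <- d + a[r] * cos(modes$m[r] * theta + p[r]) *
        cos(pi * modes$n[r] * zn + q[r])
    }
    d
  }

  half <- R0 + 3 * thickness_noise_sd + voxel_size
  nxy <- 2L * as.integer(ceiling(half / voxel_size))
  nk <- max(1L, as.integer(round(height / voxel_size)))
  xc <- (seq_len(nxy) - (nxy + 1) / 2) * voxel_size   # centred voxel centres
  zc <- (seq_len(nk) - 0.5) * voxel_size

  occ <- array(FALSE, c(nxy, nxy, nk))
  X <- matrix(xc, nxy, nxy)
  Y <- matrix(xc, nxy, nxy, byrow = TRUE)
  rho_out <- sqrt(X^2 + Y^2)
  th_out <- atan2(Y, X)
  rho_in <- sqrt((X - cx)^2 + Y^2)
  th_in <- atan2(Y, X - cx)
  for (k in seq_len(nk)) {
    zn <- zc[k] / height
    Rk <- R0 + perturb(as.vector(th_out), zn, draw$a_out, draw$p_out, draw$q_out)
    rk <- r0 + perturb(as.vector(th_in), zn, draw$a_in, draw$p_in, draw$q_in)
    occ[, , k] <- (as.vector(rho_out) <= Rk) & (as.vector(rho_in) >= rk)
  }
  if (!any(occ)) {
    stop("generated occupancy is empty; check geometry parameters", call. = FALSE)
  }
  occ <- keep_largest_component(occ, "generate_hollow_cylinder")
  # every k-slice must remain populated, otherwise the shell is unresolved
  per_slice <- apply(occ, 3, sum)
  if (any(per_slice == 0)) {
    stop("voxel_size too coarse: generated shell has empty layers", call. = FALSE)
  }
  origin <- c(xc[1] - voxel_size / 2, xc[1] - voxel_size / 2, 0)
  voxel_specimen(occ, voxel_size, origin)
}

# VTK hexahedron corner offsets in the node lattice (zeta along k)
hex_corner_offsets <- matrix(c(
  0L, 0L, 0L,
  1L, 0L, 0L,
  1L, 1L, 0L,
  0L, 1L, 0L,
  0L, 0L, 1L,
  1L, 0L, 1L,
  1L, 1L, 1L,
  0L, 1L, 1L), ncol = 3, byrow = TRUE)

#' Convert a voxel specimen to a conforming 8-node hexahedral mesh
#'
#' One hexahedral element per occupied voxel; corner nodes shared between
#' neighbouring voxels are merged exactly by integer lattice index, so shared
#' faces reference identical node indices with no tolerance ambiguity.
#'
#' @param spec A [voxel_specimen()].
#' @return Object of class `hex_mesh` with fields `nodes` (N x 3, mm),
#'   `elements` (nel x 8 node indices, VTK hexahedron ordering),
#'   `spacing`, `element_volume`, `node_sets` (`top_surface`,
#'   `bottom_surface`: nodes at the max/min k coordinate), `voxel_ijk`
#'   (element -> voxel map) and `face_neighbors` (nel x 6, NA where no
#'   face-adjacent element exists).
#' @export
voxels_to_mesh <- function(spec) {
  stopifnot(inherits(spec, "voxel_specimen"))
  d <- dim(spec$occupancy)
  lin <- which(spec$occupancy)
  ijk <- arrayInd(lin, d)
  nel <- length(lin)
  nd <- d + 1L  # node lattice dims

  # 8 corner node lattice indices per element
  corner_lin <- matrix(0, nel, 8)
  for (a in 1:8) {
    ci <- ijk[, 1] + hex_corner_offsets[a, 1]
    cj <- ijk[, 2] + hex_corner_offsets[a, 2]
    ck <- ijk[, 3] + hex_corner_offsets[a, 3]
    corner_lin[, a] <- ci + (cj - 1) * nd[1] + (ck - 1) * nd[1] * nd[2]
  }
  used <- sort(unique(as.vector(corner_lin)))
  elements <- matrix(match(corner_lin, used), nel, 8)

  nijk <- arrayInd(used, nd)
  nodes <- cbind(spec$origin[1] + (nijk[, 1] - 1) * spec$spacing,
                 spec$origin[2] + (nijk[, 2] - 1) * spec$spacing,
                 spec$origin[3] + (nijk[, 3] - 1) * spec$spacing)

  kmin <- min(nijk[, 3]); kmax <- max(nijk[, 3])
  node_sets <- list(bottom_surface = which(nijk[, 3] == kmin),
                    top_surface = which(nijk[, 3] == kmax))

  # face adjacency between elements via voxel lattice lookup
  vox_lin <- lin
  face_off <- matrix(c(-1L, 0L, 0L, 1L, 0L, 0L, 0L, -1L, 0L,
                       0L, 1L, 0L, 0L, 0L, -1L, 0L, 0L, 1L),
                     ncol = 3, byrow = TRUE)
  face_neighbors <- matrix(NA_integer_, nel, 6)
  for (f in 1:6) {
    ni <- ijk[, 1] + face_off[f, 1]
    nj <- ijk[, 2] + face_off[f, 2]
    nk <- ijk[, 3] + face_off[f, 3]
    ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
    key <- rep(NA_real_, nel)
    key[ok] <- ni[ok] + (nj[ok] - 1) * d[1] + (nk[ok] - 1) * d[1] * d[2]
    face_neighbors[, f] <- match(key, vox_lin)
  }

  structure(list(nodes = nodes, elements = elements,
                 spacing = spec$spacing,
                 element_volume = spec$spacing^3,
                 node_sets = node_sets,
                 voxel_ijk = ijk,
                 voxel_dims = d,
                 face_neighbors = face_neighbors,
                 origin = spec$origin),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("Hex mesh: %d C3D8-style elements, %d nodes, spacing %g mm\n",
              nrow(x$elements), nrow(x$nodes), x$spacing))
  cat(sprintf("  node sets: top_surface (%d), bottom_surface (%d)\n",
              length(x$node_sets$top_surface),
              length(x$node_sets$bottom_surface)))
  invisible(x)
}

#' Element centroids
#'
#' @param mesh A [voxels_to_mesh()] result.
#' @return nel x 3 matrix of element centroid coordinates, mm.
#' @export
element_centroids <- function(mesh) {
  sweep((mesh$voxel_ijk - 0.5) * mesh$spacing, 2, mesh$origin, "+")
}

#' Geometry content hash
#'
#' MD5 of the occupancy grid, spacing and origin; embedded in run summaries
#' to make runs self-describing.
#'
#' @param spec A [voxel_specimen()].
#' @return Character scalar.
#' @export
specimen_hash <- function(spec) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(list(dim = dim(spec$occupancy), occ = which(spec$occupancy),
               spacing = spec$spacing, origin = spec$origin),
          tf, version = 2)
  unname(tools::md5sum(tf))
}
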