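# Transversely isotropic elasticity in engineering constants.
#
# Voigt component order used throughout the package: (11, 22, 33, 12, 13, 23),
# with the longitudinal (osteon) material axis along the third (k / loading)
# coordinate by default.  Strain vectors at the stiffness-matrix boundary use
# engineering shear (gamma = 2 * eps_ij); strain *tensors* elsewhere are
# tensorial.

#' Transversely isotropic elastic constants for cortical bone
#'
#' Cortical bone is modelled as a transversely isotropic continuum whose stiff
#' axis follows the osteons (the longitudinal shaft direction).  The default
#' moduli are nanoindentation values for rat femoral cortical bone tissue:
#' longitudinal modulus 13,498 MPa, transverse modulus 11,025 MPa, Poisson's
#' ratio 0.3.  The remaining constants of a transversely isotropic solid are
#' not independently measured; by default `nu_TT = nu_LT` and
#' `G_LT = E_L / (2 * (1 + nu_LT))`, both overridable.
#'
#' @param E_L Longitudinal Young's modulus, MPa.
#' @param E_T Transverse Young's modulus, MPa.
#' @param nu_LT Longitudinal-transverse Poisson ratio (contraction transverse
#'   to the osteon axis under load along it).
#' @param nu_TT Transverse-transverse Poisson ratio.
#' @param G_LT Longitudinal shear modulus, MPa; `NULL` for the isotropic-style
#'   default `E_L / (2 * (1 + nu_LT))`.
#' @return An object of class `elastic_constants`.
#' @export
elastic_constants <- function(E_L = 13498, E_T = 11025,
                              nu_LT = 0.3, nu_TT = 0.3, G_LT = NULL) {
  if (is.null(G_LT)) G_LT <- E_L / (2 * (1 + nu_LT))
  ec <- structure(list(E_L = E_L, E_T = E_T, nu_LT = nu_LT,
                       nu_TT = nu_TT, G_LT = G_LT),
                  class = "elastic_constants")
  validate_elastic_constants(ec)
  ec
}

validate_elastic_constants <- function(ec) {
  bad <- character(0)
  if (!(ec$E_L > 0)) bad <- c(bad, "E_L must be > 0")
  if (!(ec$E_T > 0)) bad <- c(bad, "E_T must be > 0")
  if (!(ec$G_LT > 0)) bad <- c(bad, "G_LT must be > 0")
  for (nm in c("nu_LT", "nu_TT")) {
    v <- ec[[nm]]
    if (!(v > -1 && v < 0.5)) bad <- c(bad, paste0(nm, " must lie in (-1, 0.5)"))
  }
  if (length(bad)) stop("inadmissible elastic constants: ",
                        paste(bad, collapse = "; "), call. = FALSE)
  # thermodynamic admissibility: assembled stiffness must be SPD
  S <- compliance_matrix_raw(ec)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop("inadmissible elastic constants: assembled 6x6 stiffness is not ",
         "positive definite (compliance eigenvalues ",
         paste(signif(ev, 4), collapse = ", "), ")", call. = FALSE)
  }
  invisible(ec)
}

#' @export
print.elastic_constants <- function(x, ...) {
  cat("Transversely isotropic elastic constants (MPa):\n")
  cat(sprintf("  E_L = %g  E_T = %g  nu_LT = %g  nu_TT = %g  G_LT = %g\n",
              x$E_L, x$E_T, x$nu_LT, x$nu_TT, x$G_LT))
  invisible(x)
}

# 6x6 compliance, longitudinal axis along coordinate 3, Voigt (11,22,33,12,13,23)
compliance_matrix_raw <- function(ec) {
  S <- matrix(0, 6, 6)
  S[1, 1] <- S[2, 2] <- 1 / ec$E_T
  S[3, 3] <- 1 / ec$E_L
  S[1, 2] <- S[2, 1] <- -ec$nu_TT / ec$E_T
  S[1, 3] <- S[3, 1] <- S[2, 3] <- S[3, 2] <- -ec$nu_LT / ec$E_L
  S[4, 4] <- 2 * (1 + ec$nu_TT) / ec$E_T   # in-plane (transverse) shear
  S[5, 5] <- S[6, 6] <- 1 / ec$G_LT        # longitudinal-transverse shear
  S
}

#' Assemble the 6x6 stiffness matrix
#'
#' Voigt order (11, 22, 33, 12, 13, 23); maps engineering strain
#' `(e11, e22, e33, g12, g13, g23)` to stress in MPa.  The longitudinal
#' material axis lies along the coordinate named by `axis` (default `"z"`,
#' the loading axis of the voxel mesh).
#'
#' @param constants An [elastic_constants()] object.
#' @param axis Coordinate carrying the longitudinal (osteon) material axis.
#' @return Symmetric positive definite 6x6 matrix, MPa.
#' @export
stiffness_matrix <- function(constants, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  validate_elastic_constants(constants)
  C <- solve(compliance_matrix_raw(constants))
  C <- (C + t(C)) / 2
  perm <- switch(axis,
    z = 1:6,
    # swap coordinate labels 1<->3: 11<->33, 12<->23, 13 fixed
    x = c(3L, 2L, 1L, 6L, 5L, 4L),
    # swap coordinate labels 2<->3: 22<->33, 12<->13, 23 fixed
    y = c(1L, 3L, 2L, 5L, 4L, 6L))
  C[perm, perm]
}

# --- tensor <-> Voigt helpers (tensorial shear in the 3x3 form) ---

#' Convert a symmetric 3x3 strain tensor to its 6-vector form
#'
#' @param eps Symmetric 3x3 matrix (tensorial shear components).
#' @param engineering If `TRUE`, shear entries are doubled (engineering
#'   gammas, the convention the stiffness matrix expects).
#' @return Numeric length-6 vector, order (11, 22, 33, 12, 13, 23).
#' @export
strain_to_voigt <- function(eps, engineering = TRUE) {
  s <- if (engineering) 2 else 1
  c(eps[1, 1], eps[2, 2], eps[3, 3],
    s * eps[1, 2], s * eps[1, 3], s * eps[2, 3])
}

#' Convert a 6-vector to a symmetric 3x3 tensor
#'
#' @param v Length-6 vector, order (11, 22, 33, 12, 13, 23).
#' @param engineering If `TRUE`, shear entries of `v` are engineering gammas
#'   and are halved to tensorial components.
#' @return Symmetric 3x3 matrix.
#' @export
voigt_to_tensor <- function(v, engineering = FALSE) {
  s <- if (engineering) 0.5 else 1
  matrix(c(v[1],     s * v[4], s * v[5],
           s * v[4], v[2],     s * v[6],
           s * v[5], s * v[6], v[3]), 3, 3)
}
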