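# Scalar continuum damage model with strain-driven exponential softening.
#
# Damage degrades the whole stiffness tensor uniformly: sigma = (1 - D) C eps.
# The driving strain ("criterion strain") is either the magnitude of the most
# compressive principal strain or the von Mises equivalent strain; damage is
# made irreversible through a history variable kappa = running maximum of the
# criterion strain.

#' Damage law for quasi-brittle cortical bone failure
#'
#' Once the driving strain exceeds the critical failure strain
#' `epsilon_f` (4.3% in compression for rat femoral cortical bone), the damage
#' variable evolves as `D = 1 - exp(1 - kappa / epsilon_f)`, capped at
#' `D_max`.  An element whose modulus has degraded to `residual_fraction`
#' of the original (i.e. `D >= D_max`) is considered failed and loses its
#' load-bearing capacity.  `residual_fraction` must equal `1 - D_max`; the
#' constructor enforces the consistency.
#'
#' @param epsilon_f Critical failure strain, dimensionless.
#' @param D_max Cap on the damage variable.
#' @param residual_fraction Modulus fraction at which the element fails.
#' @return Object of class `damage_law`.
#' @export
damage_law <- function(epsilon_f = 0.043, D_max = 0.9,
                       residual_fraction = 1 - D_max) {
  if (!(epsilon_f > 0 && epsilon_f < 1)) {
    stop("epsilon_f must lie in (0, 1)", call. = FALSE)
  }
  if (!(D_max > 0 && D_max < 1)) stop("D_max must lie in (0, 1)", call. = FALSE)
  if (abs(residual_fraction - (1 - D_max)) > 1e-12) {
    stop("residual_fraction must equal 1 - D_max (got ", residual_fraction,
         " vs ", 1 - D_max, ")", call. = FALSE)
  }
  structure(list(epsilon_f = epsilon_f, D_max = D_max,
                 residual_fraction = residual_fraction),
            class = "damage_law")
}

#' @export
print.damage_law <- function(x, ...) {
  cat(sprintf(
    "Damage law: eps_f = %g, D capped at %g, element fails at %g%% residual modulus\n",
    x$epsilon_f, x$D_max, 100 * x$residual_fraction))
  invisible(x)
}

#' Damage variable from the strain history variable
#'
#' `D = 0` for `kappa <= epsilon_f`; `D = min(D_max, 1 - exp(1 - kappa /
#' epsilon_f))` beyond.  Continuous at the threshold and non-decreasing in
#' `kappa`.  Vectorized over `kappa`.
#'
#' @param kappa Non-negative history variable (running maximum of the
#'   criterion strain).
#' @param law A [damage_law()].
#' @return Damage values in `[0, D_max]`.
#' @export
damage_from_kappa <- function(kappa, law) {
  stopifnot(all(kappa >= 0))
  D <- 1 - exp(1 - kappa / law$epsilon_f)
  # relative guard absorbs roundoff so a state loaded exactly to the
  # threshold is undamaged (the comparison is strict: damage beyond eps_f)
  D[kappa <= law$epsilon_f * (1 + 1e-9)] <- 0
  pmin(D, law$D_max)
}

#' Strain-judging criterion
#'
#' @param mode `"min_principal"` (magnitude of the most compressive principal
#'   strain drives damage; tensile-dominated states drive none) or
#'   `"equivalent"` (von Mises equivalent strain).
#' @return Object of class `strain_criterion`.
#' @export
strain_criterion <- function(mode = c("min_principal", "equivalent")) {
  structure(list(mode = match.arg(mode)), class = "strain_criterion")
}

as_strain_criterion <- function(x) {
  if (inherits(x, "strain_criterion")) return(x)
  strain_criterion(x)
}

#' Minimum principal strain of a symmetric tensor
#'
#' Returns the smallest (most negative) eigenvalue.
#'
#' @param eps Symmetric 3x3 strain tensor (tensorial shear).
#' @return Signed scalar.
#' @export
min_principal_strain <- function(eps) {
  min(eigen(eps, symmetric = TRUE, only.values = TRUE)$values)
}

#' Von Mises equivalent strain
#'
#' `eps_eq = sqrt((2/3) e : e)` with `e` the deviatoric part of the total
#' strain tensor; zero iff the deviator vanishes, rotation-invariant, and
#' sensitive to shear — the property that distinguishes it from the principal
#' strain criterion.
#'
#' @param eps Symmetric 3x3 strain tensor (tensorial shear).
#' @return Non-negative scalar.
#' @export
equivalent_strain <- function(eps) {
  e <- eps - diag(mean(diag(eps)), 3)
  sqrt(2 / 3 * sum(e * e))
}

#' Criterion (driving) strain of a state
#'
#' For `min_principal`, the compressive magnitude `max(0,
#' -min_principal_strain(eps))`; for `equivalent`, the von Mises equivalent
#' strain.
#'
#' @param eps Symmetric 3x3 strain tensor.
#' @param criterion A [strain_criterion()] or its mode string.
#' @return Non-negative scalar driving strain.
#' @export
criterion_strain <- function(eps, criterion) {
  criterion <- as_strain_criterion(criterion)
  switch(criterion$mode,
         min_principal = max(0, -min_principal_strain(eps)),
         equivalent = equivalent_strain(eps))
}

# --- vectorized forms over 6 x n tensorial strain columns ---
# rows: e11, e22, e33, e12, e13, e23 (tensorial shear)

# smallest eigenvalue of many symmetric 3x3 tensors at once
# (trigonometric closed form; eigen() is the test oracle)
min_principal_strain_cols <- function(E) {
  a11 <- E[1, ]; a22 <- E[2, ]; a33 <- E[3, ]
  a12 <- E[4, ]; a13 <- E[5, ]; a23 <- E[6, ]
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  out <- q
  nz <- p > 0
  if (any(nz)) {
    pn <- p[nz]; qn <- q[nz]
    b11 <- (a11[nz] - qn) / pn; b22 <- (a22[nz] - qn) / pn
    b33 <- (a33[nz] - qn) / pn
    b12 <- a12[nz] / pn; b13 <- a13[nz] / pn; b23 <- a23[nz] / pn
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(1, pmax(-1, detB / 2))
    phi <- acos(r) / 3
    out[nz] <- qn + 2 * pn * cos(phi + 2 * pi / 3)
  }
  out
}

equivalent_strain_cols <- function(E) {
  m <- (E[1, ] + E[2, ] + E[3, ]) / 3
  sqrt(2 / 3 * ((E[1, ] - m)^2 + (E[2, ] - m)^2 + (E[3, ] - m)^2 +
                  2 * (E[4, ]^2 + E[5, ]^2 + E[6, ]^2)))
}

criterion_strain_cols <- function(E, criterion) {
  criterion <- as_strain_criterion(criterion)
  switch(criterion$mode,
         min_principal = pmax(0, -min_principal_strain_cols(E)),
         equivalent = equivalent_strain_cols(E))
}

#' Fresh (undamaged) material point state
#'
#' @return Object of class `point_state` with zero strain, zero damage, zero
#'   history variable and `failed = FALSE`.
#' @export
point_state <- function() {
  structure(list(strain = matrix(0, 3, 3), D = 0, kappa = 0, failed = FALSE),
            class = "point_state")
}

#' Point-level material update (UMAT-style contract)
#'
#' Given the current total strain and the previous state, advances the history
#' variable `kappa` (running maximum of the criterion strain, guaranteeing
#' irreversibility even on unloading), evaluates the damage variable, and
#' returns the stress `sigma = (1 - D) C eps`, the updated state, and the
#' secant stiffness `(1 - D) C`.
#'
#' @param eps Symmetric 3x3 strain tensor (tensorial shear).
#' @param state Previous [point_state()].
#' @param constants [elastic_constants()].
#' @param law [damage_law()].
#' @param criterion [strain_criterion()] or mode string.
#' @return List with `stress` (3x3, MPa), `state` (updated `point_state`),
#'   and `secant_matrix` (6x6, MPa).
#' @export
material_update <- function(eps, state, constants, law, criterion) {
  C <- stiffness_matrix(constants)
  kappa_new <- max(state$kappa, criterion_strain(eps, criterion))
  D_new <- max(state$D, damage_from_kappa(kappa_new, law))
  failed <- state$failed || D_new >= law$D_max - 1e-12
  sv <- (1 - D_new) * as.vector(C %*% strain_to_voigt(eps, engineering = TRUE))
  new_state <- structure(list(strain = eps, D = D_new, kappa = kappa_new,
                              failed = failed), class = "point_state")
  list(stress = voigt_to_tensor(sv, engineering = FALSE),
       state = new_state,
       secant_matrix = (1 - D_new) * C)
}

#' Consistent (algorithmic) tangent stiffness after damage onset
#'
#' The full derivative of the stress map with respect to strain on a loading
#' path: `d sigma / d eps = (1 - D) C - (C eps) (dD/deps)^T`, where
#' `dD/deps = (dD/dkappa) (dkappa/deps)` whenever the criterion strain is
#' advancing the history variable, and zero on unloading or at the cap.  Kept
#' for verification; the incremental solver uses the secant `(1 - D) C`,
#' which with the staggered scheme is sufficient for equilibrium and far more
#' robust for quasi-brittle softening.
#'
#' Matrix acts on engineering-Voigt strain increments (order 11, 22, 33, 12,
#' 13, 23).
#'
#' @inheritParams material_update
#' @return 6x6 tangent matrix, MPa.
#' @export
consistent_tangent <- function(eps, state, constants, law, criterion) {
  criterion <- as_strain_criterion(criterion)
  C <- stiffness_matrix(constants)
  kap <- criterion_strain(eps, criterion)
  kappa_new <- max(state$kappa, kap)
  D_new <- max(state$D, damage_from_kappa(kappa_new, law))
  Cd <- (1 - D_new) * C
  # damage evolving only if the current criterion strain is the active maximum
  # and lies strictly between the threshold and the cap crossing
  if (kap < state$kappa || kappa_new <= law$epsilon_f ||
      D_new >= law$D_max - 1e-12) {
    return(Cd)
  }
  dD_dk <- exp(1 - kappa_new / law$epsilon_f) / law$epsilon_f
  # dkappa/deps as a tensor, then conjugate engineering-Voigt form (shear
  # entries keep the tensorial value: g = dkappa/dgamma_ij = (1/2) * 2 * t_ij)
  if (criterion$mode == "min_principal") {
    eg <- eigen(eps, symmetric = TRUE)
    n <- eg$vectors[, which.min(eg$values)]
    Tm <- -(n %o% n)                      # kappa = -lambda_min
  } else {
    e <- eps - diag(mean(diag(eps)), 3)
    eq <- equivalent_strain(eps)
    if (eq == 0) return(Cd)
    Tm <- (2 / 3) * e / eq
  }
  g <- c(Tm[1, 1], Tm[2, 2], Tm[3, 3], Tm[1, 2], Tm[1, 3], Tm[2, 3])
  sv <- as.vector(C %*% strain_to_voigt(eps, engineering = TRUE))
  Cd - dD_dk * (sv %o% g)
}
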