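# Incremental progressive-failure driver.
#
# Displacement-controlled loading with a staggered (operator-split) damage
# iteration at each increment: solve equilibrium with the current per-element
# secant factors, recover centroid strains, advance the damage field, and
# repeat at frozen boundary displacement until the damage field is stationary.
# Failed elements ((1 - D) <= residual fraction) keep a small stiffness floor
# instead of being deleted, which keeps the system non-singular.

#' Simulation configuration
#'
#' @param total_displacement Total platen displacement magnitude, mm.
#' @param n_increments Number of equal displacement increments.
#' @param criterion [strain_criterion()] or mode string.
#' @param stagger_tolerance Convergence threshold on the max per-element
#'   damage change within a stagger iteration.
#' @param max_stagger_iterations Iteration cap; non-convergence is accepted
#'   with a warning and flagged in the result, never silent.
#' @param stiffness_floor Residual stiffness factor of failed elements.
#' @param load_drop_fraction Terminate once the reaction has dropped by this
#'   fraction from its peak (after damage has begun); `NULL` disables.
#' @param percolation_check Terminate when failed elements disconnect the
#'   intact element graph between top and bottom (`TRUE`/`FALSE`).
#' @param bisection_fraction If more than this fraction of elements changes
#'   to failed within one increment, the increment is re-tried at half size
#'   (down to 1/16 of the nominal increment) to avoid overshooting the
#'   brutal softening branch.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(total_displacement = 0.5, n_increments = 100,
                              criterion = "min_principal",
                              stagger_tolerance = 1e-3,
                              max_stagger_iterations = 25,
                              stiffness_floor = 1e-4,
                              load_drop_fraction = 0.2,
                              percolation_check = TRUE,
                              bisection_fraction = 0.05) {
  stopifnot(n_increments >= 1, total_displacement > 0,
            stagger_tolerance > 0, max_stagger_iterations >= 1)
  if (!(stiffness_floor > 0 && stiffness_floor < 0.1)) {
    stop("stiffness_floor must lie in (0, 1 - D_max)", call. = FALSE)
  }
  if (!is.null(load_drop_fraction) &&
      !(load_drop_fraction > 0 && load_drop_fraction < 1)) {
    stop("load_drop_fraction must lie in (0, 1) or be NULL", call. = FALSE)
  }
  structure(list(total_displacement = total_displacement,
                 n_increments = n_increments,
                 criterion = as_strain_criterion(criterion),
                 stagger_tolerance = stagger_tolerance,
                 max_stagger_iterations = max_stagger_iterations,
                 stiffness_floor = stiffness_floor,
                 load_drop_fraction = load_drop_fraction,
                 percolation_check = isTRUE(percolation_check),
                 bisection_fraction = bisection_fraction),
            class = "simulation_config")
}

# secant factors from the element state fields
secant_factors <- function(D, failed, floor) {
  f <- 1 - D
  f[failed] <- floor
  f
}

#' One staggered damage iteration pass at frozen boundary displacement
#'
#' Fixed-point iteration on the damage field: repeatedly solve equilibrium
#' and advance `kappa`/`D` until the largest per-element damage change falls
#' below the tolerance.  `D` is non-decreasing within the iteration (history
#' variable semantics).
#'
#' @param sys An [fe_system()].
#' @param state List with numeric vectors `kappa`, `D` and logical `failed`
#'   (one entry per element).
#' @param lambda Load factor of the frozen boundary displacement.
#' @param law [damage_law()].
#' @param config [simulation_config()].
#' @return List: updated `state`, `solution` (last [solve_system()] output),
#'   `converged` flag and `iterations` used.
#' @export
stagger_iteration <- function(sys, state, lambda, law, config) {
  converged <- FALSE
  iters <- 0L
  sol <- NULL
  repeat {
    iters <- iters + 1L
    f <- secant_factors(state$D, state$failed, config$stiffness_floor)
    sol <- solve_system(sys, f, lambda)
    E <- recover_centroid_strains(sys$mesh, sol$u)
    kap <- pmax(state$kappa, criterion_strain_cols(E, config$criterion))
    D_new <- pmax(state$D, damage_from_kappa(kap, law))
    dmax <- max(abs(D_new - state$D))
    state$kappa <- kap
    state$D <- D_new
    state$failed <- state$failed | (D_new >= law$D_max - 1e-12)
    if (dmax <= config$stagger_tolerance) { converged <- TRUE; break }
    if (iters >= config$max_stagger_iterations) break
  }
  list(state = state, solution = sol, converged = converged,
       iterations = iters)
}

#' Has the failed-element set percolated across the specimen?
#'
#' Operationalizes "apparent failure once failed elements accumulate":
#' returns `TRUE` when the face-connected graph of *intact* elements no
#' longer links the top voxel layer to the bottom voxel layer, i.e. a
#' failed-element surface separates the specimen.
#'
#' @param mesh A [voxels_to_mesh()] mesh.
#' @param failed Logical vector, one per element.
#' @return `TRUE` if the intact graph is disconnected top-to-bottom.
#' @export
check_percolation <- function(mesh, failed) {
  if (!any(failed)) return(FALSE)
  intact <- !failed
  kk <- mesh$voxel_ijk[, 3]
  top_set <- intact & kk == max(kk)
  bot_set <- intact & kk == min(kk)
  if (!any(top_set) || !any(bot_set)) return(TRUE)
  # BFS over intact elements from the top layer
  reach <- logical(length(failed))
  frontier <- which(top_set)
  reach[frontier] <- TRUE
  fn <- mesh$face_neighbors
  while (length(frontier) > 0) {
    nb <- unique(as.vector(fn[frontier, , drop = FALSE]))
    nb <- nb[!is.na(nb)]
    nb <- nb[intact[nb] & !reach[nb]]
    reach[nb] <- TRUE
    frontier <- nb
  }
  !any(reach & bot_set)
}

#' Run a displacement-controlled progressive-failure simulation
#'
#' Applies the platen displacement in equal increments; at each increment a
#' staggered damage iteration brings equilibrium and the damage field to a
#' fixed point.  An increment in which more than `bisection_fraction` of the
#' elements newly fails is discarded and re-tried at half size.  The run
#' terminates at full displacement, at a load drop of `load_drop_fraction`
#' from the peak reaction, or when failed elements percolate across the
#' specimen.
#'
#' @param mesh A [voxels_to_mesh()] mesh.
#' @param constants [elastic_constants()].
#' @param law [damage_law()].
#' @param criterion [strain_criterion()] or mode string; overrides the one in
#'   `config` if non-`NULL`.
#' @param config [simulation_config()].
#' @param bcs [boundary_conditions()]; its axial displacement is replaced by
#'   `-config$total_displacement`.
#' @param verbose Print one line per accepted increment.
#' @return Object of class `simulation_result`: `records` (data.frame with
#'   one row per accepted increment: `displacement` mm, `reaction` N,
#'   `n_damaged`, `n_failed`, `max_D`, `stagger_iterations`, `converged`),
#'   final `D`, `kappa`, `failed` per element, `termination` reason, and the
#'   configuration used.
#' @export
run_compression <- function(mesh, constants, law,
                            criterion = NULL, config = simulation_config(),
                            bcs = boundary_conditions(), verbose = FALSE) {
  if (!is.null(criterion)) config$criterion <- as_strain_criterion(criterion)
  bcs$applied_axial_displacement <- -config$total_displacement
  sys <- fe_system(mesh, constants, bcs)
  nel <- nrow(mesh$elements)
  state <- list(kappa = numeric(nel), D = numeric(nel),
                failed = logical(nel))

  # load factor tracked as an exact integer fraction (increments may be
  # bisected down to 1/16 of the nominal step) so prescribed displacements
  # carry no accumulated roundoff
  den <- 16 * config$n_increments
  lam_k <- 0L
  lambda <- 0
  records <- list(list(displacement = 0, reaction = 0, n_damaged = 0L,
                       n_failed = 0L, max_D = 0, stagger_iterations = 0L,
                       converged = TRUE))
  peak <- 0
  termination <- "full_displacement"
  any_warn <- FALSE

  while (lam_k < den) {
    step_k <- min(16L, den - lam_k)
    accepted <- FALSE
    while (!accepted) {
      target_k <- lam_k + step_k
      target <- target_k / den
      trial <- stagger_iteration(sys, state, target, law, config)
      newly_failed <- sum(trial$state$failed) - sum(state$failed)
      if (newly_failed > config$bisection_fraction * nel && step_k > 1L) {
        step_k <- step_k %/% 2L   # overshoot of the softening branch: re-try
        next
      }
      if (!trial$converged) {
        any_warn <- TRUE
        warning(sprintf(
          "stagger iteration did not converge at displacement %.4g mm (%d iterations); increment accepted",
          target * config$total_displacement,
          trial$iterations), call. = FALSE)
      }
      state <- trial$state
      lam_k <- target_k
      lambda <- target
      rec <- list(displacement = lambda * config$total_displacement,
                  reaction = trial$solution$reaction_top,
                  n_damaged = sum(state$D > 0),
                  n_failed = sum(state$failed),
                  max_D = max(state$D),
                  stagger_iterations = trial$iterations,
                  converged = trial$converged)
      records[[length(records) + 1L]] <- rec
      if (verbose) {
        message(sprintf("  u = %.4f mm  R = %.2f N  damaged %d  failed %d",
                        rec$displacement, rec$reaction, rec$n_damaged,
                        rec$n_failed))
      }
      accepted <- TRUE
      peak <- max(peak, rec$reaction)
      if (!is.null(config$load_drop_fraction) && any(state$D > 0) &&
          rec$reaction < (1 - config$load_drop_fraction) * peak) {
        termination <- "load_drop"
      }
      if (config$percolation_check && check_percolation(mesh, state$failed)) {
        termination <- if (termination == "load_drop") {
          "load_drop+percolation"
        } else "percolation"
      }
    }
    if (termination != "full_displacement") break
  }

  rec_df <- do.call(rbind, lapply(records, as.data.frame))
  structure(list(records = rec_df,
                 D = state$D, kappa = state$kappa, failed = state$failed,
                 termination = termination,
                 stagger_warnings = any_warn,
                 criterion = config$criterion$mode,
                 config = config, bcs = bcs,
                 n_elements = nel),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  r <- x$records
  cat(sprintf(
    "Compression simulation (%s criterion): %d increments on %d elements\n",
    x$criterion, nrow(r) - 1, x$n_elements))
  cat(sprintf("  peak reaction %.2f N at %.4f mm; %d failed elements; terminated: %s\n",
              max(r$reaction), r$displacement[which.max(r$reaction)],
              max(r$n_failed), x$termination))
  cat("  note: platen friction is approximated by nodal stick/frictionless",
      "constraints\n")
  invisible(x)
}
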