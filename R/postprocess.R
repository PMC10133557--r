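# Derived fracture quantities and the two comparison studies.

#' Summarize a simulation into fracture parameters
#'
#' Fracture load is the peak reaction of the load-displacement record;
#' fracture displacement is the displacement at that peak, and fracture time
#' converts it to seconds at the quasi-static test rate of 1 mm/min.
#' Apparent stiffness is the least-squares slope of the ascending branch
#' restricted to reactions between 10% and 40% of the peak.  The crack plane
#' is fitted to the centroids of the largest face-connected cluster of
#' failed elements by principal-axis analysis (plane normal = direction of
#' smallest centroid spread); the crack angle is measured between that
#' normal and the loading axis, and the crack is classed transverse when the
#' angle is at most 15 degrees, else oblique.
#'
#' @param result A [run_compression()] result (at least 3 increments).
#' @param mesh The mesh the simulation ran on.
#' @param stiffness_window Reaction window for the stiffness fit, as
#'   fractions of the peak load.
#' @return Object of class `fracture_summary` with fields `fracture_load`
#'   (N), `fracture_displacement` (mm), `fracture_time` (s),
#'   `apparent_stiffness` (N/mm), `crack_angle` (degrees), `crack_class`,
#'   `any_failure`, `termination`.
#' @export
summarize_fracture <- function(result, mesh,
                               stiffness_window = c(0.1, 0.4)) {
  r <- result$records
  if (nrow(r) < 3) stop("need at least 3 increments to summarize", call. = FALSE)
  ipeak <- which.max(r$reaction)
  peak <- r$reaction[ipeak]

  asc <- seq_len(ipeak)
  win <- asc[r$reaction[asc] >= stiffness_window[1] * peak &
               r$reaction[asc] <= stiffness_window[2] * peak]
  stiff <- if (length(win) >= 2) {
    unname(stats::coef(stats::lm(r$reaction[win] ~ r$displacement[win]))[2])
  } else NA_real_

  any_failure <- any(result$failed)
  if (any_failure) {
    cl <- largest_failed_cluster(mesh, result$failed)
    ang <- crack_plane_angle(element_centroids(mesh)[cl, , drop = FALSE])
    summary_load <- peak
    summary_disp <- r$displacement[ipeak]
  } else {
    ang <- NA_real_
    summary_load <- NA_real_
    summary_disp <- NA_real_
  }
  structure(list(
    fracture_load = summary_load,
    fracture_displacement = summary_disp,
    fracture_time = summary_disp * 60,   # 1 mm/min = 1/60 mm/s
    apparent_stiffness = stiff,
    crack_angle = ang,
    crack_class = if (is.na(ang)) NA_character_ else {
      if (ang <= 15) "transverse" else "oblique"
    },
    any_failure = any_failure,
    termination = result$termination,
    criterion = result$criterion),
    class = "fracture_summary")
}

#' @export
print.fracture_summary <- function(x, ...) {
  cat(sprintf("Fracture summary (%s criterion):\n", x$criterion))
  if (x$any_failure) {
    cat(sprintf("  fracture load %.2f N at %.4f mm (%.1f s at 1 mm/min)\n",
                x$fracture_load, x$fracture_displacement, x$fracture_time))
    cat(sprintf("  crack angle %.1f deg -> %s\n", x$crack_angle, x$crack_class))
  } else {
    cat("  no element failure occurred\n")
  }
  cat(sprintf("  apparent stiffness %.1f N/mm; terminated: %s\n",
              x$apparent_stiffness, x$termination))
  invisible(x)
}

# indices of the largest face-connected cluster of failed elements
largest_failed_cluster <- function(mesh, failed) {
  idx <- which(failed)
  if (length(idx) == 0) return(integer(0))
  fn <- mesh$face_neighbors
  seen <- logical(length(failed))
  best <- integer(0)
  for (s in idx) {
    if (seen[s]) next
    comp <- s
    frontier <- s
    seen[s] <- TRUE
    while (length(frontier) > 0) {
      nb <- unique(as.vector(fn[frontier, , drop = FALSE]))
      nb <- nb[!is.na(nb)]
      nb <- nb[failed[nb] & !seen[nb]]
      seen[nb] <- TRUE
      comp <- c(comp, nb)
      frontier <- nb
    }
    if (length(comp) > length(best)) best <- comp
  }
  best
}

# angle (degrees) between the best-fit plane normal of a centroid cloud and
# the loading (z) axis; normal = principal axis of smallest spread
crack_plane_angle <- function(centroids) {
  n <- nrow(centroids)
  if (n < 3) return(0)
  X <- sweep(centroids, 2, colMeans(centroids))
  cv <- crossprod(X) / n
  eg <- eigen(cv, symmetric = TRUE)
  normal <- eg$vectors[, which.min(eg$values)]
  acos(min(1, abs(normal[3]))) * 180 / pi
}

#' Mesh-sensitivity study
#'
#' Generates the same synthetic specimen (same seed, same underlying
#' surfaces) at several element sizes and runs a full fracture simulation at
#' each, with identical material, damage law, criterion and loading.
#'
#' @param geometry Named list of [generate_hollow_cylinder()] arguments
#'   (excluding `voxel_size`).
#' @param sizes_um Element sizes in micrometres.
#' @param constants [elastic_constants()].
#' @param law [damage_law()].
#' @param criterion [strain_criterion()] or mode string.
#' @param config [simulation_config()].
#' @param bcs [boundary_conditions()].
#' @param verbose Print progress.
#' @return Object of class `sensitivity_table`: data.frame with one row per
#'   size (`element_size_um`, `element_count`, `fracture_load`,
#'   `apparent_stiffness`, `ok`), sorted by size; sizes too coarse for the
#'   wall are flagged (`ok = FALSE`, NA results), not fatal.
#' @export
mesh_sensitivity_study <- function(geometry = list(), sizes_um,
                                   constants = elastic_constants(),
                                   law = damage_law(),
                                   criterion = "equivalent",
                                   config = simulation_config(),
                                   bcs = boundary_conditions(),
                                   verbose = FALSE) {
  stopifnot(length(sizes_um) >= 1)
  sz <- sort(unique(sizes_um))
  if (length(sz) < length(sizes_um)) {
    warning("duplicate element sizes removed", call. = FALSE)
  }
  rows <- lapply(sz, function(s) {
    row <- list(element_size_um = s, element_count = NA_integer_,
                fracture_load = NA_real_, apparent_stiffness = NA_real_,
                ok = FALSE)
    spec <- tryCatch(
      do.call(generate_hollow_cylinder,
              c(geometry, list(voxel_size = s / 1000))),
      error = function(e) e)
    if (inherits(spec, "error")) {
      warning(sprintf("size %g um skipped: %s", s, conditionMessage(spec)),
              call. = FALSE)
      return(as.data.frame(row))
    }
    mesh <- voxels_to_mesh(spec)
    if (verbose) message(sprintf("size %g um: %d elements", s,
                                 nrow(mesh$elements)))
    res <- run_compression(mesh, constants, law, criterion, config, bcs)
    sm <- summarize_fracture(res, mesh)
    row$element_count <- nrow(mesh$elements)
    row$fracture_load <- sm$fracture_load
    row$apparent_stiffness <- sm$apparent_stiffness
    row$ok <- TRUE
    as.data.frame(row)
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("sensitivity_table", class(tab))
  tab
}

#' Compare the two strain-judging criteria on one specimen
#'
#' Runs two otherwise identical simulations, one per criterion, and reports
#' both fracture summaries, the fracture-load and displacement-at-failure
#' ratios, both crack classes, and a check that the pre-damage portions of
#' the two load-displacement curves coincide (they must, since the assigned
#' elastic moduli are identical).
#'
#' @param mesh A [voxels_to_mesh()] mesh.
#' @param constants [elastic_constants()].
#' @param law [damage_law()].
#' @param config [simulation_config()].
#' @param bcs [boundary_conditions()].
#' @param verbose Print progress.
#' @return Object of class `criterion_comparison`: list with `min_principal`
#'   and `equivalent` entries (each `result` + `summary`), `load_ratio`
#'   (equivalent / min-principal fracture load), `displacement_ratio`,
#'   `crack_classes`, and `early_curve_max_rel_diff` over increments where
#'   both runs are damage-free.
#' @export
compare_criteria <- function(mesh, constants = elastic_constants(),
                             law = damage_law(),
                             config = simulation_config(),
                             bcs = boundary_conditions(),
                             verbose = FALSE) {
  runs <- lapply(c("min_principal", "equivalent"), function(cr) {
    if (verbose) message("running criterion: ", cr)
    res <- run_compression(mesh, constants, law, cr, config, bcs,
                           verbose = verbose)
    list(result = res, summary = summarize_fracture(res, mesh))
  })
  names(runs) <- c("min_principal", "equivalent")

  ra <- runs$min_principal$result$records
  rb <- runs$equivalent$result$records
  n <- min(max(which(ra$n_damaged == 0)), max(which(rb$n_damaged == 0)),
           nrow(ra), nrow(rb))
  pre <- 2:n
  rel <- if (n >= 2) {
    max(abs(ra$reaction[pre] - rb$reaction[pre]) /
          pmax(abs(ra$reaction[pre]), 1e-12))
  } else 0

  structure(list(
    min_principal = runs$min_principal,
    equivalent = runs$equivalent,
    load_ratio = runs$equivalent$summary$fracture_load /
      runs$min_principal$summary$fracture_load,
    displacement_ratio = runs$equivalent$summary$fracture_displacement /
      runs$min_principal$summary$fracture_displacement,
    crack_classes = c(
      min_principal = runs$min_principal$summary$crack_class,
      equivalent = runs$equivalent$summary$crack_class),
    early_curve_max_rel_diff = rel),
    class = "criterion_comparison")
}

#' @export
print.criterion_comparison <- function(x, ...) {
  cat("Criterion comparison (min-principal vs equivalent strain):\n")
  cat(sprintf("  fracture load: %.2f N vs %.2f N (ratio eq/mp = %.3f)\n",
              x$min_principal$summary$fracture_load,
              x$equivalent$summary$fracture_load, x$load_ratio))
  cat(sprintf("  fracture displacement: %.4f mm vs %.4f mm (ratio %.3f)\n",
              x$min_principal$summary$fracture_displacement,
              x$equivalent$summary$fracture_displacement,
              x$displacement_ratio))
  cat(sprintf("  crack classes: %s vs %s\n",
              x$crack_classes[["min_principal"]],
              x$crack_classes[["equivalent"]]))
  cat(sprintf("  pre-damage curve max relative difference: %.2e\n",
              x$early_curve_max_rel_diff))
  invisible(x)
}
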