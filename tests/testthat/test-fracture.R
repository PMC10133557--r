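# Progressive-failure driver: thresholds, irreversibility, staggering,
# percolation, floor insensitivity.

test_that("sub-threshold loading stays elastic and matches a pure elastic solve", {
  mesh <- voxels_to_mesh(block_specimen(2, 2, 3, h = 0.5))
  # 1% total strain: well below the 4.3% threshold
  cfg <- simulation_config(total_displacement = 0.015, n_increments = 5)
  res <- run_compression(mesh, elastic_constants(), damage_law(),
                         "min_principal", cfg, boundary_conditions())
  expect_identical(res$termination, "full_displacement")
  expect_equal(max(res$D), 0)
  expect_identical(unique(res$records$n_damaged), 0L)
  # linear curve through the origin
  r <- res$records
  slopes <- r$reaction[-1] / r$displacement[-1]
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-8 * slopes[1])
  # final increment reproduces a one-shot elastic solve (ulp-level agreement)
  bc <- boundary_conditions(applied_axial_displacement = -0.015)
  sol <- assemble_and_solve(mesh, elastic_constants(), bc)
  expect_equal(r$reaction[nrow(r)], sol$reaction_top, tolerance = 1e-12)
})

test_that("single element: last zero-damage strain is the 4.3% threshold and failure records D = 0.9", {
  res <- single_element_ramp("min_principal", total = 0.2, step = 0.001)
  r <- res$records
  undamaged <- r$displacement[r$n_damaged == 0]
  expect_equal(max(undamaged), 0.043)           # strain = displacement / 1 mm
  expect_equal(min(r$displacement[r$n_damaged > 0]), 0.044)
  fail_row <- which(r$n_failed > 0)[1]
  expect_equal(r$max_D[fail_row], 0.9)          # cap engaged exactly
  expect_equal(r$max_D[fail_row - 1] < 0.9, TRUE)
  # threshold crossing is where the analytic cap crossing predicts
  expect_equal(r$displacement[fail_row], 0.143)  # first step past eps_f(1+ln10)
})

test_that("damage and failure counts are monotone across increments", {
  mesh <- test_tube_mesh(voxel_size = 0.25)
  cfg <- simulation_config(n_increments = 50)
  res <- suppressWarnings(
    run_compression(mesh, elastic_constants(), damage_law(), "min_principal",
                    cfg, boundary_conditions()))
  r <- res$records
  expect_true(all(diff(r$displacement) > 0))
  expect_true(all(diff(r$n_failed) >= 0))
  expect_true(all(diff(r$n_damaged) >= 0))
  expect_true(all(diff(r$max_D) >= 0))
  expect_true(all(res$D >= 0 & res$D <= 0.9))
})

test_that("stagger iteration: one pass below threshold, monotone D above", {
  mesh <- voxels_to_mesh(block_specimen(1, 1, 1, h = 1))
  bc <- boundary_conditions(top = "frictionless_platen",
                            applied_axial_displacement = -0.2)
  sys <- fe_system(mesh, elastic_constants(), bc)
  law <- damage_law()
  cfg <- simulation_config(total_displacement = 0.2)
  st0 <- list(kappa = 0, D = 0, failed = FALSE)
  # below threshold: converges in one iteration
  out <- stagger_iteration(sys, st0, lambda = 0.1, law, cfg)
  expect_identical(out$iterations, 1L)
  expect_true(out$converged)
  expect_equal(out$state$D, 0)
  # just past threshold: D sequence non-decreasing, bounded by the cap
  out2 <- stagger_iteration(sys, st0, lambda = 0.25, law, cfg)
  expect_true(out2$converged)
  expect_gt(out2$state$D, 0)
  expect_lte(out2$state$D, 0.9)
})

test_that("results self-converge when the stagger tolerance is tightened", {
  mesh <- voxels_to_mesh(block_specimen(3, 3, 8, h = 0.25))  # 72 elements
  mk <- function(tol) {
    cfg <- simulation_config(total_displacement = 0.11, n_increments = 22,
                             stagger_tolerance = tol,
                             load_drop_fraction = NULL,
                             percolation_check = FALSE)
    suppressWarnings(run_compression(mesh, elastic_constants(), damage_law(),
                                     NULL, cfg, boundary_conditions()))
  }
  ra <- mk(1e-3); rb <- mk(1e-4)
  # damage-free increments are exact fixed points: identical reactions
  pre <- which(ra$records$n_damaged == 0 & rb$records$n_damaged == 0)[-1]
  expect_lt(max(abs(ra$records$reaction[pre] - rb$records$reaction[pre])) /
              max(ra$records$reaction), 1e-6)
  # the fracture load self-converges under a 10x tighter tolerance
  expect_lt(abs(max(ra$records$reaction) - max(rb$records$reaction)) /
              max(rb$records$reaction), 1e-3)
})

test_that("fracture load and pre-collapse curve are floor-insensitive within 1%", {
  mesh <- voxels_to_mesh(block_specimen(3, 3, 6, h = 0.25))
  mk <- function(floor) {
    cfg <- simulation_config(total_displacement = 0.12, n_increments = 24,
                             stiffness_floor = floor)
    suppressWarnings(run_compression(mesh, elastic_constants(), damage_law(),
                                     "min_principal", cfg,
                                     boundary_conditions()))
  }
  r3 <- mk(1e-3); r5 <- mk(1e-5)
  peak <- max(r3$records$reaction)
  expect_lt(abs(peak - max(r5$records$reaction)) / peak, 0.01)
  common <- seq_len(min(nrow(r3$records), nrow(r5$records)))
  expect_lt(max(abs(r3$records$reaction[common] -
                      r5$records$reaction[common])) / peak, 0.01)
})

test_that("percolation detection: none / full layer / isolated element", {
  mesh <- voxels_to_mesh(block_specimen(5, 5, 5, h = 0.2))
  nel <- nrow(mesh$elements)
  expect_false(check_percolation(mesh, rep(FALSE, nel)))
  layer <- mesh$voxel_ijk[, 3] == 3
  expect_true(check_percolation(mesh, layer))
  single <- rep(FALSE, nel); single[which(mesh$voxel_ijk[, 3] == 3)[1]] <- TRUE
  expect_false(check_percolation(mesh, single))
  # an oblique staircase of failed layers also separates the block
  stair <- mesh$voxel_ijk[, 3] == pmin(5, pmax(1, mesh$voxel_ijk[, 1]))
  expect_true(check_percolation(mesh, stair))
})

test_that("run with identical inputs is deterministic", {
  mesh <- voxels_to_mesh(block_specimen(2, 2, 4, h = 0.25))
  cfg <- simulation_config(total_displacement = 0.06, n_increments = 12)
  r1 <- suppressWarnings(run_compression(mesh, elastic_constants(),
                                         damage_law(), NULL, cfg,
                                         boundary_conditions()))
  r2 <- suppressWarnings(run_compression(mesh, elastic_constants(),
                                         damage_law(), NULL, cfg,
                                         boundary_conditions()))
  # a capped stagger increment is accepted with a warning and flagged
  expect_true(any(!r1$records$converged))
  expect_identical(r1$records, r2$records)
  expect_identical(r1$D, r2$D)
})
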