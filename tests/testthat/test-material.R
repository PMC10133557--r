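# Transversely isotropic elasticity and the strain-driven damage law.

test_that("stiffness matrix reproduces the engineering constants", {
  C <- stiffness_matrix(elastic_constants())
  S <- solve(C)
  # uniaxial-stress slope along the osteon axis and transverse to it
  expect_equal(1 / S[3, 3], 13498, tolerance = 1e-10)
  expect_equal(1 / S[1, 1], 11025, tolerance = 1e-10)
  expect_equal(1 / S[2, 2], 11025, tolerance = 1e-10)
  # lateral/axial strain ratio under longitudinal uniaxial stress
  expect_equal(-S[1, 3] / S[3, 3], 0.3, tolerance = 1e-10)
  expect_equal(C, t(C))
  expect_true(all(eigen(C, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("isotropic limit equals the closed-form isotropic stiffness", {
  E <- 10000; nu <- 0.28
  ec <- elastic_constants(E_L = E, E_T = E, nu_LT = nu, nu_TT = nu,
                          G_LT = E / (2 * (1 + nu)))
  expect_equal(stiffness_matrix(ec), isotropic_stiffness_oracle(E, nu),
               tolerance = 1e-12)
})

test_that("axis permutation moves the stiff direction", {
  Cx <- stiffness_matrix(elastic_constants(), axis = "x")
  Sx <- solve(Cx)
  expect_equal(1 / Sx[1, 1], 13498, tolerance = 1e-10)
  expect_equal(1 / Sx[3, 3], 11025, tolerance = 1e-10)
  Cy <- stiffness_matrix(elastic_constants(), axis = "y")
  expect_equal(1 / solve(Cy)[2, 2], 13498, tolerance = 1e-10)
})

test_that("inadmissible constants are rejected with the violated bound named", {
  expect_error(elastic_constants(E_L = -1), "E_L")
  expect_error(elastic_constants(nu_LT = 0.6), "nu_LT")
  # thermodynamically inadmissible combination: compliance loses definiteness
  expect_error(elastic_constants(E_L = 100, E_T = 11025, nu_LT = 0.45),
               "positive definite")
})

test_that("minimum principal strain matches examples and the polynomial oracle", {
  expect_equal(min_principal_strain(diag(c(-0.05, 0.015, 0.015))), -0.05)
  shear <- matrix(c(0, 0.01, 0, 0.01, 0, 0, 0, 0, 0), 3, 3)
  expect_equal(min_principal_strain(shear), -0.01)
  set.seed(7)
  for (i in 1:100) {
    eps <- random_strain()
    expect_equal(min_principal_strain(eps), eig3_poly_oracle(eps)[1],
                 tolerance = 1e-9)
  }
})

test_that("vectorized principal-strain routine agrees with eigen()", {
  set.seed(11)
  tensors <- replicate(200, random_strain(), simplify = FALSE)
  E6 <- vapply(tensors, function(e)
    c(e[1, 1], e[2, 2], e[3, 3], e[1, 2], e[1, 3], e[2, 3]), numeric(6))
  got <- cdmbone:::min_principal_strain_cols(E6)
  want <- vapply(tensors, min_principal_strain, 0)
  expect_equal(got, want, tolerance = 1e-9)
  # degenerate: purely volumetric tensor
  expect_equal(cdmbone:::min_principal_strain_cols(
    matrix(c(0.02, 0.02, 0.02, 0, 0, 0), 6, 1)), 0.02)
})

test_that("equivalent strain matches closed-form cases", {
  expect_equal(equivalent_strain(diag(c(-0.03, 0, 0))), 0.02)
  expect_equal(equivalent_strain(diag(c(0.017, 0.017, 0.017))), 0)
  gam <- 0.02
  shear <- matrix(c(0, gam / 2, 0, gam / 2, 0, 0, 0, 0, 0), 3, 3)
  expect_equal(equivalent_strain(shear), gam / sqrt(3))
  # vectorized form agrees with the scalar form
  set.seed(3)
  tensors <- replicate(50, random_strain(), simplify = FALSE)
  E6 <- vapply(tensors, function(e)
    c(e[1, 1], e[2, 2], e[3, 3], e[1, 2], e[1, 3], e[2, 3]), numeric(6))
  expect_equal(cdmbone:::equivalent_strain_cols(E6),
               vapply(tensors, equivalent_strain, 0), tolerance = 1e-12)
})

test_that("criterion strain: compressive magnitude vs deviatoric norm", {
  eps <- diag(c(-0.05, 0.015, 0.015))
  expect_equal(criterion_strain(eps, "min_principal"), 0.05)
  expect_equal(criterion_strain(diag(c(0.05, 0, 0)), "min_principal"), 0)
  expect_equal(criterion_strain(eps, "equivalent"), equivalent_strain(eps))
})

test_that("both criterion strains are rotation invariant", {
  set.seed(19)
  for (i in 1:40) {
    eps <- random_strain()
    Q <- random_rotation()
    rot <- Q %*% eps %*% t(Q)
    expect_equal(criterion_strain(rot, "min_principal"),
                 criterion_strain(eps, "min_principal"), tolerance = 1e-10)
    expect_equal(criterion_strain(rot, "equivalent"),
                 criterion_strain(eps, "equivalent"), tolerance = 1e-10)
  }
})

test_that("damage law analytics: threshold, e-folding point, cap crossing", {
  law <- damage_law()
  ef <- law$epsilon_f
  expect_equal(damage_from_kappa(ef, law), 0)
  expect_equal(damage_from_kappa(0, law), 0)
  # just beyond the threshold the law is continuous
  expect_lt(damage_from_kappa(ef * (1 + 1e-9), law), 1e-8)
  expect_equal(damage_from_kappa(2 * ef, law), 1 - exp(-1))
  # cap engages exactly at its analytic crossing eps_f (1 + ln 10)
  kstar <- ef * (1 + log(10))
  expect_equal(kstar, 0.1420112, tolerance = 1e-6)
  expect_lt(damage_from_kappa(kstar * (1 - 1e-9), law), 0.9)
  expect_equal(damage_from_kappa(kstar, law), 0.9)
  expect_equal(damage_from_kappa(10, law), 0.9)
  # monotone non-decreasing
  ks <- seq(0, 0.4, by = 1e-3)
  expect_true(all(diff(damage_from_kappa(ks, law)) >= 0))
})

test_that("damage law construction enforces consistency", {
  expect_error(damage_law(epsilon_f = -0.01), "epsilon_f")
  expect_error(damage_law(D_max = 0.9, residual_fraction = 0.2),
               "residual_fraction")
})

test_that("material update: elasticity below threshold, definitional identity", {
  ec <- elastic_constants(); law <- damage_law()
  C <- stiffness_matrix(ec)
  eps <- diag(c(0.003, 0.003, -0.01))
  out <- material_update(eps, point_state(), ec, law, "min_principal")
  expect_equal(out$state$D, 0)
  sv <- C %*% strain_to_voigt(eps, engineering = TRUE)
  expect_equal(out$stress, voigt_to_tensor(sv), tolerance = 1e-12)
  expect_equal(out$secant_matrix, C)
  # stress = (1 - D) C eps and secant consistency hold for damaged states too
  set.seed(5)
  st <- point_state()
  for (i in 1:20) {
    eps <- random_strain(0.04)
    out <- material_update(eps, st, ec, law, "equivalent")
    st <- out$state
    expect_equal(out$stress,
                 voigt_to_tensor((1 - st$D) *
                                   (C %*% strain_to_voigt(eps, TRUE))),
                 tolerance = 1e-10)
    expect_equal(voigt_to_tensor(out$secant_matrix %*%
                                   strain_to_voigt(eps, TRUE)),
                 out$stress, tolerance = 1e-10)
  }
})

test_that("damage is irreversible: load past threshold then unload", {
  ec <- elastic_constants(); law <- damage_law()
  st <- point_state()
  big <- diag(c(0, 0, -2 * law$epsilon_f))
  out <- material_update(big, st, ec, law, "min_principal")
  expect_equal(out$state$D, 1 - exp(-1))
  small <- diag(c(0, 0, -0.01))
  out2 <- material_update(small, out$state, ec, law, "min_principal")
  expect_equal(out2$state$D, 1 - exp(-1))   # D frozen at the running max
  C <- stiffness_matrix(ec)
  expect_equal(out2$stress,
               voigt_to_tensor((1 - (1 - exp(-1))) *
                                 (C %*% strain_to_voigt(small, TRUE))),
               tolerance = 1e-12)
})

test_that("D stays within [0, D_max] and non-decreasing over random load paths", {
  ec <- elastic_constants(); law <- damage_law()
  set.seed(42)
  for (rep in 1:10) {
    st <- point_state()
    crit <- if (rep %% 2) "min_principal" else "equivalent"
    prev <- 0
    for (i in 1:30) {
      out <- material_update(random_strain(0.06), st, ec, law, crit)
      st <- out$state
      expect_gte(st$D, prev)
      expect_lte(st$D, law$D_max)
      prev <- st$D
    }
    expect_identical(st$failed, st$D >= law$D_max - 1e-12)
  }
})

test_that("consistent tangent matches directional finite differences", {
  ec <- elastic_constants(); law <- damage_law()
  for (crit in c("min_principal", "equivalent")) {
    # a damaged, still-evolving state on a monotone compressive path
    eps0 <- diag(c(0.018, 0.02, -0.06))
    st <- material_update(eps0 * 0.9, point_state(), ec, law, crit)$state
    Tg <- consistent_tangent(eps0, st, ec, law, crit)
    st0 <- material_update(eps0, st, ec, law, crit)$state
    h <- 1e-7
    # probe a strain direction that increases the criterion strain
    dirs <- list(diag(c(0, 0, -1)), diag(c(1, 1, -2)))
    for (d in dirs) {
      sp <- material_update(eps0 + h * d, st, ec, law, crit)
      sm <- material_update(eps0 - h * d, st, ec, law, crit)
      num <- (strain_to_voigt(sp$stress, FALSE) -
                strain_to_voigt(sm$stress, FALSE)) / (2 * h)
      dv <- strain_to_voigt(d, engineering = TRUE)
      expect_equal(as.vector(Tg %*% dv), num, tolerance = 1e-3)
    }
    # softening: tangent axial entry is below the secant's
    expect_lt(Tg[3, 3], ((1 - st0$D) * stiffness_matrix(ec))[3, 3])
  }
})
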