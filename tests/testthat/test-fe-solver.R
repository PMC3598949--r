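test_that("element stiffness is symmetric PSD with six rigid-body modes", {
  set.seed(1)
  for (k in 1:5) {
    coords <- unit_tet + matrix(rnorm(12, sd = 0.1), 4, 3)
    if (element_volume(coords) < 1e-3) next
    K <- element_stiffness(coords, E = 1500, nu = 0.3)
    expect_lt(max(abs(K - t(K))), 1e-10 * max(abs(K)))
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6)
    expect_true(all(ev > -1e-8 * max(ev)))
  }
})

test_that("rigid translations lie in the stiffness nullspace", {
  K <- element_stiffness(unit_tet, E = 84100, nu = 0.2)
  for (ax in 1:3) {
    u <- rep(0, 12)
    u[seq(ax, 12, by = 3)] <- 1
    expect_lt(max(abs(K %*% u)), 1e-8 * max(abs(K)))
  }
})

test_that("element stiffness is linear in Young's modulus", {
  K1 <- element_stiffness(unit_tet, E = 1000, nu = 0.3)
  K2 <- element_stiffness(unit_tet, E = 2000, nu = 0.3)
  expect_equal(K2, 2 * K1, tolerance = 1e-12)
})

test_that("degenerate tetrahedra are rejected", {
  flat <- unit_tet
  flat[4, ] <- c(0.5, 0.5, 0)  # coplanar
  expect_error(element_stiffness(flat, 1000, 0.3), "degenerate")
})

test_that("patch test: affine boundary displacements reproduce sym(A) exactly", {
  mats <- material_table()
  A <- matrix(c(1e-3, 2e-4, 0,
                3e-4, -5e-4, 1e-4,
                0, 2e-4, 4e-4), 3, 3, byrow = TRUE)
  for (region in c("cancellous_bone", "follicle_pdl")) {
    err <- patch_test_error(box_mesh(c(3, 3, 3), 1, region), mats, A)
    expect_lt(err, 1e-8)
  }
  # also on an anisotropic box shape with finer pitch
  err <- patch_test_error(box_mesh(c(4, 2, 6), 0.5), mats, A)
  expect_lt(err, 1e-8)
})

test_that("uniaxial bar matches sigma = F/A and sigma_h = F/(3A)", {
  mats <- material_table()
  bar <- uniaxial_bar(n = c(3, 3, 6), pitch = 1, F_total = 90)
  sol <- solve_elasticity(bar$mesh, mats, bar$load)
  fld <- recover_strain_stress(bar$mesh, mats, sol)
  sigma <- bar$F_total / bar$A
  expect_equal(max(abs(fld$stress[, "szz"] - sigma)) / sigma, 0,
               tolerance = 1e-6)
  sh <- (fld$stress[, "sxx"] + fld$stress[, "syy"] + fld$stress[, "szz"]) / 3
  expect_equal(max(abs(sh - sigma / 3)) / (sigma / 3), 0, tolerance = 1e-6)
  # transverse stresses vanish
  expect_lt(max(abs(fld$stress[, c("sxx", "syy", "sxy", "syz", "szx")])),
            1e-6 * sigma)
  # equilibrium: reaction sum balances the applied load
  expect_lt(sol$residual, 1e-6)
  eq <- equilibrium_summary(sol)
  expect_equal(eq$reaction[3], -bar$F_total, tolerance = 1e-6)
  expect_lt(eq$relative_imbalance, 1e-6)
})

test_that("zero load with fixities gives zero displacement", {
  mats <- material_table()
  m <- box_mesh(c(2, 2, 2), 1)
  bottom <- nodes_where(m, function(x, y, z) z < 1e-9)
  fixed <- data.frame(node = rep(bottom, each = 3), axis = 1:3, value = 0)
  sol <- solve_elasticity(m, mats, load_case(nrow(m$nodes), fixed))
  expect_equal(max(abs(sol$u)), 0)
})

test_that("insufficient constraints raise a singularity error", {
  mats <- material_table()
  m <- box_mesh(c(2, 2, 2), 1)
  f <- matrix(0, nrow(m$nodes), 3); f[1, 3] <- 1
  lc <- load_case(nrow(m$nodes), data.frame(node = 1:2, axis = 3), f)
  expect_error(solve_elasticity(m, mats, lc), "singular|insufficient")
})

test_that("solutions scale linearly with the load and superpose", {
  mats <- material_table()
  bar <- uniaxial_bar(n = c(2, 2, 4), pitch = 1, F_total = 10)
  sol1 <- solve_elasticity(bar$mesh, mats, bar$load)
  lc2 <- load_case(bar$load$n_nodes, bar$load$fixed, 2 * bar$load$forces)
  sol2 <- solve_elasticity(bar$mesh, mats, lc2)
  expect_equal(sol2$u, 2 * sol1$u, tolerance = 1e-9)
  r1 <- reaction_forces(sol1); r2 <- reaction_forces(sol2)
  expect_equal(r2$force, 2 * r1$force, tolerance = 1e-9)
})

test_that("prescribed displacements are honoured exactly at fixed DOFs", {
  mats <- material_table()
  m <- box_mesh(c(2, 2, 3), 1)
  bnodes <- sort(unique(as.integer(boundary_faces(m))))
  A <- diag(c(1e-3, -2e-4, 5e-4))
  ub <- m$nodes[bnodes, , drop = FALSE] %*% t(A)
  fixed <- data.frame(node = rep(bnodes, each = 3),
                      axis = rep(1:3, length(bnodes)),
                      value = as.numeric(t(ub)))
  sol <- solve_elasticity(m, mats, load_case(nrow(m$nodes), fixed))
  expect_identical(sol$u[cbind(fixed$node, fixed$axis)], fixed$value)
})

test_that("hydrostatic stress and equivalent strain are frame-objective", {
  mats <- material_table()
  bar <- uniaxial_bar(n = c(2, 2, 4), pitch = 1, F_total = 40)
  # reference solve with a fully clamped bottom face (rotation-safe BCs)
  m <- bar$mesh
  bottom <- nodes_where(m, function(x, y, z) z < 1e-9)
  fixed <- data.frame(node = rep(bottom, each = 3),
                      axis = rep(1:3, length(bottom)), value = 0)
  lc <- load_case(nrow(m$nodes), fixed, bar$load$forces)
  sol <- solve_elasticity(m, mats, lc)
  rec <- tensor_field_records(
    m, recover_strain_stress(m, mats, sol), mats)

  set.seed(11)
  R <- random_rotation()
  m2 <- m
  m2$nodes <- m$nodes %*% t(R)
  lc2 <- load_case(nrow(m$nodes), fixed, bar$load$forces %*% t(R))
  sol2 <- solve_elasticity(m2, mats, lc2)
  rec2 <- tensor_field_records(
    m2, recover_strain_stress(m2, mats, sol2), mats)

  scale_h <- max(abs(rec$sigma_h))
  expect_lt(max(abs(rec2$sigma_h - rec$sigma_h)) / scale_h, 1e-6)
  expect_lt(max(abs(rec2$s_e - rec$s_e)) / max(rec$s_e), 1e-6)
})
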