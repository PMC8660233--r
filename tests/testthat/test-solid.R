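test_that("material constants reproduce the study's table after rounding", {
  mc <- material_constants(5000, 0.3)
  expect_equal(round(mc$G), 1923)
  expect_equal(round(mc$Lambda), 2885)
  expect_equal(mc$G, 5000 / 2.6, tolerance = 1e-12)
  ## zero Poisson ratio: G = E/2, Lambda = 0
  mc0 <- material_constants(7000, 0)
  expect_equal(mc0$G, 3500)
  expect_equal(mc0$Lambda, 0)
  ## admissibility interval is open
  expect_error(material_constants(5000, 0.5),
               class = "gradfss_invalid_material")
  expect_error(material_constants(5000, -1),
               class = "gradfss_invalid_material")
  expect_error(material_constants(-5, 0.3),
               class = "gradfss_invalid_material")
})

test_that("strain energy vanishes exactly on rigid motions", {
  mat <- solid_material()
  expect_equal(strain_energy_density(diag(3), mat), 0)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(strain_energy_density(R, mat), 0, tolerance = 1e-10)
  expect_error(strain_energy_density(diag(c(-1, 1, 1)), mat),
               class = "gradfss_inverted_element")
})

test_that("strain energy is non-negative over random admissible deformations", {
  mat <- solid_material()
  set.seed(42)
  n_ok <- 0
  while (n_ok < 1e4) {
    F <- diag(3) + matrix(rnorm(9, sd = 0.3), 3, 3)
    if (det(F) <= 0) next
    n_ok <- n_ok + 1
    expect_gte(strain_energy_density(F, mat), 0)
  }
})

test_that("small strains reduce to Hooke's law with (G, Lambda)", {
  mat <- solid_material()
  ## uniaxial stretch: W ~ eps^2 (G + Lambda/2) to leading order
  eps <- 1e-3
  W <- strain_energy_density(diag(c(1 + eps, 1, 1)), mat)
  expect_equal(W, eps^2 * (mat$G + mat$Lambda / 2), tolerance = 5e-3)
  ## linearized stress from numerical differentiation at F = I:
  ## sigma = 2 G eps + Lambda tr(eps) I for a random symmetric strain
  set.seed(7)
  E <- matrix(rnorm(9, sd = 1), 3, 3); E <- (E + t(E)) / 2
  h <- 1e-6
  S_num <- matrix(0, 3, 3)   # dW/dF at F = I + hE is P ~ sigma for small h
  for (i in 1:3) for (j in 1:3) {
    dF <- matrix(0, 3, 3); dF[i, j] <- h
    S_num[i, j] <- (strain_energy_density(diag(3) + h * E + dF, mat) -
                    strain_energy_density(diag(3) + h * E - dF, mat)) /
                   (2 * h)
  }
  S_hooke <- h * (2 * mat$G * E + mat$Lambda * sum(diag(E)) * diag(3))
  expect_equal(S_num, S_hooke, tolerance = 1e-2)
})

test_that("onion-layer tet mesh fills the hemisphere volume", {
  m <- mesh_cell_surface(cell_placement(6e-3, 25e-3), 4)
  vm <- mesh_cell_volume(m, 3)
  a <- 10e-6
  expect_equal(sum(vm$volumes), 2 / 3 * pi * a^3, tolerance = 0.01)
  expect_true(all(vm$volumes > 0))
  ## outer layer coincides with the surface mesh
  expect_equal(vm$nodes[vm$surface_nodes, ], m$nodes, tolerance = 1e-15,
               ignore_attr = TRUE)
  ## adhesion set: all z = 0 nodes, non-empty
  expect_true(all(abs(vm$nodes[vm$fixed, 3]) < 1e-12))
  expect_gt(length(vm$fixed), 0)
})

test_that("cell deformation is zero without load, linear and small with it", {
  m <- mesh_cell_surface(cell_placement(6e-3, 25e-3), 4)
  vm <- mesh_cell_volume(m, 2)
  mat <- solid_material()
  tr0 <- matrix(0, nrow(m$nodes), 3)
  d0 <- solve_cell_deformation(vm, tr0, mat)
  expect_equal(d0$max_displacement, 0)
  expect_equal(d0$energy, 0)
  ## uniform 1 Pa streamwise traction (the study's upper FSS scale)
  tr1 <- tr0; tr1[, 2] <- 1
  d1 <- cached("solid_d1", function() solve_cell_deformation(vm, tr1, mat))
  expect_true(d1$converged)
  expect_lt(d1$residual, 0.05)
  expect_true(all(d1$J > 0))
  expect_true(all(d1$W_s >= -1e-12))
  ## displacements are ~tau/E of the radius: far below the cell size,
  ## justifying one-way coupling
  a <- 10e-6
  expect_lt(d1$max_displacement, 1e-2 * a)
  expect_gt(d1$max_displacement, 1e-5 * a)
  ## near-linear response at small load
  d2 <- solve_cell_deformation(vm, 2 * tr1, mat)
  expect_equal(d2$max_displacement / d1$max_displacement, 2,
               tolerance = 1e-3)
  ## fixed base does not move
  expect_equal(max(abs(d1$displacement[vm$fixed, ])), 0)
})

test_that("mismatched traction shapes are rejected", {
  m <- mesh_cell_surface(cell_placement(6e-3, 25e-3), 4)
  vm <- mesh_cell_volume(m, 2)
  expect_error(solve_cell_deformation(vm, matrix(0, 5, 3), solid_material()),
               class = "gradfss_pairing_error")
})
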