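test_that("compiled operator kernel matches the reference R implementation", {
  set.seed(11)
  dom <- build_local_domain(single_cell_arrangement(),
                            list(tau0 = 0.4, g = 50), delta = 5e-6)
  pars <- list(mu = dom$mu, lambda = 20 * dom$mu,
               eta = 1e4 * dom$mu / dom$delta^2)
  U <- gradfss:::mac_zeros(dom)
  U$u[] <- rnorm(length(U$u)); U$v[] <- rnorm(length(U$v))
  U$w[] <- rnorm(length(U$w))
  U <- gradfss:::mask_free(U, dom)
  a1 <- gradfss:::apply_stokes_op(U, dom, pars)
  a2 <- gradfss:::apply_stokes_op_r(U, dom, pars)
  scale <- max(abs(a2$u), abs(a2$v), abs(a2$w))
  expect_lt(max(abs(a1$u - a2$u), abs(a1$v - a2$v), abs(a1$w - a2$w)) / scale,
            1e-12)
})

test_that("the operator is symmetric positive definite on free dofs", {
  set.seed(12)
  dom <- build_local_domain(single_cell_arrangement(),
                            list(tau0 = 0.4, g = 0), delta = 10e-6)
  pars <- list(mu = dom$mu, lambda = 20 * dom$mu,
               eta = 1e4 * dom$mu / dom$delta^2)
  rnd <- function() {
    U <- gradfss:::mac_zeros(dom)
    U$u[] <- rnorm(length(U$u)); U$v[] <- rnorm(length(U$v))
    U$w[] <- rnorm(length(U$w))
    gradfss:::mask_free(U, dom)
  }
  for (i in 1:3) {
    X <- rnd(); Y <- rnd()
    AX <- gradfss:::apply_stokes_op(X, dom, pars)
    AY <- gradfss:::apply_stokes_op(Y, dom, pars)
    expect_equal(gradfss:::mac_inner(AX, Y), gradfss:::mac_inner(X, AY),
                 tolerance = 1e-10)
    expect_gt(gradfss:::mac_inner(X, AX), 0)
  }
})

test_that("empty domain reproduces the imposed linear shear exactly", {
  ce <- cached_empty_uniform()
  ff <- local_floor_fss(ce$field)
  expect_lt(max(abs(ff / 0.4 - 1)), 0.005)
  ## velocity profile is the linear shear tau z / mu at every column
  dom <- ce$dom
  zc <- ((1:dom$nz) - 0.5) * dom$delta
  vprof <- ce$field$v[2 + dom$nx %/% 2, 2 + dom$ny %/% 2, 2:(dom$nz + 1)]
  expect_equal(vprof, 0.4 * zc / dom$mu, tolerance = 1e-6)
  expect_lt(ce$field$div_max, 1e-6)
})

test_that("empty domain with transverse gradient matches the background", {
  res <- cached("empty_gradient", function() {
    dom <- build_local_domain(NULL, list(tau0 = 0.4, g = 200))
    list(dom = dom, field = solve_stokes_local(dom))
  })
  ff <- local_floor_fss(res$field)
  xc <- res$dom$x0 + ((1:res$dom$nx) - 0.5) * res$dom$delta
  expect_lt(max(abs(sweep(ff, 1, 0.4 + 200 * (xc - res$dom$xc), "/") - 1)),
            0.005)
})

test_that("surface FSS scales exactly linearly with the forcing", {
  arr <- single_cell_arrangement()
  mesh <- mesh_cell_surface(arr$cells[[1]], 4)
  solve_tr <- function(tau0) {
    dom <- build_local_domain(arr, list(tau0 = tau0, g = 0), delta = 4e-6)
    compute_surface_traction(solve_stokes_local(dom), mesh)
  }
  s1 <- solve_tr(0.3)
  s2 <- solve_tr(0.6)
  expect_lt(max(abs(s2$traction - 2 * s1$traction)) / max(abs(s2$traction)),
            1e-6)
  expect_lt(max(abs(s2$fss - 2 * s1$fss)) / max(s2$fss), 1e-6)
})

test_that("apex FSS exceeds near-base FSS on a wall-attached hemisphere", {
  ut <- cached_single_units()
  sf <- gradfss:::surface_field_from_traction(ut$mesh, 0.4 * ut$t0, 2)
  th <- ut$mesh$theta_e_deg
  apex <- th > 70
  base <- th >= 2 & th < 25
  expect_gt(mean(sf$fss[apex]), mean(sf$fss[base]))
  expect_true(all(is.finite(sf$fss)))
  expect_true(all(sf$fss >= 0))
})

test_that("zero-gradient flow is mirror-symmetric fore-aft and crosswise", {
  ut <- cached_single_units()
  mesh <- ut$mesh
  sf <- gradfss:::surface_field_from_traction(mesh, 0.4 * ut$t0, 2)
  ctr <- c(mesh$placement$x, mesh$placement$y)
  key <- function(x, y) paste(round(x, 12), round(y, 12))
  ## phi -> -phi (fore-aft reflection through the flow axis)
  rel <- sweep(mesh$nodes[, 1:2], 2, ctr)
  ix <- match(key(rel[, 1], -rel[, 2]), key(rel[, 1], rel[, 2]))
  expect_true(all(is.finite(ix)))
  v <- sf$valid
  expect_lt(max(abs(sf$fss[v] - sf$fss[ix][v])) / max(sf$fss), 1e-5)
  ## +x vs -x hemisphere means agree within 1% (no gradient, no bias)
  part <- partition_sectors(mesh, c(1, 0))
  r <- compute_rav(sf, part)
  expect_lt(abs(r$rav), 0.01)
})

test_that("neighbours in a tight hexagonal packing shield the central cell", {
  hex2 <- cached("hex2_tau", function() {
    ch <- build_chamber(1, 1, 0.5e-3, 0.5e-3)
    arr <- place_hexagonal(ch, c(0.5, 0.5), 2e-6)
    dom <- build_local_domain(arr, list(tau0 = 0.4, g = 0))
    mesh <- mesh_cell_surface(arr$cells[[1]], 4)
    compute_surface_traction(solve_stokes_local(dom), mesh)
  })
  iso <- gradfss:::surface_field_from_traction(
    cached_single_units()$mesh, 0.4 * cached_single_units()$t0, 2)
  expect_lte(field_mean_fss(hex2), field_mean_fss(iso))
})

test_that("drag on a wall-attached hemisphere matches the refined-grid reference", {
  ## reference: this solver at delta = 1.5 um (80 x 80 x 34 grid, tau0 = 1
  ## Pa, g = 0), computed once and frozen
  drag_ref <- 1.5082160e-09
  f <- cached("single_tau_field", function() {
    dom <- build_local_domain(single_cell_arrangement(),
                              list(tau0 = 1, g = 0))
    solve_stokes_local(dom)
  })
  drag <- cell_drag_force(f)
  expect_equal(drag[2], drag_ref, tolerance = 0.05)
  ## transverse and vertical force components are comparatively small
  expect_lt(abs(drag[1]), 0.05 * abs(drag[2]))
})

test_that("mean surface FSS converges under grid refinement", {
  cr <- cached("convergence", function()
    convergence_study(single_cell_arrangement(), list(tau0 = 0.4, g = 0)))
  expect_true(cr$converged)
  ch <- cr$levels$change_pct
  expect_lt(ch[length(ch)], 2)
  ## determinism: repeating the finest level reproduces the value exactly
  dom <- build_local_domain(single_cell_arrangement(),
                            list(tau0 = 0.4, g = 0),
                            delta = cr$levels$delta[3])
  mesh <- mesh_cell_surface(single_cell_arrangement()$cells[[1]], 4)
  m2 <- mean_surface_fss(compute_surface_traction(
    solve_stokes_local(dom), mesh, probe_dist = cr$probe_dist))
  expect_identical(m2, cr$levels$mean_fss[3])
})

test_that("local domains enforce the submodel margin rule", {
  expect_error(build_local_domain(single_cell_arrangement(),
                                  list(tau0 = 0.4, g = 0),
                                  margin_radii = 3),
               class = "gradfss_domain_error")
  dom <- build_local_domain(single_cell_arrangement(),
                            list(tau0 = 0.4, g = 0))
  a <- 10e-6
  expect_gte(dom$nx * dom$delta / 2, 6 * a)   # footprint + 5 radii
})
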