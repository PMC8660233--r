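test_that("chamber height profile is linear with the stated end heights", {
  ch <- study_chamber()
  expect_equal(chamber_height(ch, 0), 0.2e-3)
  expect_equal(chamber_height(ch, 12e-3), 0.8e-3)
  expect_equal(chamber_height(ch, 6e-3), 0.5e-3)   # midpoint of the wedge
  ## parallel-plate limit
  pp <- build_chamber(12e-3, 50e-3, 0.5e-3, 0.5e-3)
  xs <- seq(0, 12e-3, length.out = 7)
  expect_equal(chamber_height(pp, xs), rep(0.5e-3, 7))
  ## exact linearity
  x <- seq(0, 12e-3, length.out = 23)
  expect_equal(chamber_height(ch, x), 0.2e-3 + (0.6e-3) * x / 12e-3)
})

test_that("invalid chamber dimensions are rejected", {
  expect_error(build_chamber(-1, 50e-3, 0.2e-3, 0.8e-3),
               class = "gradfss_invalid_geometry")
  expect_error(build_chamber(12e-3, 50e-3, 0, 0.8e-3),
               class = "gradfss_invalid_geometry")
  expect_error(build_chamber(12e-3, 50e-3, 0.8e-3, 0.2e-3),
               class = "gradfss_invalid_geometry")
  expect_error(chamber_height(study_chamber(), 13e-3),
               class = "gradfss_domain_error")
})

test_that("discrete replicates reproduce the 10-40 mm / 5 mm layout", {
  ch <- study_chamber()
  arr <- place_discrete_replicates(ch, 6e-3, 10e-3, 40e-3, 7)
  ys <- vapply(arr$cells, function(p) p$y, numeric(1))
  expect_equal(ys, seq(10e-3, 40e-3, by = 5e-3))
  expect_equal(diff(ys), rep(5e-3, 6))
  xs <- vapply(arr$cells, function(p) p$x, numeric(1))
  expect_true(all(xs == 6e-3))
  ## n = 1 degenerate case
  one <- place_discrete_replicates(ch, 6e-3, 25e-3, 25e-3, 1)
  expect_length(one$cells, 1)
  expect_equal(one$cells[[1]]$y, 25e-3)
  ## placements outside the floor are rejected
  expect_error(place_discrete_replicates(ch, 6e-3, -1e-3, 40e-3, 7),
               class = "gradfss_out_of_bounds")
  expect_error(place_discrete_replicates(ch, 12e-3, 10e-3, 40e-3, 7),
               class = "gradfss_out_of_bounds")
})

test_that("hexagonal packing has 7 cells at d = 2 a + gap for hemispheres", {
  ch <- study_chamber()
  ctr <- c(6e-3, 25e-3)
  for (gap in c(0, 2e-6, 20e-6, 40e-6)) {
    arr <- place_hexagonal(ch, ctr, gap)
    expect_length(arr$cells, 7)
    expect_equal(arr$central, 1L)
    d <- vapply(arr$cells[-1], function(p)
      sqrt((p$x - ctr[1])^2 + (p$y - ctr[2])^2), numeric(1))
    expect_equal(d, rep(2 * 10e-6 + gap, 6), tolerance = 1e-12)
  }
  ## neighbour azimuths at 60-degree spacing, one aligned with +x
  arr <- place_hexagonal(ch, ctr, 20e-6)
  az <- sort(vapply(arr$cells[-1], function(p)
    atan2(p$y - ctr[2], p$x - ctr[1]) * 180 / pi %% 360, numeric(1)) %% 360)
  expect_equal(az, c(0, 60, 120, 180, 240, 300), tolerance = 1e-9)
  ## 60-degree rotation maps the neighbour set onto itself
  rot <- place_hexagonal(ch, ctr, 20e-6, rotation_deg = 60)
  pos <- function(a) sort(vapply(a$cells[-1], function(p)
    complex(real = round(p$x - ctr[1], 12),
            imaginary = round(p$y - ctr[2], 12)), complex(1)))
  expect_equal(pos(rot), pos(arr))
  ## a ring whose outer neighbour footprint leaves the floor
  expect_error(place_hexagonal(ch, c(45e-6, 25e-3), 20e-6),
               class = "gradfss_out_of_bounds")
})

test_that("cap surface mesh satisfies area, normal and angle invariants", {
  p <- cell_placement(6e-3, 25e-3)
  m <- mesh_cell_surface(p, 4)
  expect_gte(nrow(m$nodes), 200)
  ## total area weight within 1% of the analytic hemisphere area 2 pi a^2
  expect_equal(sum(m$area_weight), 2 * pi * (10e-6)^2, tolerance = 0.01)
  ## unit outward (radial) normals
  expect_equal(sqrt(rowSums(m$normals^2)), rep(1, nrow(m$nodes)))
  ctr <- c(p$x, p$y, p$z_center)
  rad <- sweep(m$nodes, 2, ctr)
  expect_true(all(rowSums(rad * m$normals) > 0))
  ## angle conventions
  expect_true(all(m$theta_e_deg >= 0 & m$theta_e_deg <= 90))
  expect_true(all(m$phi_deg >= 0 & m$phi_deg < 360))
  apex <- which.max(m$nodes[, 3])
  expect_equal(m$theta_e_deg[apex], 90)
  ## a rim node on the +x side: zero elevation, zero azimuth
  rim_x <- which.min(abs(m$nodes[, 1] - (p$x + 10e-6)))
  expect_equal(m$theta_e_deg[rim_x], 0, tolerance = 1e-9)
  expect_equal(m$phi_deg[rim_x], 0, tolerance = 1e-9)
  ## nodes sit on the sphere
  expect_equal(sqrt(rowSums(rad^2)), rep(10e-6, nrow(m$nodes)))
})

test_that("cap area converges under mesh refinement", {
  p <- cell_placement(6e-3, 25e-3)
  areas <- vapply(4:6, function(l)
    sum(mesh_cell_surface(p, l)$area_weight), numeric(1))
  expect_lt(abs(areas[3] - areas[2]) / areas[3], 0.001)
})

test_that("too-coarse surface meshes are rejected", {
  p <- cell_placement(6e-3, 25e-3)
  expect_error(mesh_cell_surface(p, 3), class = "gradfss_resolution_error")
})

test_that("non-hemispherical caps keep their analytic area and rim angle", {
  p <- cell_placement(6e-3, 25e-3, contact_angle_deg = 60)
  m <- mesh_cell_surface(p, 4)
  a <- 10e-6
  expect_equal(sum(m$area_weight), 2 * pi * a^2 * (1 - cos(pi / 3)),
               tolerance = 0.01)
  expect_equal(min(m$theta_e_deg), 30, tolerance = 1e-9)  # rim at 90 - 60
  expect_equal(p$base_radius, a * sin(pi / 3))
})
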