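mesh_fixture <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- mesh_cell_surface(cell_placement(6e-3, 25e-3), 4)
    m
  }
})

test_that("sector partition quarters the surface about the gradient axis", {
  m <- mesh_fixture()
  part <- partition_sectors(m, c(1, 0))
  expect_setequal(levels(part$label),
                  c("SHFSS", "LATERAL_UP", "SLFSS", "LATERAL_DOWN"))
  expect_false(any(is.na(part$label)))
  ## sector centres and the counter-clockwise tie-break
  sector_of <- gradfss:::sector_of
  expect_equal(as.character(sector_of(0, c(1, 0))), "SHFSS")
  expect_equal(as.character(sector_of(180, c(1, 0))), "SLFSS")
  expect_equal(as.character(sector_of(44.999, c(1, 0))), "SHFSS")
  expect_equal(as.character(sector_of(45, c(1, 0))), "LATERAL_UP")
  expect_equal(as.character(sector_of(135, c(1, 0))), "SLFSS")
  expect_equal(as.character(sector_of(225, c(1, 0))), "LATERAL_DOWN")
  expect_equal(as.character(sector_of(315, c(1, 0))), "SHFSS")
  ## rotating the gradient direction rotates the labels with it
  part_y <- partition_sectors(m, c(0, 2))
  node_90 <- which.min(abs(m$phi_deg - 90) + abs(m$theta_e_deg - 45))
  expect_equal(as.character(part_y$label[node_90]), "SHFSS")
  expect_error(partition_sectors(m, c(0, 0)),
               class = "gradfss_direction_error")
})

test_that("the four sectors carry equal area within 1%", {
  m <- mesh_fixture()
  part <- partition_sectors(m, c(1, 0))
  areas <- tapply(m$area_weight, part$label, sum)
  expect_lt(diff(range(areas)) / mean(areas), 0.01)
})

test_that("elevation bands select the expected rings", {
  m <- mesh_fixture()
  b30 <- select_band(m, 30); b60 <- select_band(m, 60)
  ## the 30-degree band sits nearer the adhesion region than the 60-degree
  expect_lt(mean(m$nodes[b30$in_band, 3]), mean(m$nodes[b60$in_band, 3]))
  ## enough nodes per sector inside each band at default resolution
  part <- partition_sectors(m, c(1, 0))
  for (tb in c(30, 45, 60)) {
    b <- select_band(m, tb)
    per_sector <- table(part$label[b$in_band])
    expect_true(all(per_sector >= 10))
  }
  ## degenerate window covers the whole dorsal surface
  ball <- select_band(m, 45, 90)
  expect_true(all(ball$in_band))
  ## near-apex band
  btop <- select_band(m, 89, 7.5)
  expect_true(all(m$theta_e_deg[btop$in_band] > 80))
  expect_error(select_band(m, 95), class = "gradfss_resolution_error")
  ## a sliver between two node rings is empty
  expect_error(select_band(m, 36.5, half_width = 0.01),
               class = "gradfss_resolution_error")
})

test_that("a uniform field has ratio 1 and RAV 0", {
  m <- mesh_fixture()
  sf <- synth_surface_field(m, synth_field_spec(tau0 = 0.7, eps = 0,
                                                shape_exponent = 0))
  r <- compute_rav(sf, partition_sectors(m, c(1, 0)))
  expect_equal(r$ratio, 1, tolerance = 1e-12)
  expect_equal(r$rav, 0, tolerance = 1e-12)
})

test_that("RAV recovers prescribed polarization against the quadrature oracle", {
  m <- mesh_fixture()
  part <- partition_sectors(m, c(1, 0))
  for (eps in c(0.01, 0.05, 0.1)) {
    sf <- synth_surface_field(m, synth_field_spec(tau0 = 0.4, eps = eps))
    r <- compute_rav(sf, part)
    expect_equal(r$rav, rav_quadrature_oracle(eps), tolerance = 0.01)
  }
  ## bands too: the factorized field polarizes every band equally
  for (tb in c(30, 45, 60)) {
    sf <- synth_surface_field(m, synth_field_spec(tau0 = 0.4, eps = 0.1))
    r <- compute_rav(sf, part, select_band(m, tb))
    expect_equal(r$rav,
                 rav_quadrature_oracle(0.1, theta_range = c(tb - 7.5,
                                                            tb + 7.5)),
                 tolerance = 0.01)
  }
})

test_that("reversing the gradient direction inverts the RAV ratio", {
  m <- mesh_fixture()
  sf <- synth_surface_field(m, synth_field_spec(tau0 = 0.4, eps = 0.1))
  r_fwd <- compute_rav(sf, partition_sectors(m, c(1, 0)))
  r_rev <- compute_rav(sf, partition_sectors(m, c(-1, 0)))
  expect_equal(r_fwd$ratio * r_rev$ratio, 1, tolerance = 1e-10)
})

test_that("mismatched meshes and empty sectors raise classed errors", {
  m <- mesh_fixture()
  m2 <- mesh_cell_surface(cell_placement(6e-3, 25e-3), 5)
  sf <- synth_surface_field(m, synth_field_spec(tau0 = 0.4))
  expect_error(compute_rav(sf, partition_sectors(m2, c(1, 0))),
               class = "gradfss_pairing_error")
})

test_that("replicate aggregation reports mean and SD per condition", {
  tb <- data.frame(gradient = rep(c(0.05, 0.1), each = 7),
                   magnitude = 0.1,
                   rav = c(rep(0.02, 7), rep(0.04, 7)),
                   ratio = c(rep(1.02, 7), rep(1.04, 7)))
  agg <- aggregate_replicates(tb, c("gradient", "magnitude"))
  expect_equal(nrow(agg), 2)
  expect_equal(agg$n, c(7, 7))
  expect_equal(agg$rav_sd, c(0, 0))         # identical replicates
  expect_equal(agg$rav_mean, c(0.02, 0.04))
  expect_equal(agg$ratio_mean, c(1.02, 1.04))
  ## two groups of one value each: means equal the values
  one <- data.frame(g = c("a", "b"), rav = c(0.1, 0.3))
  agg1 <- aggregate_replicates(one, "g")
  expect_equal(agg1$rav_mean, c(0.1, 0.3))
  expect_equal(agg1$rav_sd, c(0, 0))
  expect_error(aggregate_replicates(tb[0, ], "gradient"),
               class = "gradfss_grouping_error")
})
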