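test_that("lubrication closed form gives the end-of-chamber FSS values", {
  ch <- study_chamber()
  fc <- study_flow(200)   # dp = 100 Pa
  ## tau = h * dp / (2 l): 0.2 Pa at the shallow side, 0.8 Pa at the deep
  expect_equal(lubrication_wall_fss(ch, fc, 0), 0.2)
  expect_equal(lubrication_wall_fss(ch, fc, 12e-3), 0.8)
  expect_equal(lubrication_fss_gradient(ch, fc), 50)   # Pa/m = 0.05 Pa/mm
  ## parallel plates: no transverse gradient
  pp <- build_chamber(12e-3, 50e-3, 0.5e-3, 0.5e-3)
  xs <- seq(0, 12e-3, length.out = 11)
  expect_equal(lubrication_wall_fss(pp, fc, xs), rep(0.5, 11))
  expect_error(lubrication_wall_fss(ch, fc, 13e-3),
               class = "gradfss_domain_error")
})

test_that("inverse placement finds the width position of a target FSS", {
  ch <- study_chamber(); fc <- study_flow(200)
  expect_equal(locate_x_for_fss(ch, fc, 0.4), 4e-3)
  expect_equal(locate_x_for_fss(ch, fc, 0.2), 0)
  expect_equal(lubrication_wall_fss(ch, fc, locate_x_for_fss(ch, fc, 0.65)),
               0.65)
  expect_error(locate_x_for_fss(ch, fc, 0.1), class = "gradfss_range_error")
  expect_error(locate_x_for_fss(ch, fc, 0.9), class = "gradfss_range_error")
})

test_that("gradient fitting recovers closed-form slopes exactly", {
  ch <- study_chamber()
  x <- seq(0, 12e-3, length.out = 121)
  fit1 <- fit_fss_gradient(x, lubrication_wall_fss(ch, study_flow(200), x))
  expect_equal(fit1$slope_Pa_per_mm, 0.05, tolerance = 1e-10)
  expect_equal(fit1$r_squared, 1)
  fit2 <- fit_fss_gradient(x, lubrication_wall_fss(ch, study_flow(100), x))
  expect_equal(fit2$slope_Pa_per_mm, 0.10, tolerance = 1e-10)
  ## parallel plates: zero slope
  pp <- build_chamber(12e-3, 50e-3, 0.5e-3, 0.5e-3)
  fit0 <- fit_fss_gradient(x, lubrication_wall_fss(pp, study_flow(200), x))
  expect_equal(fit0$slope_Pa_per_mm, 0, tolerance = 1e-12)
  expect_error(fit_fss_gradient(x[1:30], rep(1, 30), window = c(2e-3, 2.5e-3)),
               class = "gradfss_fit_error")
})

test_that("cross-section solve matches lubrication away from side walls", {
  ch <- study_chamber(); fc <- study_flow(200)
  cs <- cached("cs_dp100", function()
    solve_cross_section_flow(ch, fc, 192, 48))
  lub <- lubrication_wall_fss(ch, fc, cs$x)
  keep <- cs$x >= 2e-3 & cs$x <= 10e-3
  expect_lt(max(abs(cs$tau_floor[keep] / lub[keep] - 1)), 0.02)
  ## no-slip: boundary velocities are zero, interior positive
  expect_true(all(cs$u[1, ] == 0) && all(cs$u[, 1] == 0))
  expect_true(all(cs$u[, ncol(cs$u)] == 0))
  expect_true(all(cs$u[2:(nrow(cs$u) - 1), 2:(ncol(cs$u) - 1)] > 0))
})

test_that("cross-section floor shear is linear in the pressure drop", {
  ch <- study_chamber()
  cs1 <- cached("cs_dp100", function()
    solve_cross_section_flow(ch, study_flow(200), 192, 48))
  cs2 <- solve_cross_section_flow(ch, study_flow(100), 192, 48)
  expect_equal(cs2$tau_floor, 2 * cs1$tau_floor, tolerance = 1e-10)
  expect_equal(cs2$u, 2 * cs1$u, tolerance = 1e-10)
})

test_that("cross-section floor shear converges under grid refinement", {
  ch <- study_chamber(); fc <- study_flow(200)
  a <- solve_cross_section_flow(ch, fc, 128, 32)
  b <- solve_cross_section_flow(ch, fc, 256, 64)
  keep <- a$x >= 2e-3 & a$x <= 10e-3
  ix <- match(round(a$x[keep], 12), round(b$x, 12))
  expect_true(all(is.finite(ix)))
  expect_lt(max(abs(a$tau_floor[keep] / b$tau_floor[ix] - 1)), 0.005)
})

test_that("channel Reynolds number is deep in the laminar regime", {
  ch <- study_chamber()
  for (po in c(200, 100, 0))
    expect_lt(channel_reynolds(ch, study_flow(po)), 1000)
})

test_that("solver rejects under-resolved grids and bad conditions", {
  ch <- study_chamber()
  expect_error(solve_cross_section_flow(ch, study_flow(200), 16, 48),
               class = "gradfss_resolution_error")
  expect_error(flow_conditions(100, 300), class = "gradfss_invalid_flow")
  expect_error(flow_conditions(300, 200, mu = 0),
               class = "gradfss_invalid_flow")
})
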