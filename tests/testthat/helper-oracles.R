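## Independent oracles and shared fixtures for the test suite.

## Direct 2D quadrature of the closed-form polarized surface field
##   f(theta, phi) = tau0 * sin(theta)^shape * (1 + eps * cos(phi))
## over the SHFSS / SLFSS sectors (midpoint rule on a fine grid, with the
## spherical area element cos(theta) dtheta dphi).  Entirely independent of
## the package's mesh and quadrature machinery.
rav_quadrature_oracle <- function(eps, shape = 1, theta_range = c(2, 90),
                                  tau0 = 1, n = 1500) {
  th <- seq(theta_range[1], theta_range[2], length.out = n + 1)
  th <- (th[-1] + th[-(n + 1)]) / 2 * pi / 180
  sector_mean <- function(phi_lo, phi_hi) {
    ph <- seq(phi_lo, phi_hi, length.out = n + 1)
    ph <- (ph[-1] + ph[-(n + 1)]) / 2 * pi / 180
    fl <- outer(tau0 * sin(th)^shape, 1 + eps * cos(ph))
    area <- outer(cos(th), rep(1, n))
    sum(fl * area) / sum(area)
  }
  m_sh <- sector_mean(-45, 45)
  m_sl <- sector_mean(135, 225)
  m_sh / m_sl - 1
}

## The study chamber and flow conditions.
study_chamber <- function() build_chamber(12e-3, 50e-3, 0.2e-3, 0.8e-3)
study_flow <- function(p_out = 200) flow_conditions(300, p_out)

## A single hemisphere on a neutral (parallel-plate) host chamber, placed
## away from walls; used for local-solve fixtures.
single_cell_arrangement <- function() {
  ch <- build_chamber(1, 1, 0.5e-3, 0.5e-3)
  place_discrete_replicates(ch, 0.5, 0.5, 0.5, 1)
}

## Shared cache of expensive solves (one R session per test run, shared
## across test files).
.solve_cache <- new.env(parent = emptyenv())
cached <- function(name, builder) {
  if (is.null(.solve_cache[[name]])) .solve_cache[[name]] <- builder()
  .solve_cache[[name]]
}

## Empty local domain (no cell) under a uniform 0.4 Pa background.
cached_empty_uniform <- function() cached("empty_uniform", function() {
  dom <- build_local_domain(NULL, list(tau0 = 0.4, g = 0))
  list(dom = dom, field = solve_stokes_local(dom))
})

## Single-hemisphere unit tractions at pipeline defaults (tau0 = 1 / g = 1).
cached_single_units <- function() cached("single_units", function() {
  cfg <- experiment_config(backend = "stokes", arrangement = "single")
  gradfss:::unit_tractions(cfg, NA_real_)
})

## Hexagonal (gap 20 um) unit tractions at pipeline defaults.
cached_hex20_units <- function() cached("hex20_units", function() {
  cfg <- experiment_config(backend = "stokes", arrangement = "hexagonal")
  gradfss:::unit_tractions(cfg, 20e-6)
})

## Quadrature-based area-weighted mean FSS of a surface field (package
## quadrature; used where tests need a scalar summary of a field).
field_mean_fss <- function(sf, theta_min = 2) {
  q <- gradfss:::surface_quadrature(sf$mesh, sf$fss)
  k <- q$theta_deg >= theta_min
  sum(q$f[k] * q$w[k]) / sum(q$w[k])
}
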