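## End-to-end experiment driver: from a single configuration, place cells,
## solve (or synthesize) the local FSS fields, and tabulate RAV per
## condition.
##
## Stokes linearity is exploited throughout: for each arrangement geometry
## only two unit solves are run (unit FSS magnitude with zero gradient, and
## zero magnitude with unit gradient); every (magnitude, gradient)
## condition is a superposition of the two nodal traction fields.  In the
## fully developed background, replicates along the flow axis see
## identical local physics, so their RAV values coincide exactly (and the
## replicate SD is zero by construction).

#' Experiment configuration
#'
#' Assembles (and validates) the configuration describing one experiment
#' grid: chamber, flow conditions, cell geometry, arrangements, analytics
#' parameters and solver resolutions.  Defaults reproduce the study
#' conditions: a 12 x 50 mm chamber with heights 0.2/0.8 mm, inlet 300 Pa
#' with outlets {200, 100, 0} Pa (transverse gradients 0.05 / 0.10 / 0.15
#' Pa/mm by the closed form), FSS magnitudes {0.1, 0.4, 0.8} Pa, seven
#' replicate positions from 10 to 40 mm, and hexagonal gaps {2, 20, 40} um.
#'
#' @param chamber List `w`, `l`, `h1`, `h2` (m).
#' @param fluid List `rho` (kg/m^3), `mu` (Pa s).
#' @param p_in Inlet pressure (Pa).
#' @param p_outs Outlet pressures (Pa), one per gradient condition.
#' @param gradients_Pa_per_mm Optional explicit transverse gradients
#'   (Pa/mm).  When given, conditions are run in "imposed" mode (the local
#'   background is prescribed directly, whether or not the chamber can
#'   realize it); when `NULL` they derive from `p_outs`.
#' @param magnitudes_Pa Target local FSS magnitudes (Pa).
#' @param arrangement `"single"` or `"hexagonal"`.
#' @param gaps Hexagonal surface-to-surface gaps (m).
#' @param replicates Number of single-cell replicates along the flow axis.
#' @param y_range Flow-axis range of the replicates (m).
#' @param cell List `radius` (m), `contact_angle_deg`, `mesh_level`.
#' @param bands Band elevations (degrees) for per-band RAV; `NULL` for
#'   whole-sector only.
#' @param band_half_width Degrees.
#' @param cutoff_deg Contact-line exclusion (degrees).
#' @param backend `"stokes"` (local viscous solve) or `"synthetic"`
#'   (closed-form stand-in fields; same table schema, runs in seconds).
#' @param delta Stokes grid spacing (m).
#' @param solver Extra arguments passed to [solve_stokes_local()].
#' @param eps_factor Synthetic-backend polarization per unit `g a / tau0`.
#' @param sigma Synthetic noise SD (Pa).
#' @param seed RNG seed (synthetic noise only; solves are deterministic).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(
    chamber = list(w = 12e-3, l = 50e-3, h1 = 0.2e-3, h2 = 0.8e-3),
    fluid = list(rho = 1000, mu = 1e-3),
    p_in = 300, p_outs = c(200, 100, 0),
    gradients_Pa_per_mm = NULL,
    magnitudes_Pa = c(0.1, 0.4, 0.8),
    arrangement = c("single", "hexagonal"),
    gaps = c(2e-6, 20e-6, 40e-6),
    replicates = 7, y_range = c(10e-3, 40e-3),
    cell = list(radius = 10e-6, contact_angle_deg = 90, mesh_level = 4),
    bands = c(30, 45, 60), band_half_width = 7.5, cutoff_deg = 2,
    backend = c("stokes", "synthetic"),
    delta = 2.5e-6, solver = list(),
    eps_factor = 1, sigma = 0, seed = NULL) {
  arrangement <- match.arg(arrangement)
  backend <- match.arg(backend)
  geom <- build_chamber(chamber$w, chamber$l, chamber$h1, chamber$h2)
  cfg <- list(geom = geom, fluid = fluid, p_in = p_in, p_outs = p_outs,
              gradients_Pa_per_mm = gradients_Pa_per_mm,
              magnitudes_Pa = magnitudes_Pa,
              arrangement = arrangement, gaps = gaps,
              replicates = replicates, y_range = y_range, cell = cell,
              bands = bands, band_half_width = band_half_width,
              cutoff_deg = cutoff_deg, backend = backend, delta = delta,
              solver = solver, eps_factor = eps_factor, sigma = sigma,
              seed = seed)
  class(cfg) <- "experiment_config"
  cfg
}

## In-memory cache of unit solves, keyed by the geometric sub-configuration.
.gradfss_cache <- new.env(parent = emptyenv())

#' Clear the unit-solve cache
#' @export
clear_solve_cache <- function() {
  rm(list = ls(.gradfss_cache), envir = .gradfss_cache)
  invisible(NULL)
}

## Two unit Stokes solves for one arrangement geometry; returns the nodal
## traction matrices of the analyzed cell for tau0 = 1 Pa (t0) and
## g = 1 Pa/m (t1), plus the analysis mesh.
unit_tractions <- function(cfg, gap = NA_real_) {
  key <- paste("unit", cfg$arrangement, format(gap, digits = 12),
               cfg$cell$radius, cfg$cell$contact_angle_deg,
               cfg$cell$mesh_level, cfg$delta, cfg$cutoff_deg,
               sep = "|")
  hit <- .gradfss_cache[[key]]
  if (!is.null(hit)) return(hit)
  big <- build_chamber(1, 1, 0.5e-3, 0.5e-3)  # neutral host for placement
  ctr <- c(0.5, 0.5)
  arr <- if (cfg$arrangement == "hexagonal") {
    place_hexagonal(big, ctr, gap, radius = cfg$cell$radius,
                    contact_angle_deg = cfg$cell$contact_angle_deg)
  } else {
    place_discrete_replicates(big, ctr[1], ctr[2], ctr[2], 1,
                              radius = cfg$cell$radius,
                              contact_angle_deg = cfg$cell$contact_angle_deg)
  }
  mesh <- mesh_cell_surface(arr$cells[[1]], cfg$cell$mesh_level)
  tr <- lapply(list(list(tau0 = 1, g = 0), list(tau0 = 0, g = 1)),
               function(bg) {
    dom <- build_local_domain(arr, bg, mu = cfg$fluid$mu, delta = cfg$delta)
    fld <- do.call(solve_stokes_local, c(list(dom), cfg$solver))
    compute_surface_traction(fld, mesh, cutoff_deg = cfg$cutoff_deg)$traction
  })
  out <- list(mesh = mesh, t0 = tr[[1]], t1 = tr[[2]])
  assign(key, out, envir = .gradfss_cache)
  out
}

## Rebuild a surface_fss_field from a (superposed) traction matrix.
surface_field_from_traction <- function(mesh, traction, cutoff_deg = 2) {
  tn <- rowSums(traction * mesh$normals)
  tt <- traction - mesh$normals * tn
  structure(list(mesh = mesh, traction = traction,
                 fss = sqrt(rowSums(tt^2)),
                 valid = mesh$theta_e_deg >= cutoff_deg,
                 probe_dist = NA_real_, cutoff_deg = cutoff_deg),
            class = "surface_fss_field")
}

#' Run an experiment grid
#'
#' Executes the full condition grid of a configuration: for each transverse
#' gradient and target FSS magnitude, places the arrangement (via
#' [locate_x_for_fss()] when the chamber can realize the condition,
#' flagged "imposed" otherwise), obtains the cell-surface FSS field from
#' the selected backend, and computes whole-sector and per-band RAV for
#' the analyzed cell (the central cell of hexagonal packings).
#'
#' @param cfg An [experiment_config()].
#' @return An `experiment_bundle`: `rav_table` (one row per condition x
#'   replicate x band), the configuration, and the gradient conditions.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  cond0 <- flow_conditions(cfg$p_in, min(cfg$p_outs),
                           rho = cfg$fluid$rho, mu = cfg$fluid$mu)
  ## gradient conditions: (label Pa/mm, g Pa/m, dp or NA)
  conds <- if (is.null(cfg$gradients_Pa_per_mm)) {
    lapply(cfg$p_outs, function(po) {
      fc <- flow_conditions(cfg$p_in, po, rho = cfg$fluid$rho,
                            mu = cfg$fluid$mu)
      list(g = lubrication_fss_gradient(cfg$geom, fc), dp = fc$dp, fc = fc)
    })
  } else {
    lapply(cfg$gradients_Pa_per_mm, function(gm)
      list(g = gm * 1e3, dp = NA_real_, fc = NULL))
  }
  gaps <- if (cfg$arrangement == "hexagonal") cfg$gaps else NA_real_
  ys <- seq(cfg$y_range[1], cfg$y_range[2], length.out = cfg$replicates)
  rows <- list()
  for (gap in gaps) {
    ut <- if (cfg$backend == "stokes") unit_tractions(cfg, gap) else {
      big <- build_chamber(1, 1, 0.5e-3, 0.5e-3)
      arr1 <- place_discrete_replicates(big, 0.5, 0.5, 0.5, 1,
                                        radius = cfg$cell$radius,
                                        contact_angle_deg = cfg$cell$contact_angle_deg)
      list(mesh = mesh_cell_surface(arr1$cells[[1]], cfg$cell$mesh_level))
    }
    part <- partition_sectors(ut$mesh, c(1, 0))
    band_sel <- lapply(cfg$bands, function(tb)
      select_band(ut$mesh, tb, cfg$band_half_width))
    for (ci in seq_along(conds)) {
      cn <- conds[[ci]]
      for (tau0 in cfg$magnitudes_Pa) {
        placed <- if (!is.null(cn$fc))
          tryCatch(list(x = locate_x_for_fss(cfg$geom, cn$fc, tau0),
                        achievable = TRUE),
                   gradfss_range_error = function(e)
                     list(x = cfg$geom$w / 2, achievable = FALSE))
        else list(x = NA_real_, achievable = NA)
        sfield <- if (cfg$backend == "stokes") {
          surface_field_from_traction(
            ut$mesh, tau0 * ut$t0 + cn$g * ut$t1, cfg$cutoff_deg)
        } else {
          eps <- min(0.9, cfg$eps_factor * abs(cn$g) * cfg$cell$radius / tau0)
          synth_surface_field(
            ut$mesh,
            synth_field_spec(tau0 = tau0, eps = eps, sigma = cfg$sigma,
                             seed = if (cfg$sigma > 0)
                               cfg$seed + ci * 1000 + round(tau0 * 100)
                             else NULL),
            cutoff_deg = cfg$cutoff_deg)
        }
        ravs <- c(list(whole = compute_rav(sfield, part)),
                  setNames(lapply(band_sel, function(b)
                    compute_rav(sfield, part, b)),
                    sprintf("%g", cfg$bands)))
        for (rep_i in seq_len(if (cfg$arrangement == "single")
                                cfg$replicates else 1L)) {
          for (bn in names(ravs)) {
            rv <- ravs[[bn]]
            rows[[length(rows) + 1L]] <- data.frame(
              backend = cfg$backend,
              arrangement = cfg$arrangement,
              gap_um = gap * 1e6,
              gradient_Pa_per_mm = cn$g / 1e3,
              dp_Pa = cn$dp,
              magnitude_Pa = tau0,
              x_mm = placed$x * 1e3,
              y_mm = if (cfg$arrangement == "single") ys[rep_i] * 1e3
                     else NA_real_,
              replicate = rep_i,
              achievable = placed$achievable,
              band = bn,
              mean_sh_Pa = rv$mean_sh_Pa,
              mean_sl_Pa = rv$mean_sl_Pa,
              ratio = rv$ratio,
              rav = rv$rav)
          }
        }
      }
    }
  }
  structure(list(rav_table = do.call(rbind, rows), config = cfg,
                 conditions = conds),
            class = "experiment_bundle")
}

#' @export
print.experiment_bundle <- function(x, ...) {
  tb <- x$rav_table
  cat(sprintf(
    "<experiment_bundle> %s/%s: %d rows (%d conditions x bands x replicates)\n",
    x$config$backend, x$config$arrangement, nrow(tb),
    length(unique(paste(tb$gradient_Pa_per_mm, tb$magnitude_Pa, tb$gap_um)))))
  invisible(x)
}

#' Check an experiment bundle against the study's qualitative findings
#'
#' Evaluates the qualitative properties the simulated grids are expected to
#' reproduce: positive RAV under every nonzero gradient; larger RAV at the
#' steepest gradient for the lowest magnitude; the 30-degree band RAV
#' exceeding the 45- and 60-degree bands; near-zero RAV for zero-gradient
#' controls; and RAV decreasing with FSS magnitude under the steeper
#' gradients.
#'
#' @param bundle A [run_experiment()] result.
#' @param tol_zero Zero-gradient |RAV| threshold (default 0.01).
#' @return Data frame: `property`, `applicable`, `pass`, `margin` (the
#'   worst-case signed margin; positive = satisfied).
#' @export
validate_against_properties <- function(bundle, tol_zero = 0.01) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  tb <- bundle$rav_table
  tb1 <- tb[tb$replicate == 1, ]
  res <- list()
  add <- function(property, applicable, pass = NA, margin = NA_real_)
    res[[length(res) + 1L]] <<- data.frame(
      property = property, applicable = applicable, pass = pass,
      margin = margin)
  nz <- tb1$gradient_Pa_per_mm > 0 & tb1$band == "whole"
  if (any(nz)) add("rav_positive_under_gradient", TRUE,
                   all(tb1$rav[nz] > 0), min(tb1$rav[nz]))
  else add("rav_positive_under_gradient", FALSE)
  ## gradient monotonicity at the lowest magnitude
  lo <- tb1[tb1$band == "whole" & tb1$gradient_Pa_per_mm > 0 &
              tb1$magnitude_Pa == min(tb1$magnitude_Pa), ]
  if (length(unique(lo$gradient_Pa_per_mm)) >= 2 && nrow(lo) >= 2) {
    margins <- vapply(split(lo, paste(lo$gap_um)), function(d) {
      d$rav[which.max(d$gradient_Pa_per_mm)] -
        d$rav[which.min(d$gradient_Pa_per_mm)]
    }, numeric(1))
    add("rav_increases_with_gradient_at_low_magnitude", TRUE,
        all(margins > 0), min(margins))
  } else add("rav_increases_with_gradient_at_low_magnitude", FALSE)
  ## band ordering, per nonzero-gradient condition
  bb <- tb1[tb1$band != "whole" & tb1$gradient_Pa_per_mm > 0, ]
  if (nrow(bb) > 0 && all(c("30", "45", "60") %in% bb$band)) {
    sp <- split(bb, paste(bb$gradient_Pa_per_mm, bb$magnitude_Pa, bb$gap_um))
    margins <- vapply(sp, function(d) {
      r30 <- d$rav[d$band == "30"]
      min(r30 - d$rav[d$band == "45"], r30 - d$rav[d$band == "60"])
    }, numeric(1))
    add("band30_rav_largest", TRUE, all(margins > 0), min(margins))
  } else add("band30_rav_largest", FALSE)
  ## zero-gradient control
  zg <- tb1[tb1$band == "whole" & tb1$gradient_Pa_per_mm == 0, ]
  if (nrow(zg) > 0)
    add("zero_gradient_rav_near_zero", TRUE,
        all(abs(zg$rav) < tol_zero), tol_zero - max(abs(zg$rav)))
  else add("zero_gradient_rav_near_zero", FALSE)
  ## magnitude monotonicity at steeper gradients (>= 0.1 Pa/mm)
  st <- tb1[tb1$band == "whole" & tb1$gradient_Pa_per_mm >= 0.1 - 1e-9, ]
  if (length(unique(st$magnitude_Pa)) >= 2 && nrow(st) >= 2) {
    sp <- split(st, paste(st$gradient_Pa_per_mm, st$gap_um))
    margins <- vapply(sp, function(d) {
      d <- d[order(d$magnitude_Pa), ]
      min(-diff(d$rav))
    }, numeric(1))
    add("rav_decreases_with_magnitude_at_steep_gradient", TRUE,
        all(margins > 0), min(margins))
  } else add("rav_decreases_with_magnitude_at_steep_gradient", FALSE)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
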