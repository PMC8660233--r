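## Background (cell-free) flow in the wedge channel and the floor wall FSS.
##
## Two routes to the same field: a lubrication closed form (the channel is
## locally a parallel-plate Poiseuille flow, tau_w(x) = h(x) * dp / (2 l)),
## and a fully developed cross-section solve of the axial momentum balance
##   mu * (u_xx + u_zz) = -G_p,  G_p = (p_in - p_out) / l
## on the trapezoidal cross-section with no-slip walls, used to validate the
## closed form away from the side walls.

#' Flow conditions for the chamber
#'
#' @param p_in,p_out Inlet and outlet pressures (Pa), `p_in > p_out`.
#' @param rho Fluid density (kg/m^3); default water/medium, 1000.
#' @param mu Dynamic viscosity (Pa s); default 1e-3.
#' @return A `flow_conditions` object; `$Gp` is the axial pressure gradient
#'   magnitude `(p_in - p_out) / l`, filled in per chamber by the solvers.
#' @export
flow_conditions <- function(p_in = 300, p_out = 200, rho = 1000, mu = 1e-3) {
  if (p_in <= p_out)
    stop_gradfss("need p_in > p_out for forward flow", "gradfss_invalid_flow")
  if (rho <= 0 || mu <= 0)
    stop_gradfss("rho and mu must be positive", "gradfss_invalid_flow")
  structure(list(p_in = p_in, p_out = p_out, dp = p_in - p_out,
                 rho = rho, mu = mu),
            class = "flow_conditions")
}

#' Lubrication (locally parallel-plate) floor wall shear stress
#'
#' For a slowly leaning cover (`dh/dx` = 0.05 here) each width station is a
#' plane Poiseuille flow of local height `h(x)`, so the floor FSS is
#' `tau_w(x) = h(x) * (p_in - p_out) / (2 l)` — linear in `x` because `h`
#' is.
#'
#' @param geom A [build_chamber()] object.
#' @param cond A [flow_conditions()] object.
#' @param x Width coordinate(s) (m) in `[0, w]`.
#' @return Floor wall shear stress (Pa) at each `x`.
#' @export
lubrication_wall_fss <- function(geom, cond, x) {
  h <- chamber_height(geom, x)   # also validates x in [0, w]
  h * cond$dp / (2 * geom$l)
}

#' Closed-form transverse FSS gradient of the chamber
#'
#' `d tau_w / dx = (dh/dx) * dp / (2 l)`, in Pa/m.
#' @inheritParams lubrication_wall_fss
#' @export
lubrication_fss_gradient <- function(geom, cond) {
  (geom$h2 - geom$h1) / geom$w * cond$dp / (2 * geom$l)
}

#' Width position giving a target floor FSS
#'
#' Inverts the lubrication closed form to find where a cell must sit to
#' experience a prescribed FSS magnitude.
#'
#' @inheritParams lubrication_wall_fss
#' @param tau_target Target floor FSS (Pa); must lie within
#'   `[tau_w(0), tau_w(w)]`.
#' @return Width coordinate x (m).
#' @export
locate_x_for_fss <- function(geom, cond, tau_target) {
  tau0 <- lubrication_wall_fss(geom, cond, 0)
  tau1 <- lubrication_wall_fss(geom, cond, geom$w)
  if (tau_target < tau0 - 1e-12 || tau_target > tau1 + 1e-12)
    stop_gradfss(sprintf(
      "target FSS %.3g Pa outside achievable range [%.3g, %.3g] Pa",
      tau_target, tau0, tau1), "gradfss_range_error")
  if (tau1 == tau0) return(0)   # parallel plates: any x works; return 0
  h_t <- 2 * geom$l * tau_target / cond$dp
  (h_t - geom$h1) / (geom$h2 - geom$h1) * geom$w
}

#' Channel Reynolds number audit
#'
#' `Re = rho * U_mean * D_h / mu` with the local parallel-plate mean speed
#' `U = h^2 dp / (12 mu l)` and hydraulic diameter `D_h = 2 h`, evaluated at
#' the deep side (worst case). Used to audit the laminar-flow assumption.
#'
#' @inheritParams lubrication_wall_fss
#' @export
channel_reynolds <- function(geom, cond) {
  h <- geom$h2
  U <- h^2 * cond$dp / (12 * cond$mu * geom$l)
  cond$rho * U * 2 * h / cond$mu
}

#' Fully developed cross-section flow solve
#'
#' Solves the axial momentum balance of fully developed laminar flow,
#' `mu * laplacian(u_y) = -(p_in - p_out)/l`, over the trapezoidal
#' cross-section `0 <= z <= h(x)`, `0 <= x <= w`, with no-slip on the floor,
#' the leaning cover and both side walls.  The sloped cover is handled by
#' the height-mapped coordinate `eta = z / h(x)` (second-order central
#' differences, including the metric cross terms), and the linear system is
#' solved directly with a sparse LU.
#'
#' @inheritParams lubrication_wall_fss
#' @param nx,nz Number of grid cells across the width and (mapped) height;
#'   both at least 32.
#' @return A `cross_section_field`: `x` and `eta` grids, velocity matrix
#'   `u` (m/s, rows = x), floor shear `tau_floor(x)` (Pa), and conditions.
#' @export
solve_cross_section_flow <- function(geom, cond, nx = 256, nz = 64) {
  if (nx < 32 || nz < 32)
    stop_gradfss("need nx, nz >= 32", "gradfss_resolution_error")
  Gp <- cond$dp / geom$l
  w <- geom$w
  dh <- (geom$h2 - geom$h1) / w
  ## interior nodes i = 1..nx-1 (x), j = 1..nz-1 (eta)
  xi  <- seq(0, w, length.out = nx + 1)
  eta <- seq(0, 1, length.out = nz + 1)
  dxi <- w / nx; deta <- 1 / nz
  ii <- rep(1:(nx - 1), each = nz - 1)
  jj <- rep(1:(nz - 1), times = nx - 1)
  x_i <- xi[ii + 1]; e_j <- eta[jj + 1]
  h_i <- geom$h1 + dh * x_i
  alpha <- -e_j * dh / h_i                  # d eta / dx metric
  cxx <- 1
  cee <- alpha^2 + 1 / h_i^2
  cxe <- 2 * alpha
  ce  <- 2 * e_j * (dh / h_i)^2
  idx <- function(i, j) (i - 1) * (nz - 1) + j   # 0 for out-of-domain
  n_un <- (nx - 1) * (nz - 1)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  add <- function(r, i, j, v) {
    keep <- i >= 1 & i <= nx - 1 & j >= 1 & j <= nz - 1 & v != 0
    rows <<- c(rows, r[keep]); cols <<- c(cols, idx(i[keep], j[keep]))
    vals <<- c(vals, v[keep])
  }
  r <- idx(ii, jj)
  add(r, ii, jj, -2 * cxx / dxi^2 - 2 * cee / deta^2)
  add(r, ii + 1L, jj, rep(cxx / dxi^2, n_un))
  add(r, ii - 1L, jj, rep(cxx / dxi^2, n_un))
  add(r, ii, jj + 1L, cee / deta^2 + ce / (2 * deta))
  add(r, ii, jj - 1L, cee / deta^2 - ce / (2 * deta))
  cc <- cxe / (4 * dxi * deta)
  add(r, ii + 1L, jj + 1L,  cc)
  add(r, ii - 1L, jj - 1L,  cc)
  add(r, ii + 1L, jj - 1L, -cc)
  add(r, ii - 1L, jj + 1L, -cc)
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(n_un, n_un))
  b <- rep(-Gp / cond$mu, n_un)
  u_int <- as.numeric(Matrix::solve(A, b))
  u <- matrix(0, nx + 1, nz + 1)
  u[cbind(ii + 1L, jj + 1L)] <- u_int
  ## floor shear: tau = mu/h * du/deta at eta = 0, one-sided second order
  tau_floor <- cond$mu / (geom$h1 + dh * xi) *
    (4 * u[, 2] - u[, 3]) / (2 * deta)
  structure(list(x = xi, eta = eta, u = u, tau_floor = tau_floor,
                 geom = geom, cond = cond, nx = nx, nz = nz),
            class = "cross_section_field")
}

#' Fit the transverse FSS gradient of a floor-shear profile
#'
#' Least-squares line through `(x, tau_w)` samples restricted to an interior
#' window (default 2–10 mm) that excludes the side-wall boundary layers.
#'
#' @param x Width positions (m).
#' @param tau Floor FSS samples (Pa) at `x`.
#' @param window Length-2 fit window in metres; samples outside are dropped.
#' @return A `fss_gradient_fit` list: `slope_Pa_per_mm`, `intercept_Pa`,
#'   `r_squared`, `window`, `n`.
#' @export
fit_fss_gradient <- function(x, tau, window = c(2e-3, 10e-3)) {
  keep <- x >= window[1] & x <= window[2]
  if (sum(keep) < 10)
    stop_gradfss("need >= 10 samples inside the fit window",
                 "gradfss_fit_error")
  x_mm <- x[keep] * 1e3
  fit <- lm(tau[keep] ~ x_mm)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((tau[keep] - mean(tau[keep]))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope_Pa_per_mm = unname(coef(fit)[2]),
                 intercept_Pa = unname(coef(fit)[1]),
                 r_squared = r2, window = window, n = sum(keep)),
            class = "fss_gradient_fit")
}

#' @export
print.fss_gradient_fit <- function(x, ...) {
  cat(sprintf("<fss_gradient_fit> g = %.4g Pa/mm, R^2 = %.6f (n = %d)\n",
              x$slope_Pa_per_mm, x$r_squared, x$n))
  invisible(x)
}

#' Floor-shear profile of a cross-section solve as a data frame
#'
#' @param field A [solve_cross_section_flow()] result.
#' @return `data.frame(x_mm, tau_wall_Pa)`.
#' @export
floor_fss_profile <- function(field) {
  data.frame(x_mm = field$x * 1e3, tau_wall_Pa = field$tau_floor)
}
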