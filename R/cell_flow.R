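## Local viscous flow around an arrangement of wall-attached cells.
##
## The cells are ~10 um tall in a channel >= 200 um deep and 12 mm wide, so
## instead of meshing both scales we solve steady incompressible Stokes flow
## in a small box around the arrangement (a submodel), imposing the
## background channel flow on the box faces: a linear shear
##   v_y(x, z) = (tau0 + g (x - x_c)) * z / mu
## carrying both the local FSS magnitude tau0 and its transverse gradient g.
## Discretization: staggered (MAC) finite differences; the cell bodies enter
## through smoothed volume penalization (a Brinkman drag that forces the
## velocity to zero inside the solid); incompressibility is enforced by an
## augmented-Lagrangian (Uzawa) outer loop around a matrix-free
## Jacobi-preconditioned conjugate-gradient inner solve.  Everything is
## deterministic and linear in the boundary forcing, which the pipeline
## exploits by superposing unit solves.

#' Local flow sub-domain around a cell arrangement
#'
#' Builds the box, grid and solid-fraction masks for a local Stokes solve.
#' The box is centred on the (central) cell, extends at least
#' `margin_radii` cell radii beyond the outermost cell footprint laterally,
#' and `height_radii` radii vertically (truncating the channel; the
#' background shear profile is imposed on the top face).
#'
#' @param arrangement A `cell_arrangement` (or `NULL` for an empty,
#'   cell-free domain, used for validation).
#' @param background List with `tau0` (floor FSS at the box centre, Pa) and
#'   `g` (transverse FSS gradient, Pa/m).  Use
#'   [background_at()] to derive it from a chamber position.
#' @param mu Dynamic viscosity (Pa s).
#' @param delta Grid spacing (m); default 2.5 um (8 cells per cell radius).
#' @param margin_radii Lateral clearance beyond the outermost cell, in cell
#'   radii; at least 5 (the submodel validity rule).
#' @param height_radii Box height in cell radii (default 5).
#' @param center Optional `(x, y)` box centre (m); defaults to the central
#'   cell, or `(0, 0)` for an empty domain.
#' @param radius Cell radius used for the empty-domain box size (m).
#' @return A `local_domain` object.
#' @export
build_local_domain <- function(arrangement, background, mu = 1e-3,
                               delta = 2.5e-6, margin_radii = 5,
                               height_radii = 5, center = NULL,
                               radius = 10e-6) {
  if (margin_radii < 5)
    stop_gradfss("lateral margin must be >= 5 cell radii",
                 "gradfss_domain_error")
  cells <- if (is.null(arrangement)) list() else arrangement$cells
  if (length(cells) > 0) {
    a <- cells[[1]]$radius
    if (is.null(center)) center <- c(cells[[1]]$x, cells[[1]]$y)
    reach <- max(vapply(cells, function(p)
      sqrt((p$x - center[1])^2 + (p$y - center[2])^2) + p$base_radius,
      numeric(1)))
  } else {
    a <- radius
    if (is.null(center)) center <- c(0, 0)
    reach <- 0
  }
  ext <- reach + margin_radii * a
  nx <- 2L * as.integer(ceiling(ext / delta))   # even: keeps the box (and
  ny <- nx                                      # the solid mask) mirror-
  nz <- as.integer(ceiling(height_radii * a / delta))  # symmetric about x_c
  x0 <- center[1] - nx / 2 * delta
  y0 <- center[2] - ny / 2 * delta
  dom <- list(
    arrangement = arrangement, background = background, mu = mu,
    delta = delta, nx = nx, ny = ny, nz = nz,
    x0 = x0, y0 = y0, z0 = 0,
    xc = center[1], yc = center[2],
    z_top = nz * delta
  )
  class(dom) <- "local_domain"
  dom$chi <- solid_fraction_masks(dom)
  dom
}

#' Background descriptor from a chamber position
#'
#' Evaluates the lubrication floor FSS and its transverse gradient at a
#' width position, packaging them for [build_local_domain()].
#'
#' @inheritParams lubrication_wall_fss
#' @param x Width position of the arrangement centre (m).
#' @export
background_at <- function(geom, cond, x) {
  list(tau0 = lubrication_wall_fss(geom, cond, x),
       g = lubrication_fss_gradient(geom, cond))
}

#' @export
print.local_domain <- function(x, ...) {
  cat(sprintf(
    "<local_domain> %d x %d x %d cells (delta %.3g um), box %.3g x %.3g x %.3g um, %d cell(s)\n",
    x$nx, x$ny, x$nz, x$delta * 1e6,
    x$nx * x$delta * 1e6, x$ny * x$delta * 1e6, x$nz * x$delta * 1e6,
    if (is.null(x$arrangement)) 0L else length(x$arrangement$cells)))
  invisible(x)
}

## Smoothed solid fraction at every velocity face: chi = 1 deep inside a
## cell, 0 in the fluid, linear across one grid cell at the surface.  The
## smoothing makes grid refinement behave smoothly (no stair-step jumps in
## the effective radius).
solid_fraction_masks <- function(dom) {
  d <- dom$delta
  cells <- if (is.null(dom$arrangement)) list() else dom$arrangement$cells
  frac_at <- function(xv, yv, zv) {
    A <- array(0, c(length(xv), length(yv), length(zv)))
    if (length(cells) == 0) return(A)
    dist <- array(Inf, dim(A))
    for (p in cells) {
      dd <- sqrt(outer(outer((xv - p$x)^2, (yv - p$y)^2, "+"),
                       (zv - p$z_center)^2, "+")) - p$radius
      dist <- pmin(dist, dd)
    }
    pmin(1, pmax(0, 0.5 - dist / d))
  }
  xf <- dom$x0 + (0:dom$nx) * d            # face coords
  xc <- dom$x0 + ((1:dom$nx) - 0.5) * d    # centre coords
  yf <- dom$y0 + (0:dom$ny) * d
  yc <- dom$y0 + ((1:dom$ny) - 0.5) * d
  zf <- (0:dom$nz) * d
  zc <- ((1:dom$nz) - 0.5) * d
  ## real-position fractions; embedded later into padded arrays
  list(u = frac_at(xf, yc, zc),   # (nx+1, ny, nz)
       v = frac_at(xc, yf, zc),   # (nx, ny+1, nz)
       w = frac_at(xc, yc, zf))   # (nx, ny, nz+1)
}

## ---- padded MAC arrays -----------------------------------------------------
## u: dim (nx+1, ny+2, nz+2), real at [1:(nx+1), 2:(ny+1), 2:(nz+1)]
## v: dim (nx+2, ny+1, nz+2), real at [2:(nx+1), 1:(ny+1), 2:(nz+1)]
## w: dim (nx+2, ny+2, nz+1), real at [2:(nx+1), 2:(ny+1), 1:(nz+1)]
## Ghost layers implement tangential no-slip / background Dirichlet walls;
## boundary-normal faces are Dirichlet degrees of freedom.

mac_zeros <- function(dom) {
  list(u = array(0, c(dom$nx + 1, dom$ny + 2, dom$nz + 2)),
       v = array(0, c(dom$nx + 2, dom$ny + 1, dom$nz + 2)),
       w = array(0, c(dom$nx + 2, dom$ny + 2, dom$nz + 1)))
}

## Background axial velocity v_y(x, z) = (tau0 + g (x - xc)) z / mu
vbg_fun <- function(dom) {
  b <- dom$background
  function(x, z) outer((b$tau0 + b$g * (x - dom$xc)) / dom$mu, z)
}

## Fill ghost layers.  hom = TRUE uses zero boundary values (the CG
## operator); hom = FALSE uses the background Dirichlet data.
ghost_fill <- function(U, dom, hom = TRUE) {
  nx <- dom$nx; ny <- dom$ny; nz <- dom$nz
  u <- U$u; v <- U$v; w <- U$w
  ## u: tangential bc = 0 on y walls, floor, top
  u[, 1, ] <- -u[, 2, ];        u[, ny + 2, ] <- -u[, ny + 1, ]
  u[, , 1] <- -u[, , 2];        u[, , nz + 2] <- -u[, , nz + 1]
  ## w: tangential bc = 0 on x and y walls
  w[1, , ] <- -w[2, , ];        w[nx + 2, , ] <- -w[nx + 1, , ]
  w[, 1, ] <- -w[, 2, ];        w[, ny + 2, ] <- -w[, ny + 1, ]
  ## v: tangential on x walls (background) and floor/top
  if (hom) {
    v[1, , ] <- -v[2, , ];      v[nx + 2, , ] <- -v[nx + 1, , ]
    v[, , 1] <- -v[, , 2];      v[, , nz + 2] <- -v[, , nz + 1]
  } else {
    vb <- vbg_fun(dom)
    zc_pad <- ((0:(nz + 1)) - 0.5) * dom$delta       # padded z centres
    bc_x0 <- vb(dom$x0, zc_pad)[1, ]                 # vector over k
    bc_x1 <- vb(dom$x0 + nx * dom$delta, zc_pad)[1, ]
    v[1, , ] <- matrix(bc_x0 * 2, ny + 1, nz + 2, byrow = TRUE) - v[2, , ]
    v[nx + 2, , ] <- matrix(bc_x1 * 2, ny + 1, nz + 2, byrow = TRUE) - v[nx + 1, , ]
    v[, , 1] <- -v[, , 2]                            # floor: v = 0
    xc_pad <- dom$x0 + ((0:(nx + 1)) - 0.5) * dom$delta
    bc_top <- vb(xc_pad, dom$z_top)[, 1]             # vector over i
    v[, , nz + 2] <- matrix(bc_top * 2, nx + 2, ny + 1) - v[, , nz + 1]
  }
  list(u = u, v = v, w = w)
}

## Set the Dirichlet (boundary-normal) faces of an inhomogeneous state.
set_dirichlet <- function(U, dom) {
  nz <- dom$nz; nx <- dom$nx; ny <- dom$ny
  vb <- vbg_fun(dom)
  xc <- dom$x0 + ((1:nx) - 0.5) * dom$delta
  zc <- ((1:nz) - 0.5) * dom$delta
  vface <- vb(xc, zc)                               # (nx, nz)
  U$v[2:(nx + 1), 1, 2:(nz + 1)] <- vface           # inflow
  U$v[2:(nx + 1), ny + 1, 2:(nz + 1)] <- vface      # outflow
  ## u normal faces (x walls) and w normal faces (floor/top) are zero
  U
}

## Zero every non-free position (ghosts + Dirichlet normal faces).
mask_free <- function(U, dom) {
  nx <- dom$nx; ny <- dom$ny; nz <- dom$nz
  u <- array(0, dim(U$u)); v <- array(0, dim(U$v)); w <- array(0, dim(U$w))
  if (nx >= 2)
    u[2:nx, 2:(ny + 1), 2:(nz + 1)] <- U$u[2:nx, 2:(ny + 1), 2:(nz + 1)]
  if (ny >= 2)
    v[2:(nx + 1), 2:ny, 2:(nz + 1)] <- U$v[2:(nx + 1), 2:ny, 2:(nz + 1)]
  if (nz >= 2)
    w[2:(nx + 1), 2:(ny + 1), 2:nz] <- U$w[2:(nx + 1), 2:(ny + 1), 2:nz]
  list(u = u, v = v, w = w)
}

## MAC divergence at cell centres, (nx, ny, nz); uses only real positions.
mac_div <- function(U, dom) {
  nx <- dom$nx; ny <- dom$ny; nz <- dom$nz; d <- dom$delta
  (U$u[2:(nx + 1), 2:(ny + 1), 2:(nz + 1)] -
     U$u[1:nx,      2:(ny + 1), 2:(nz + 1)] +
   U$v[2:(nx + 1), 2:(ny + 1), 2:(nz + 1)] -
     U$v[2:(nx + 1), 1:ny,      2:(nz + 1)] +
   U$w[2:(nx + 1), 2:(ny + 1), 2:(nz + 1)] -
     U$w[2:(nx + 1), 2:(ny + 1), 1:nz]) / d
}

## Gradient of a centre scalar onto interior faces, embedded in padded arrays.
mac_grad <- function(q, dom) {
  nx <- dom$nx; ny <- dom$ny; nz <- dom$nz; d <- dom$delta
  G <- mac_zeros(dom)
  G$u[2:nx, 2:(ny + 1), 2:(nz + 1)] <-
    (q[2:nx, , ] - q[1:(nx - 1), , ]) / d
  G$v[2:(nx + 1), 2:ny, 2:(nz + 1)] <-
    (q[, 2:ny, ] - q[, 1:(ny - 1), ]) / d
  G$w[2:(nx + 1), 2:(ny + 1), 2:nz] <-
    (q[, , 2:nz] - q[, , 1:(nz - 1)]) / d
  G
}

## 7-point Laplacian over the real region of one padded component.
lap_component <- function(A, d) {
  di <- dim(A)
  i <- 2:(di[1] - 1); j <- 2:(di[2] - 1); k <- 2:(di[3] - 1)
  out <- array(0, di)
  out[i, j, k] <- (A[i + 1, j, k] + A[i - 1, j, k] +
                   A[i, j + 1, k] + A[i, j - 1, k] +
                   A[i, j, k + 1] + A[i, j, k - 1] - 6 * A[i, j, k]) / d^2
  out
}

## The SPD operator A U = -mu lap U - lambda grad(div U) + eta chi U,
## restricted to free dofs.  `hom` selects ghost data (TRUE inside CG).
## The stencil runs in compiled code; apply_stokes_op_r is the reference
## R implementation, kept for cross-checking the kernel.
apply_stokes_op <- function(U, dom, pars, hom = TRUE) {
  Ug <- ghost_fill(U, dom, hom = hom)
  out <- stokes_apply_kernel(Ug$u, Ug$v, Ug$w,
                             dom$chi$u, dom$chi$v, dom$chi$w,
                             dom$nx, dom$ny, dom$nz,
                             dom$delta, pars$mu, pars$lambda, pars$eta)
  list(u = array(out$u, dim(U$u)),
       v = array(out$v, dim(U$v)),
       w = array(out$w, dim(U$w)))
}

apply_stokes_op_r <- function(U, dom, pars, hom = TRUE) {
  Ug <- ghost_fill(U, dom, hom = hom)
  d <- dom$delta
  dv <- mac_div(Ug, dom)
  G <- mac_grad(dv, dom)
  nx <- dom$nx; ny <- dom$ny; nz <- dom$nz
  out <- list(
    u = -pars$mu * lap_component(Ug$u, d) - pars$lambda * G$u,
    v = -pars$mu * lap_component(Ug$v, d) - pars$lambda * G$v,
    w = -pars$mu * lap_component(Ug$w, d) - pars$lambda * G$w
  )
  ## penalization on real positions
  out$u[, 2:(ny + 1), 2:(nz + 1)] <- out$u[, 2:(ny + 1), 2:(nz + 1)] +
    pars$eta * dom$chi$u * Ug$u[, 2:(ny + 1), 2:(nz + 1)]
  out$v[2:(nx + 1), , 2:(nz + 1)] <- out$v[2:(nx + 1), , 2:(nz + 1)] +
    pars$eta * dom$chi$v * Ug$v[2:(nx + 1), , 2:(nz + 1)]
  out$w[2:(nx + 1), 2:(ny + 1), ] <- out$w[2:(nx + 1), 2:(ny + 1), ] +
    pars$eta * dom$chi$w * Ug$w[2:(nx + 1), 2:(ny + 1), ]
  mask_free(out, dom)
}

mac_inner <- function(A, B) sum(A$u * B$u) + sum(A$v * B$v) + sum(A$w * B$w)
mac_axpy <- function(alpha, X, Y)   # Y + alpha X
  list(u = Y$u + alpha * X$u, v = Y$v + alpha * X$v, w = Y$w + alpha * X$w)

## Jacobi preconditioner: diagonal of the operator (uniform part + drag).
jacobi_inv <- function(dom, pars) {
  d0 <- 6 * pars$mu / dom$delta^2 + 2 * pars$lambda / dom$delta^2
  M <- mac_zeros(dom)
  nx <- dom$nx; ny <- dom$ny; nz <- dom$nz
  M$u[, 2:(ny + 1), 2:(nz + 1)] <- d0 + pars$eta * dom$chi$u
  M$v[2:(nx + 1), , 2:(nz + 1)] <- d0 + pars$eta * dom$chi$v
  M$w[2:(nx + 1), 2:(ny + 1), ] <- d0 + pars$eta * dom$chi$w
  Mi <- list(u = 1 / M$u, v = 1 / M$v, w = 1 / M$w)
  Mi$u[!is.finite(Mi$u)] <- 0; Mi$v[!is.finite(Mi$v)] <- 0
  Mi$w[!is.finite(Mi$w)] <- 0
  mask_free(Mi, dom)
}

pcg_solve <- function(dom, pars, b, x0, tol, maxit) {
  Mi <- pars$Mi
  x <- x0
  r <- mac_axpy(-1, apply_stokes_op(x, dom, pars), b)
  z <- list(u = Mi$u * r$u, v = Mi$v * r$v, w = Mi$w * r$w)
  p <- z
  rz <- mac_inner(r, z)
  ref <- sqrt(mac_inner(b, list(u = Mi$u * b$u, v = Mi$v * b$v,
                                w = Mi$w * b$w)))
  if (ref == 0) return(list(x = x0, iters = 0L, relres = 0))
  it <- 0L
  repeat {
    relres <- sqrt(max(rz, 0)) / ref
    if (relres < tol || it >= maxit) break
    Ap <- apply_stokes_op(p, dom, pars)
    alpha <- rz / mac_inner(p, Ap)
    x <- mac_axpy(alpha, p, x)
    r <- mac_axpy(-alpha, Ap, r)
    z <- list(u = Mi$u * r$u, v = Mi$v * r$v, w = Mi$w * r$w)
    rz_new <- mac_inner(r, z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- mac_axpy(beta, p, z)   # p <- z + beta p
    it <- it + 1L
  }
  list(x = x, iters = it, relres = sqrt(max(rz, 0)) / ref)
}

#' Solve steady Stokes flow in a local domain
#'
#' Computes the steady creeping-flow velocity and pressure around the
#' embedded cells, driven by the background shear imposed on the box faces.
#' Incompressibility is enforced by an augmented-Lagrangian outer loop
#' (pressure update `p <- p - lambda * div u`) around a conjugate-gradient
#' solve of the penalized momentum operator, so the result is
#' divergence-free to the reported `div_max` and exactly linear in the
#' background forcing.
#'
#' @param dom A [build_local_domain()] object.
#' @param tol Relative CG residual tolerance (default 1e-8).
#' @param n_outer Augmented-Lagrangian outer iterations (default 4).
#' @param lambda_factor AL penalty as a multiple of `mu` (default 20).
#' @param pen_factor Brinkman drag as a multiple of `mu / delta^2`
#'   (default 1e4); sets the residual slip velocity inside the solid.
#' @param max_cg Iteration cap per inner solve.
#' @return A `local_stokes_field` with padded velocity arrays `u`, `v`, `w`,
#'   pressure `p` (cell centres), `div_max`, iteration counts, and the
#'   domain.
#' @export
solve_stokes_local <- function(dom, tol = 1e-8, n_outer = 4,
                               lambda_factor = 20, pen_factor = 1e4,
                               max_cg = 4000) {
  stopifnot(inherits(dom, "local_domain"))
  pars <- list(mu = dom$mu,
               lambda = lambda_factor * dom$mu,
               eta = pen_factor * dom$mu / dom$delta^2)
  pars$Mi <- jacobi_inv(dom, pars)
  Ubc <- set_dirichlet(mac_zeros(dom), dom)
  ## b0 = -(A_affine Ubc): operator applied with inhomogeneous ghosts
  b0 <- apply_stokes_op(Ubc, dom, pars, hom = FALSE)
  b0 <- list(u = -b0$u, v = -b0$v, w = -b0$w)
  p <- array(0, c(dom$nx, dom$ny, dom$nz))
  x <- mac_zeros(dom)
  iters <- integer(0); relres <- NA_real_
  vscale <- max(abs(Ubc$v))
  for (outer in seq_len(n_outer)) {
    Gp <- mac_grad(p, dom)
    b <- list(u = b0$u - Gp$u, v = b0$v - Gp$v, w = b0$w - Gp$w)
    b <- mask_free(b, dom)
    sol <- pcg_solve(dom, pars, b, x, tol, max_cg)
    x <- sol$x; iters <- c(iters, sol$iters); relres <- sol$relres
    Ufull <- list(u = Ubc$u + x$u, v = Ubc$v + x$v, w = Ubc$w + x$w)
    dv <- mac_div(Ufull, dom)
    p <- p - pars$lambda * dv
  }
  div_max <- max(abs(dv)) * dom$delta / max(vscale, .Machine$double.eps)
  if (relres > 100 * tol)
    stop_gradfss(sprintf(
      "Stokes solve did not converge: final CG relative residual %.3g",
      relres), "gradfss_convergence_error")
  structure(list(u = Ufull$u, v = Ufull$v, w = Ufull$w, p = p,
                 domain = dom, div_max = div_max, cg_iters = iters,
                 relres = relres),
            class = "local_stokes_field")
}

#' @export
print.local_stokes_field <- function(x, ...) {
  cat(sprintf(
    "<local_stokes_field> %d x %d x %d, CG iters %s, relres %.2g, div %.2g\n",
    x$domain$nx, x$domain$ny, x$domain$nz,
    paste(x$cg_iters, collapse = "+"), x$relres, x$div_max))
  invisible(x)
}

## ---- derived fields --------------------------------------------------------

## Velocity-gradient tensor and pressure at cell centres.
center_fields <- function(field) {
  dom <- field$domain
  nx <- dom$nx; ny <- dom$ny; nz <- dom$nz; d <- dom$delta
  jr <- 2:(ny + 1); kr <- 2:(nz + 1); ir <- 2:(nx + 1)
  u <- field$u; v <- field$v; w <- field$w
  uc <- 0.5 * (u[1:nx, jr, kr] + u[2:(nx + 1), jr, kr])
  vc <- 0.5 * (v[ir, 1:ny, kr] + v[ir, 2:(ny + 1), kr])
  wc <- 0.5 * (w[ir, jr, 1:nz] + w[ir, jr, 2:(nz + 1)])
  ddx <- function(F) {
    out <- array(0, dim(F)); n <- dim(F)[1]
    out[2:(n - 1), , ] <- (F[3:n, , ] - F[1:(n - 2), , ]) / (2 * d)
    out[1, , ] <- (F[2, , ] - F[1, , ]) / d
    out[n, , ] <- (F[n, , ] - F[n - 1, , ]) / d
    out
  }
  ddy <- function(F) aperm(ddx(aperm(F, c(2, 1, 3))), c(2, 1, 3))
  ddz <- function(F) aperm(ddx(aperm(F, c(3, 2, 1))), c(3, 2, 1))
  list(
    dudx = (u[2:(nx + 1), jr, kr] - u[1:nx, jr, kr]) / d,
    dvdy = (v[ir, 2:(ny + 1), kr] - v[ir, 1:ny, kr]) / d,
    dwdz = (w[ir, jr, 2:(nz + 1)] - w[ir, jr, 1:nz]) / d,
    dudy = ddy(uc), dudz = ddz(uc),
    dvdx = ddx(vc), dvdz = ddz(vc),
    dwdx = ddx(wc), dwdy = ddy(wc),
    p = field$p, uc = uc, vc = vc, wc = wc
  )
}

## Vectorized trilinear interpolation of a centre field at points (m).
interp_center <- function(F, dom, px, py, pz) {
  d <- dom$delta
  gx <- (px - dom$x0) / d + 0.5
  gy <- (py - dom$y0) / d + 0.5
  gz <- pz / d + 0.5
  nx <- dom$nx; ny <- dom$ny; nz <- dom$nz
  i0 <- pmin(pmax(floor(gx), 1), nx - 1); tx <- pmin(pmax(gx - i0, 0), 1)
  j0 <- pmin(pmax(floor(gy), 1), ny - 1); ty <- pmin(pmax(gy - j0, 0), 1)
  k0 <- pmin(pmax(floor(gz), 1), nz - 1); tz <- pmin(pmax(gz - k0, 0), 1)
  val <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    wgt <- (if (di == 1) tx else 1 - tx) *
           (if (dj == 1) ty else 1 - ty) *
           (if (dk == 1) tz else 1 - tz)
    val <- val + wgt * F[cbind(i0 + di, j0 + dj, k0 + dk)]
  }
  val
}

#' Fluid traction and wall FSS on a cell surface
#'
#' Evaluates the full fluid stress tensor
#' `sigma = mu (grad u + grad u^T) - p I` at probe points offset a short
#' distance along the outward normal from each surface node (outside the
#' penalized smoothing layer), and returns the traction vector
#' `t = sigma . n` and the scalar wall FSS, the magnitude of its tangential
#' part.  Nodes below the contact-line cutoff elevation are flagged invalid
#' (viscous stress is singular at the contact line) and are excluded from
#' downstream statistics.
#'
#' @param field A [solve_stokes_local()] result.
#' @param mesh A [mesh_cell_surface()] mesh of one cell in the arrangement.
#' @param probe_dist Normal offset of the sampling points (m); default
#'   `1.5 * delta`.
#' @param cutoff_deg Contact-line exclusion: nodes with elevation below this
#'   angle are marked invalid (default 2 degrees).
#' @return A `surface_fss_field`: `mesh`, `traction` (n x 3, Pa), `fss`
#'   (Pa), `valid` (logical), `probe_dist`, `cutoff_deg`.
#' @export
compute_surface_traction <- function(field, mesh, probe_dist = NULL,
                                     cutoff_deg = 2) {
  stopifnot(inherits(field, "local_stokes_field"),
            inherits(mesh, "cell_surface_mesh"))
  dom <- field$domain
  if (is.null(probe_dist)) probe_dist <- 1.5 * dom$delta
  cf <- center_fields(field)
  pts <- mesh$nodes + probe_dist * mesh$normals
  gx <- function(F) interp_center(F, dom, pts[, 1], pts[, 2], pts[, 3])
  G11 <- gx(cf$dudx); G12 <- gx(cf$dudy); G13 <- gx(cf$dudz)
  G21 <- gx(cf$dvdx); G22 <- gx(cf$dvdy); G23 <- gx(cf$dvdz)
  G31 <- gx(cf$dwdx); G32 <- gx(cf$dwdy); G33 <- gx(cf$dwdz)
  pp <- gx(cf$p)
  n1 <- mesh$normals[, 1]; n2 <- mesh$normals[, 2]; n3 <- mesh$normals[, 3]
  mu <- dom$mu
  t1 <- mu * (2 * G11 * n1 + (G12 + G21) * n2 + (G13 + G31) * n3) - pp * n1
  t2 <- mu * ((G21 + G12) * n1 + 2 * G22 * n2 + (G23 + G32) * n3) - pp * n2
  t3 <- mu * ((G31 + G13) * n1 + (G32 + G23) * n2 + 2 * G33 * n3) - pp * n3
  tn <- t1 * n1 + t2 * n2 + t3 * n3
  tt1 <- t1 - tn * n1; tt2 <- t2 - tn * n2; tt3 <- t3 - tn * n3
  fss <- sqrt(tt1^2 + tt2^2 + tt3^2)
  if (any(!is.finite(fss)))
    stop_gradfss("non-finite traction on the cell surface",
                 "gradfss_pairing_error")
  structure(list(mesh = mesh, traction = cbind(t1, t2, t3), fss = fss,
                 valid = mesh$theta_e_deg >= cutoff_deg,
                 probe_dist = probe_dist, cutoff_deg = cutoff_deg),
            class = "surface_fss_field")
}

#' @export
print.surface_fss_field <- function(x, ...) {
  cat(sprintf(
    "<surface_fss_field> %d nodes (%d valid), FSS %.3g - %.3g Pa\n",
    length(x$fss), sum(x$valid), min(x$fss[x$valid]), max(x$fss[x$valid])))
  invisible(x)
}

#' Floor wall FSS of a local solve
#'
#' One-sided second-order shear `mu * dv/dz` at `z = 0`, for validating the
#' empty-domain solve against the channel background.
#'
#' @param field A [solve_stokes_local()] result.
#' @return Matrix (nx x ny) of floor FSS (Pa) at cell-centre columns.
#' @export
local_floor_fss <- function(field) {
  dom <- field$domain
  nx <- dom$nx; ny <- dom$ny; d <- dom$delta
  v1 <- field$v[2:(nx + 1), , 2]   # z = delta/2
  v2 <- field$v[2:(nx + 1), , 3]   # z = 3 delta/2
  vc1 <- 0.5 * (v1[, 1:ny] + v1[, 2:(ny + 1)])
  vc2 <- 0.5 * (v2[, 1:ny] + v2[, 2:(ny + 1)])
  dom$mu * (9 * vc1 - vc2) / (3 * d)
}

#' Total drag force on the embedded cells
#'
#' In the penalized formulation the force the fluid exerts on the solid
#' equals the Brinkman drag integral `sum(eta * chi * u * dV)` over the
#' solid region (steady momentum balance), a discrete quantity that
#' converges under grid refinement.  Returns the force vector in Newtons.
#'
#' @param field A [solve_stokes_local()] result.
#' @param pen_factor The `pen_factor` used in the solve (default 1e4).
#' @return Length-3 numeric, the (x, y, z) force on the solid (N).
#' @export
cell_drag_force <- function(field, pen_factor = 1e4) {
  dom <- field$domain
  nx <- dom$nx; ny <- dom$ny; nz <- dom$nz
  eta <- pen_factor * dom$mu / dom$delta^2
  dV <- dom$delta^3
  c(
    sum(dom$chi$u * field$u[, 2:(ny + 1), 2:(nz + 1)]),
    sum(dom$chi$v * field$v[2:(nx + 1), , 2:(nz + 1)]),
    sum(dom$chi$w * field$w[2:(nx + 1), 2:(ny + 1), ])
  ) * eta * dV
}

#' Area-weighted mean FSS on a surface
#'
#' @param sfield A [compute_surface_traction()] result.
#' @return Mean FSS (Pa) over valid nodes.
#' @export
mean_surface_fss <- function(sfield) {
  w <- sfield$mesh$area_weight[sfield$valid]
  sum(sfield$fss[sfield$valid] * w) / sum(w)
}

#' Grid-refinement convergence study of the mean cell-surface FSS
#'
#' Re-solves one arrangement at a sequence of grid spacings and reports the
#' area-weighted mean surface FSS per level, flagging convergence when the
#' change between successive levels falls below `tol_pct`.  The traction
#' probe distance is held at the coarsest level's value so that every level
#' samples the same physical location.
#'
#' @param arrangement,background,mu As for [build_local_domain()].
#' @param deltas Decreasing grid spacings (m); at least 3 levels.
#' @param mesh_level Surface-mesh subdivision level.
#' @param tol_pct Convergence threshold, percent change between levels.
#' @param ... Passed to [solve_stokes_local()].
#' @return A `convergence_report`: data frame `levels` with `delta`,
#'   `mean_fss`, `change_pct`, and a `converged` flag.
#' @export
convergence_study <- function(arrangement, background, mu = 1e-3,
                              deltas = c(5e-6, 10e-6 / 3, 2.5e-6),
                              mesh_level = 4, tol_pct = 2, ...) {
  if (length(deltas) < 3)
    stop_gradfss("need at least 3 refinement levels", "gradfss_domain_error")
  deltas <- sort(deltas, decreasing = TRUE)
  probe <- 1.5 * deltas[1]
  cell <- arrangement$cells[[if (arrangement$kind == "hexagonal") arrangement$central else 1L]]
  mesh <- mesh_cell_surface(cell, mesh_level)
  means <- vapply(deltas, function(d) {
    dom <- build_local_domain(arrangement, background, mu = mu, delta = d)
    f <- solve_stokes_local(dom, ...)
    mean_surface_fss(compute_surface_traction(f, mesh, probe_dist = probe))
  }, numeric(1))
  change <- c(NA, abs(diff(means)) / abs(means[-1]) * 100)
  structure(list(
    levels = data.frame(delta = deltas, mean_fss = means,
                        change_pct = change),
    converged = is.finite(change[length(change)]) &&
      change[length(change)] < tol_pct,
    tol_pct = tol_pct, probe_dist = probe
  ), class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  print(x$levels)
  cat(sprintf("converged (< %g%% between finest levels): %s\n",
              x$tol_pct, x$converged))
  invisible(x)
}
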