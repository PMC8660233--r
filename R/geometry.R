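## Geometry of the gradient flow chamber and of the adherent cells.
##
## Coordinate convention (fixed repo-wide):
##   x = width / gradient axis, 0 at the shallow (h1) side, in metres
##   y = flow axis, 0 at the inlet
##   z = height, 0 at the chamber floor
## All angles exposed to users are in degrees.

#' Build a wedge-shaped flow chamber
#'
#' The chamber is a parallel-plate channel whose top cover leans across the
#' width so that the gap height varies linearly from `h1` at `x = 0` to `h2`
#' at `x = w`.  Driving a pressure difference along the flow axis then
#' produces a floor wall shear stress that grows linearly across the width —
#' the gradient-FSS field the device exists for.
#'
#' @param w Chamber width (m), the axis along which the height (and hence the
#'   wall shear stress) varies.
#' @param l Chamber length along the flow axis (m).
#' @param h1,h2 Gap heights at `x = 0` and `x = w` (m), `0 < h1 <= h2`.
#' @return An object of class `chamber_geometry` with fields `w`, `l`, `h1`,
#'   `h2`.
#' @examples
#' ch <- build_chamber(12e-3, 50e-3, 0.2e-3, 0.8e-3)
#' chamber_height(ch, 6e-3)  # 0.5 mm at mid-width
#' @export
build_chamber <- function(w, l, h1, h2) {
  vals <- c(w = w, l = l, h1 = h1, h2 = h2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_gradfss("all chamber dimensions must be positive and finite",
                 "gradfss_invalid_geometry")
  if (h1 > h2)
    stop_gradfss("h1 must not exceed h2 (x = 0 is the shallow side)",
                 "gradfss_invalid_geometry")
  structure(list(w = w, l = l, h1 = h1, h2 = h2),
            class = "chamber_geometry")
}

#' Channel height profile
#'
#' Linear gap height `h(x) = h1 + (h2 - h1) * x / w`.
#'
#' @param geom A [build_chamber()] object.
#' @param x Width coordinate(s) (m), inside `[0, w]`.
#' @return Height(s) in metres.
#' @export
chamber_height <- function(geom, x) {
  stopifnot(inherits(geom, "chamber_geometry"))
  if (any(x < -1e-12 | x > geom$w + 1e-12))
    stop_gradfss("x outside the chamber width [0, w]", "gradfss_domain_error")
  geom$h1 + (geom$h2 - geom$h1) * x / geom$w
}

#' @export
print.chamber_geometry <- function(x, ...) {
  cat(sprintf(
    "<chamber_geometry> w = %.3g mm, l = %.3g mm, h: %.3g -> %.3g mm\n",
    x$w * 1e3, x$l * 1e3, x$h1 * 1e3, x$h2 * 1e3))
  invisible(x)
}

#' Describe a single adherent cell
#'
#' A cell is modelled as a spherical cap sitting on the chamber floor.  The
#' contact angle is the polar angle of the cap measured from its apex: 90
#' degrees is a hemisphere (the default, radius 10 um, the size of an
#' osteoclast precursor).
#'
#' @param x,y Centre of the cap base on the floor (m).
#' @param radius Sphere radius `a` (m).
#' @param contact_angle_deg Cap polar angle from the apex, in (0, 180].
#' @return A `cell_placement` object with the derived base radius and the
#'   sphere-centre height `z_center = -a * cos(theta_c)`.
#' @export
cell_placement <- function(x, y, radius = 10e-6, contact_angle_deg = 90) {
  if (!is.finite(radius) || radius <= 0)
    stop_gradfss("cell radius must be positive", "gradfss_invalid_geometry")
  if (contact_angle_deg <= 0 || contact_angle_deg > 180)
    stop_gradfss("contact angle must lie in (0, 180] degrees",
                 "gradfss_invalid_geometry")
  th <- deg2rad(contact_angle_deg)
  structure(list(
    x = x, y = y, radius = radius,
    contact_angle_deg = contact_angle_deg,
    base_radius = radius * sin(th),
    z_center = -radius * cos(th),
    height = radius * (1 - cos(th))   # apex height above the floor
  ), class = "cell_placement")
}

## A cell footprint must lie strictly inside the chamber floor.
check_inside_floor <- function(geom, placement) {
  rb <- placement$base_radius
  ok <- placement$x - rb > 0 && placement$x + rb < geom$w &&
        placement$y - rb > 0 && placement$y + rb < geom$l
  if (!ok)
    stop_gradfss(sprintf(
      "cell footprint at (x = %.3g mm, y = %.3g mm) leaves the chamber floor",
      placement$x * 1e3, placement$y * 1e3), "gradfss_out_of_bounds")
  invisible(TRUE)
}

new_cell_arrangement <- function(cells, kind, gap = NA_real_) {
  structure(list(cells = cells, kind = kind, gap = gap,
                 central = if (kind == "hexagonal") 1L else NA_integer_),
            class = "cell_arrangement")
}

#' @export
print.cell_arrangement <- function(x, ...) {
  cat(sprintf("<cell_arrangement> %s, %d cell(s)%s\n", x$kind,
              length(x$cells),
              if (is.finite(x$gap)) sprintf(", gap %.3g um", x$gap * 1e6) else ""))
  invisible(x)
}

#' Place replicate cells along the flow axis
#'
#' Single (non-interacting) cells at one width position `x_pos`, spaced
#' evenly between `y_start` and `y_end`.  Because the background flow is
#' fully developed, replicates along the flow axis experience the same local
#' FSS magnitude and gradient; the study design uses seven of them from
#' 10 mm to 40 mm in 5 mm steps.
#'
#' @param geom A [build_chamber()] object.
#' @param x_pos Width coordinate shared by all replicates (m).
#' @param y_start,y_end First and last flow-axis positions (m).
#' @param n Number of replicates (>= 1).
#' @inheritParams cell_placement
#' @return A `cell_arrangement` of kind `"single"` with `n` cells.
#' @export
place_discrete_replicates <- function(geom, x_pos, y_start, y_end, n,
                                      radius = 10e-6, contact_angle_deg = 90) {
  stopifnot(inherits(geom, "chamber_geometry"))
  if (n < 1) stop_gradfss("need n >= 1 replicates", "gradfss_invalid_geometry")
  ys <- if (n == 1) y_start else seq(y_start, y_end, length.out = n)
  cells <- lapply(ys, function(y) {
    p <- cell_placement(x_pos, y, radius, contact_angle_deg)
    check_inside_floor(geom, p)
    p
  })
  new_cell_arrangement(cells, "single")
}

#' Hexagonally packed cell cluster
#'
#' One central cell surrounded by six neighbours at 60-degree azimuthal
#' spacing.  The centre-to-centre distance is `d = 2 * a * sin(theta_c) + s`
#' where `s` is the surface-to-surface gap at the cap base (for hemispheres,
#' `d = 2a + s`).  One neighbour axis is aligned with the +x gradient
#' direction by default; `rotation_deg` rotates the whole ring.
#'
#' @param geom A [build_chamber()] object.
#' @param center Length-2 numeric, `(x, y)` of the central cell (m).
#' @param gap Surface-to-surface spacing `s >= 0` (m).
#' @param rotation_deg Azimuthal rotation of the neighbour ring (degrees).
#' @inheritParams cell_placement
#' @return A `cell_arrangement` of kind `"hexagonal"` with 7 cells; the first
#'   is the central cell (`$central == 1`).
#' @export
place_hexagonal <- function(geom, center, gap, radius = 10e-6,
                            contact_angle_deg = 90, rotation_deg = 0) {
  stopifnot(inherits(geom, "chamber_geometry"), length(center) == 2)
  if (gap < 0) stop_gradfss("gap must be non-negative", "gradfss_invalid_geometry")
  th <- deg2rad(contact_angle_deg)
  d <- 2 * radius * sin(th) + gap
  az <- deg2rad(rotation_deg + seq(0, 300, by = 60))
  cells <- c(
    list(cell_placement(center[1], center[2], radius, contact_angle_deg)),
    lapply(az, function(a)
      cell_placement(center[1] + d * cos(a), center[2] + d * sin(a),
                     radius, contact_angle_deg))
  )
  for (p in cells) check_inside_floor(geom, p)
  arr <- new_cell_arrangement(cells, "hexagonal", gap = gap)
  arr$center_distance <- d
  arr
}

## ---- spherical-cap surface mesh -------------------------------------------

## Subdivided-octahedron upper hemisphere: the octahedron has an equatorial
## square, so its geodesic subdivision has an exact node ring at zero
## elevation and mirror symmetry in x and y -- both properties the sector
## analytics rely on.  Deterministic, no RNG.
octasphere_upper <- function(level) {
  n <- 2L^level
  apex  <- c(0, 0, 1)
  ring  <- list(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  verts <- list(); tris <- list(); key_ix <- new.env(hash = TRUE)
  getv <- function(p) {
    p <- p / sqrt(sum(p^2))
    key <- paste(sprintf("%.10f", round(p, 10)), collapse = ",")
    ix <- key_ix[[key]]
    if (is.null(ix)) {
      verts[[length(verts) + 1L]] <<- p
      ix <- length(verts)
      key_ix[[key]] <- ix
    }
    ix
  }
  for (f in 1:4) {
    A <- ring[[f]]; B <- ring[[f %% 4 + 1]]; C <- apex
    ## barycentric grid: rows i = 0..n from base edge AB towards apex C
    grid <- matrix(0L, n + 1, n + 1)
    for (i in 0:n) for (j in 0:(n - i)) {
      p <- (n - i - j) * A + j * B + i * C
      grid[i + 1, j + 1] <- getv(p)
    }
    for (i in 0:(n - 1)) for (j in 0:(n - 1 - i)) {
      v1 <- grid[i + 1, j + 1]; v2 <- grid[i + 1, j + 2]; v3 <- grid[i + 2, j + 1]
      tris[[length(tris) + 1L]] <- c(v1, v2, v3)
      if (j < n - 1 - i) {
        v4 <- grid[i + 2, j + 2]
        tris[[length(tris) + 1L]] <- c(v2, v4, v3)
      }
    }
  }
  list(verts = do.call(rbind, verts), tris = do.call(rbind, tris))
}

#' Triangulated spherical-cap surface mesh of a cell
#'
#' Builds a watertight triangulation of the dorsal (wetted) surface of a
#' spherical-cap cell by geodesic subdivision of an octahedron hemisphere,
#' remapped in polar angle for contact angles other than 90 degrees.  Each
#' node carries its position, outward unit normal, spherical coordinates
#' relative to the sphere centre (elevation `theta_e` from the floor plane,
#' azimuth `phi` from +x), and an area weight (one third of the area of the
#' adjacent triangles) so that surface integrals are plain weighted sums.
#'
#' @param placement A [cell_placement()].
#' @param level Subdivision level; level 4 (545 nodes for a hemisphere) is
#'   the default. Any level giving fewer than 200 nodes is rejected.
#' @return A `cell_surface_mesh`: list with `nodes` (n x 3, m), `tris`
#'   (m x 3 indices), `normals` (n x 3), `theta_e_deg`, `phi_deg`,
#'   `area_weight` (m^2), plus the placement and analytic cap area.
#' @export
mesh_cell_surface <- function(placement, level = 4) {
  stopifnot(inherits(placement, "cell_placement"))
  base <- octasphere_upper(level)
  if (nrow(base$verts) < 200)
    stop_gradfss(sprintf(
      "subdivision level %d gives %d nodes; need >= 200 (use level >= 4)",
      level, nrow(base$verts)), "gradfss_resolution_error")
  a <- placement$radius
  thc <- deg2rad(placement$contact_angle_deg)
  ## polar angle from the apex, remapped from the hemisphere's [0, pi/2]
  psi_hat <- acos(pmin(1, pmax(-1, base$verts[, 3])))
  psi <- psi_hat * (thc / (pi / 2))
  phi <- atan2(base$verts[, 2], base$verts[, 1])
  dirs <- cbind(sin(psi) * cos(phi), sin(psi) * sin(phi), cos(psi))
  center <- c(placement$x, placement$y, placement$z_center)
  nodes <- sweep(a * dirs, 2, center, "+")
  tris <- base$tris
  ## triangle areas -> nodal weights (1/3 to each corner)
  p1 <- nodes[tris[, 1], , drop = FALSE]
  p2 <- nodes[tris[, 2], , drop = FALSE]
  p3 <- nodes[tris[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  tri_area <- 0.5 * sqrt(rowSums(cr^2))
  w <- numeric(nrow(nodes))
  for (k in 1:3) {
    acc <- tapply(tri_area / 3, tris[, k], sum)
    w[as.integer(names(acc))] <- w[as.integer(names(acc))] + acc
  }
  theta_e <- 90 - rad2deg(psi)
  phi_deg <- (rad2deg(phi)) %% 360
  structure(list(
    nodes = nodes, tris = tris, normals = dirs,
    theta_e_deg = theta_e, phi_deg = phi_deg, area_weight = w,
    placement = placement, level = level,
    cap_area = 2 * pi * a^2 * (1 - cos(thc))
  ), class = "cell_surface_mesh")
}

#' @export
print.cell_surface_mesh <- function(x, ...) {
  cat(sprintf(
    "<cell_surface_mesh> level %d: %d nodes, %d triangles, cap area %.4g m^2\n",
    x$level, nrow(x$nodes), nrow(x$tris), x$cap_area))
  invisible(x)
}
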