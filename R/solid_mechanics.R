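## Hyperelastic model of the adherent cell: a compressible isotropic
## neo-Hookean (Hookean hyperelastic) solid,
##   W_s = (G/2) (I1 - 3) + (Lambda/2) (ln J)^2 - G ln J,
## with G and Lambda derived from Young's modulus and Poisson's ratio.  The
## cell is loaded one-way by the fluid traction on its dorsal surface; its
## base is adherent (fixed).  Deformations at chamber loads are ~1e-4 of
## the radius, which is what justifies not feeding them back into the flow.

#' Shear modulus and Lamé constant from (E, Poisson)
#'
#' `G = E / (2 (1 + mu))`, `Lambda = E mu / ((1 + mu)(1 - 2 mu))`.
#' Poisson's ratio must lie strictly inside (-1, 0.5) for the strain energy
#' to be non-negative (the incompressible limit `mu -> 0.5` makes `Lambda`
#' diverge).
#'
#' @param E Young's modulus (N/m^2).
#' @param poisson Poisson's ratio, in (-1, 0.5).
#' @return List with `G` and `Lambda` (N/m^2).
#' @examples
#' material_constants(5000, 0.3)  # G = 1923.1, Lambda = 2884.6
#' @export
material_constants <- function(E, poisson) {
  if (!is.finite(E) || E <= 0)
    stop_gradfss("Young's modulus must be positive", "gradfss_invalid_material")
  if (poisson <= -1 || poisson >= 0.5)
    stop_gradfss("Poisson's ratio must lie in (-1, 0.5)",
                 "gradfss_invalid_material")
  list(G = E / (2 * (1 + poisson)),
       Lambda = E * poisson / ((1 + poisson) * (1 - 2 * poisson)))
}

#' Cell material definition
#'
#' @inheritParams material_constants
#' @param rho_cell Cell density (kg/m^3); default 1100.
#' @return A `solid_material` with `E`, `poisson`, `G`, `Lambda`, `rho_cell`.
#' @export
solid_material <- function(E = 5000, poisson = 0.3, rho_cell = 1100) {
  mc <- material_constants(E, poisson)
  structure(list(E = E, poisson = poisson, G = mc$G, Lambda = mc$Lambda,
                 rho_cell = rho_cell), class = "solid_material")
}

#' Strain energy density of the compressible neo-Hookean model
#'
#' `W_s = (G/2)(I1 - 3) + (Lambda/2)(ln J)^2 - G ln J` with
#' `I1 = tr(F^T F)` and `J = det F`.  Zero exactly at rigid motions,
#' non-negative for every admissible deformation.
#'
#' @param F A 3x3 deformation gradient with `det F > 0`.
#' @param material A [solid_material()].
#' @return Scalar energy density (J/m^3).
#' @export
strain_energy_density <- function(F, material) {
  stopifnot(is.matrix(F), all(dim(F) == c(3, 3)))
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop_gradfss("deformation gradient has det F <= 0 (inverted element)",
                 "gradfss_inverted_element")
  I1 <- sum(F^2)
  lJ <- log(J)
  material$G / 2 * (I1 - 3) + material$Lambda / 2 * lJ^2 - material$G * lJ
}

## ---- volume mesh of the spherical cap -------------------------------------

## Split one prism (bottom a1 a2 a3, top b1 b2 b3, vertical edges ai-bi)
## into three tetrahedra with quad-face diagonals chosen through the
## smallest global node id, so adjacent prisms split compatibly.
split_prism <- function(pr) {
  bot <- pr[1:3]; top <- pr[4:6]
  m <- which.min(pr)
  if (m > 3) { tmp <- bot; bot <- top; top <- tmp; m <- m - 3 }
  r <- ((m - 1):(m + 1) - 1) %% 3 + 1   # rotate so min is first
  v <- c(bot[r], top[r])                # v[1] is the global min
  ## remaining quad (v2, v3, v6, v5): diagonal through its min vertex
  if (min(v[2], v[6]) < min(v[3], v[5])) {
    rbind(c(v[1], v[2], v[3], v[6]),
          c(v[1], v[2], v[6], v[5]),
          c(v[1], v[5], v[6], v[4]))
  } else {
    rbind(c(v[1], v[2], v[3], v[5]),
          c(v[1], v[3], v[6], v[5]),
          c(v[1], v[5], v[6], v[4]))
  }
}

#' Tetrahedral volume mesh of a spherical-cap cell
#'
#' Radially layered ("onion") tetrahedralization: the surface mesh is scaled
#' towards the sphere centre in `n_layers` shells, shells are connected by
#' prisms split into tetrahedra, and the innermost shell is joined to the
#' centre by one tetrahedron per surface triangle.  The outermost layer
#' nodes coincide with the surface mesh nodes, so fluid tractions map
#' one-to-one.
#'
#' @param mesh A [mesh_cell_surface()] surface mesh.
#' @param n_layers Number of radial shells (default 3).
#' @return A `cell_volume_mesh`: `nodes` (m), `tets` (index rows), `volumes`
#'   (m^3), `surface_nodes` (outer-layer ids matching the surface mesh
#'   order), `fixed` (adhesion node ids, z = 0), `mesh`.
#' @export
mesh_cell_volume <- function(mesh, n_layers = 3) {
  stopifnot(inherits(mesh, "cell_surface_mesh"))
  p <- mesh$placement
  center <- c(p$x, p$y, p$z_center)
  ns <- nrow(mesh$nodes)
  nodes <- matrix(0, 1 + n_layers * ns, 3)
  nodes[1, ] <- center
  for (k in seq_len(n_layers))
    nodes[1 + (k - 1) * ns + seq_len(ns), ] <-
      sweep((k / n_layers) * sweep(mesh$nodes, 2, center, "-"), 2, center, "+")
  lay <- function(k, i) 1 + (k - 1) * ns + i
  tets <- vector("list", nrow(mesh$tris) * n_layers)
  ti <- 0L
  for (t in seq_len(nrow(mesh$tris))) {
    tr <- mesh$tris[t, ]
    ti <- ti + 1L
    tets[[ti]] <- matrix(c(1, lay(1, tr[1]), lay(1, tr[2]), lay(1, tr[3])), 1)
    for (k in seq_len(n_layers - 1)) {
      ti <- ti + 1L
      tets[[ti]] <- split_prism(c(lay(k, tr), lay(k + 1, tr)))
    }
  }
  tets <- do.call(rbind, tets[seq_len(ti)])
  ## orient all tets positively
  d1 <- nodes[tets[, 2], ] - nodes[tets[, 1], ]
  d2 <- nodes[tets[, 3], ] - nodes[tets[, 1], ]
  d3 <- nodes[tets[, 4], ] - nodes[tets[, 1], ]
  vol6 <- d1[, 1] * (d2[, 2] * d3[, 3] - d2[, 3] * d3[, 2]) -
          d1[, 2] * (d2[, 1] * d3[, 3] - d2[, 3] * d3[, 1]) +
          d1[, 3] * (d2[, 1] * d3[, 2] - d2[, 2] * d3[, 1])
  flip <- vol6 < 0
  tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  vol <- abs(vol6) / 6
  if (any(vol <= 0))
    stop_gradfss("degenerate tetrahedron in volume mesh",
                 "gradfss_inverted_element")
  structure(list(
    nodes = nodes, tets = tets, volumes = vol,
    surface_nodes = lay(n_layers, seq_len(ns)),
    fixed = which(abs(nodes[, 3]) < 1e-12),
    mesh = mesh, n_layers = n_layers
  ), class = "cell_volume_mesh")
}

## Per-element reference shape-gradient inverses, vectorized storage.
tet_precompute <- function(vmesh) {
  nds <- vmesh$nodes; tets <- vmesh$tets
  D <- array(0, c(nrow(tets), 3, 3))   # edge matrix columns p2-p1 ...
  for (c in 1:3) D[, , c] <- nds[tets[, c + 1], ] - nds[tets[, 1], ]
  ## inverse of each 3x3 via adjugate
  a <- D[, 1, 1]; b <- D[, 1, 2]; cc <- D[, 1, 3]
  d <- D[, 2, 1]; e <- D[, 2, 2]; f <- D[, 2, 3]
  g <- D[, 3, 1]; h <- D[, 3, 2]; i <- D[, 3, 3]
  det <- a * (e * i - f * h) - b * (d * i - f * g) + cc * (d * h - e * g)
  Binv <- array(0, c(nrow(tets), 3, 3))
  Binv[, 1, 1] <- (e * i - f * h) / det
  Binv[, 1, 2] <- (cc * h - b * i) / det
  Binv[, 1, 3] <- (b * f - cc * e) / det
  Binv[, 2, 1] <- (f * g - d * i) / det
  Binv[, 2, 2] <- (a * i - cc * g) / det
  Binv[, 2, 3] <- (cc * d - a * f) / det
  Binv[, 3, 1] <- (d * h - e * g) / det
  Binv[, 3, 2] <- (b * g - a * h) / det
  Binv[, 3, 3] <- (a * e - b * d) / det
  Binv
}

## Deformation gradients for all elements given nodal displacement (n x 3):
## F = I + (d(edge) %*% Binv), per element.
tet_defgrad <- function(vmesh, Binv, disp) {
  tets <- vmesh$tets
  Dd <- array(0, c(nrow(tets), 3, 3))
  for (c in 1:3) Dd[, , c] <- disp[tets[, c + 1], ] - disp[tets[, 1], ]
  F <- array(0, c(nrow(tets), 3, 3))
  for (r in 1:3) for (c in 1:3) {
    F[, r, c] <- (r == c) +
      Dd[, r, 1] * Binv[, 1, c] + Dd[, r, 2] * Binv[, 2, c] +
      Dd[, r, 3] * Binv[, 3, c]
  }
  F
}

tet_det3 <- function(F) {
  F[, 1, 1] * (F[, 2, 2] * F[, 3, 3] - F[, 2, 3] * F[, 3, 2]) -
  F[, 1, 2] * (F[, 2, 1] * F[, 3, 3] - F[, 2, 3] * F[, 3, 1]) +
  F[, 1, 3] * (F[, 2, 1] * F[, 3, 2] - F[, 2, 2] * F[, 3, 1])
}

tet_invT <- function(F, J) {  # transpose inverse, vectorized
  G <- array(0, dim(F))
  G[, 1, 1] <- (F[, 2, 2] * F[, 3, 3] - F[, 2, 3] * F[, 3, 2]) / J
  G[, 2, 1] <- (F[, 1, 3] * F[, 3, 2] - F[, 1, 2] * F[, 3, 3]) / J
  G[, 3, 1] <- (F[, 1, 2] * F[, 2, 3] - F[, 1, 3] * F[, 2, 2]) / J
  G[, 1, 2] <- (F[, 2, 3] * F[, 3, 1] - F[, 2, 1] * F[, 3, 3]) / J
  G[, 2, 2] <- (F[, 1, 1] * F[, 3, 3] - F[, 1, 3] * F[, 3, 1]) / J
  G[, 3, 2] <- (F[, 1, 3] * F[, 2, 1] - F[, 1, 1] * F[, 2, 3]) / J
  G[, 1, 3] <- (F[, 2, 1] * F[, 3, 2] - F[, 2, 2] * F[, 3, 1]) / J
  G[, 2, 3] <- (F[, 1, 2] * F[, 3, 1] - F[, 1, 1] * F[, 3, 2]) / J
  G[, 3, 3] <- (F[, 1, 1] * F[, 2, 2] - F[, 1, 2] * F[, 2, 1]) / J
  G   # cofactor matrix / det == transpose-inverse
}

#' Equilibrium deformation of a cell under fluid traction
#'
#' Minimizes total potential energy (neo-Hookean strain energy minus the
#' work of the surface traction) over nodal displacements with the adhesion
#' base fixed, using L-BFGS with analytic gradients on a nondimensionalized
#' problem.  At chamber loads (`tau / E ~ 1e-4`) the response is linear and
#' displacements are far below the cell radius, which is the quantitative
#' basis of the one-way fluid-to-solid coupling.
#'
#' @param vmesh A [mesh_cell_volume()] mesh.
#' @param traction n_surface x 3 matrix of traction vectors (Pa) at the
#'   surface nodes (same order as the surface mesh), e.g. from
#'   [compute_surface_traction()].
#' @param material A [solid_material()].
#' @param tol Relative energy-change convergence tolerance (default 1e-8).
#' @param maxit L-BFGS iteration cap.
#' @return A `deformation_state`: `displacement` (n x 3, m),
#'   `max_displacement` (m), per-element `J`, `I1`, `W_s` (J/m^3), total
#'   `energy` (J), external work, relative equilibrium residual, and
#'   convergence flag.
#' @export
solve_cell_deformation <- function(vmesh, traction, material,
                                   tol = 1e-8, maxit = 500) {
  stopifnot(inherits(vmesh, "cell_volume_mesh"),
            inherits(material, "solid_material"))
  ns <- length(vmesh$surface_nodes)
  if (!is.matrix(traction) || nrow(traction) != ns || ncol(traction) != 3)
    stop_gradfss("traction must be an n_surface x 3 matrix matching the mesh",
                 "gradfss_pairing_error")
  a <- vmesh$mesh$placement$radius
  n <- nrow(vmesh$nodes)
  Binv <- tet_precompute(vmesh)
  G <- material$G; L <- material$Lambda
  vol <- vmesh$volumes
  aw <- vmesh$mesh$area_weight
  fext <- matrix(0, n, 3)                       # nodal external force (N)
  fext[vmesh$surface_nodes, ] <- traction * aw
  free <- setdiff(seq_len(n), vmesh$fixed)
  ## nondimensionalization: lengths by a, energy by E a^3, displacement by
  ## a * load_scale so the optimizer sees O(1) numbers
  load_scale <- max(max(abs(traction)) / material$E, 1e-12)
  u_unit <- a * load_scale
  e_unit <- material$E * a^3 * load_scale^2
  unpack <- function(x) {
    d <- matrix(0, n, 3)
    d[free, ] <- matrix(x, ncol = 3) * u_unit
    d
  }
  energy_of <- function(disp) {
    F <- tet_defgrad(vmesh, Binv, disp)
    J <- tet_det3(F)
    if (any(J <= 0)) return(NULL)
    I1 <- F[, 1, 1]^2 + F[, 1, 2]^2 + F[, 1, 3]^2 +
          F[, 2, 1]^2 + F[, 2, 2]^2 + F[, 2, 3]^2 +
          F[, 3, 1]^2 + F[, 3, 2]^2 + F[, 3, 3]^2
    lJ <- log(J)
    Ws <- G / 2 * (I1 - 3) + L / 2 * lJ^2 - G * lJ
    list(F = F, J = J, I1 = I1, Ws = Ws,
         Eint = sum(Ws * vol), Wext = sum(fext * disp))
  }
  fn <- function(x) {
    en <- energy_of(unpack(x))
    if (is.null(en)) return(1e20)
    (en$Eint - en$Wext) / e_unit
  }
  gr <- function(x) {
    disp <- unpack(x)
    en <- energy_of(disp)
    if (is.null(en)) return(rep(0, length(x)))
    F <- en$F; J <- en$J
    FiT <- tet_invT(F, J)
    coefJ <- L * log(J) - G
    P <- array(0, dim(F))                       # first Piola-Kirchhoff
    for (r in 1:3) for (c in 1:3)
      P[, r, c] <- G * F[, r, c] + coefJ * FiT[, r, c]
    fint <- matrix(0, n, 3)
    tets <- vmesh$tets
    for (c in 1:3) {                            # dW/d(edge c) = V P Binv^T
      gcol <- matrix(0, nrow(tets), 3)
      for (r in 1:3)
        gcol[, r] <- vol * (P[, r, 1] * Binv[, c, 1] +
                            P[, r, 2] * Binv[, c, 2] +
                            P[, r, 3] * Binv[, c, 3])
      acc <- rowsum(gcol, tets[, c + 1])
      ix <- as.integer(rownames(acc))
      fint[ix, ] <- fint[ix, ] + acc
      acc1 <- rowsum(gcol, tets[, 1])
      ix1 <- as.integer(rownames(acc1))
      fint[ix1, ] <- fint[ix1, ] - acc1
    }
    as.numeric((fint - fext)[free, ]) * u_unit / e_unit
  }
  x0 <- rep(0, length(free) * 3)
  opt <- optim(x0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = tol / 1e-15))
  disp <- unpack(opt$par)
  en <- energy_of(disp)
  if (is.null(en))
    stop_gradfss("equilibrium solve produced an inverted element",
                 "gradfss_inverted_element")
  gnorm <- sqrt(sum(gr(opt$par)^2))
  fscale <- sqrt(sum((fext[free, ] * u_unit / e_unit)^2))
  structure(list(
    displacement = disp,
    max_displacement = max(sqrt(rowSums(disp^2))),
    J = en$J, I1 = en$I1, W_s = en$Ws,
    energy = en$Eint, external_work = en$Wext,
    residual = if (fscale > 0) gnorm / fscale else gnorm,
    converged = opt$convergence %in% c(0L, 52L),
    optim_message = opt$message
  ), class = "deformation_state")
}

#' @export
print.deformation_state <- function(x, ...) {
  cat(sprintf(
    "<deformation_state> max |u| = %.4g m, energy = %.4g J, residual = %.2g, converged: %s\n",
    x$max_displacement, x$energy, x$residual, x$converged))
  invisible(x)
}
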