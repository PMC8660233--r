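## Polarization analytics of the FSS field on a cell's dorsal surface.
##
## The surface is quartered by azimuth about the transverse FSS-gradient
## direction: SHFSS faces the higher-FSS side, SLFSS the lower-FSS side,
## with two lateral quarters between them.  The polarization statistic is
## the ratio of area-weighted mean FSS in SHFSS to that in SLFSS (RAV);
## RAV - 1 is reported alongside so that an unpolarized cell scores zero.
## Bands are rings of fixed elevation (30/45/60 degrees from the floor
## plane through the sphere centre): 30 degrees lies near the adhesion
## region, 60 degrees near the apex.

#' Partition a cell surface into SHFSS / SLFSS / lateral sectors
#'
#' Azimuthal quartering about the in-plane gradient direction: SHFSS is the
#' 90-degree sector centred on +gradient, SLFSS centred on -gradient.
#' Boundary azimuths (exactly 45 degrees off-axis) are assigned to the
#' sector on their counter-clockwise side.
#'
#' @param mesh A [mesh_cell_surface()] mesh.
#' @param gradient_dir Length-2 in-plane vector pointing towards higher
#'   background FSS (need not be unit length).
#' @return A `sector_partition`: factor `label` per node with levels
#'   `SHFSS`, `LATERAL_UP`, `SLFSS`, `LATERAL_DOWN`, and the unit gradient
#'   direction.
#' @export
partition_sectors <- function(mesh, gradient_dir = c(1, 0)) {
  stopifnot(inherits(mesh, "cell_surface_mesh"))
  nrm <- sqrt(sum(gradient_dir^2))
  if (!is.finite(nrm) || nrm == 0)
    stop_gradfss("gradient direction must be a nonzero in-plane vector",
                 "gradfss_direction_error")
  gdir <- gradient_dir / nrm
  ## azimuth relative to the gradient direction, wrapped to [-45, 315)
  rel <- (mesh$phi_deg - rad2deg(atan2(gdir[2], gdir[1]))) %% 360
  rel <- ifelse(rel >= 315, rel - 360, rel)
  lab <- cut(rel, breaks = c(-45, 45, 135, 225, 315), right = FALSE,
             labels = c("SHFSS", "LATERAL_UP", "SLFSS", "LATERAL_DOWN"))
  structure(list(label = lab, gradient_dir = gdir, mesh = mesh),
            class = "sector_partition")
}

#' Select an elevation band on the cell surface
#'
#' Nodes with elevation within `half_width` of the nominal band elevation
#' `theta_b` (degrees from the floor plane through the sphere centre).
#'
#' @param mesh A [mesh_cell_surface()] mesh.
#' @param theta_b Nominal band elevation in (0, 90) degrees; the study uses
#'   30, 45 and 60.
#' @param half_width Band half-width in degrees (default 7.5).
#' @return A `band_selection` with logical `in_band` per node.
#' @export
select_band <- function(mesh, theta_b, half_width = 7.5) {
  stopifnot(inherits(mesh, "cell_surface_mesh"))
  if (theta_b <= 0 || theta_b >= 90)
    stop_gradfss("band elevation must lie in (0, 90) degrees",
                 "gradfss_resolution_error")
  if (half_width <= 0)
    stop_gradfss("band half-width must be positive",
                 "gradfss_resolution_error")
  in_band <- abs(mesh$theta_e_deg - theta_b) <= half_width
  if (!any(in_band))
    stop_gradfss(sprintf("band %g +/- %g degrees contains no mesh nodes",
                         theta_b, half_width), "gradfss_resolution_error")
  structure(list(in_band = in_band, theta_b = theta_b,
                 half_width = half_width, mesh = mesh),
            class = "band_selection")
}

## Quadrature points for surface integrals: each triangle is split into
## nsub^2 barycentric sub-triangles; the piecewise-linear field is
## evaluated at the sub-centroids, whose spherical angles come from their
## own positions.  Sector assignment at quadrature-point level avoids the
## node-level ambiguity near the apex, where azimuth is ill-defined but
## the area density is highest.
surface_quadrature <- function(mesh, values, nsub = 4) {
  tris <- mesh$tris
  p1 <- mesh$nodes[tris[, 1], , drop = FALSE]
  p2 <- mesh$nodes[tris[, 2], , drop = FALSE]
  p3 <- mesh$nodes[tris[, 3], , drop = FALSE]
  f1 <- values[tris[, 1]]; f2 <- values[tris[, 2]]; f3 <- values[tris[, 3]]
  e1 <- p2 - p1; e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  tri_area <- 0.5 * sqrt(rowSums(cr^2))
  ## barycentric centroids of the nsub^2 sub-triangles (equal flat areas)
  lam <- do.call(rbind, lapply(0:(nsub - 1), function(i) {
    out <- NULL
    for (j in 0:(nsub - 1 - i)) {
      out <- rbind(out, c(i + 1 / 3, j + 1 / 3))          # upright
      if (j < nsub - 1 - i)
        out <- rbind(out, c(i + 2 / 3, j + 2 / 3))        # inverted
    }
    out
  })) / nsub
  l2 <- lam[, 1]; l3 <- lam[, 2]; l1 <- 1 - l2 - l3
  nq <- nrow(lam)
  ## all quadrature points: (ntri * nq) rows, vectorized outer products
  qx <- outer(p1[, 1], l1) + outer(p2[, 1], l2) + outer(p3[, 1], l3)
  qy <- outer(p1[, 2], l1) + outer(p2[, 2], l2) + outer(p3[, 2], l3)
  qz <- outer(p1[, 3], l1) + outer(p2[, 3], l2) + outer(p3[, 3], l3)
  qf <- outer(f1, l1) + outer(f2, l2) + outer(f3, l3)
  qw <- matrix(tri_area / nq^1, nrow(tris), nq)
  ctr <- c(mesh$placement$x, mesh$placement$y, mesh$placement$z_center)
  rx <- qx - ctr[1]; ry <- qy - ctr[2]; rz <- qz - ctr[3]
  rr <- sqrt(rx^2 + ry^2 + rz^2)
  list(theta_deg = rad2deg(asin(pmin(1, pmax(-1, rz / rr)))),
       phi_deg = rad2deg(atan2(ry, rx)) %% 360,
       f = as.numeric(qf), w = as.numeric(qw))
}

## Sector label for azimuth values, tie-break counter-clockwise.
sector_of <- function(phi_deg, gdir) {
  rel <- (phi_deg - rad2deg(atan2(gdir[2], gdir[1]))) %% 360
  rel <- ifelse(rel >= 315, rel - 360, rel)
  cut(rel, breaks = c(-45, 45, 135, 225, 315), right = FALSE,
      labels = c("SHFSS", "LATERAL_UP", "SLFSS", "LATERAL_DOWN"))
}

#' RAV polarization statistic of a surface FSS field
#'
#' Area-weighted mean FSS over the SHFSS and SLFSS sectors (optionally
#' restricted to an elevation band) and their ratio.  Means are surface
#' integrals of the piecewise-linear nodal field, evaluated by sub-triangle
#' quadrature with sector/band membership decided per quadrature point.
#' `rav = ratio - 1` is the zero-centred headline statistic: positive when
#' the high-gradient side of the cell carries more FSS.
#'
#' @param sfield A `surface_fss_field` ([compute_surface_traction()] or
#'   [synth_surface_field()]); its contact-line cutoff is honoured.
#' @param partition A [partition_sectors()] on the same mesh.
#' @param band Optional [select_band()] restriction.
#' @param nsub Quadrature subdivision per triangle edge (default 16).
#' @return A `rav_result`: `mean_sh_Pa`, `mean_sl_Pa`, `ratio`, `rav`,
#'   numbers of contributing mesh nodes, and the band label.
#' @export
compute_rav <- function(sfield, partition, band = NULL, nsub = 16) {
  stopifnot(inherits(sfield, "surface_fss_field"),
            inherits(partition, "sector_partition"))
  if (!identical(dim(partition$mesh$nodes), dim(sfield$mesh$nodes)) ||
      length(partition$label) != length(sfield$fss))
    stop_gradfss("field and partition do not share a mesh",
                 "gradfss_pairing_error")
  mesh <- sfield$mesh
  q <- surface_quadrature(mesh, sfield$fss, nsub = nsub)
  keep <- q$theta_deg >= sfield$cutoff_deg
  node_keep <- sfield$valid
  if (!is.null(band)) {
    stopifnot(inherits(band, "band_selection"))
    keep <- keep & abs(q$theta_deg - band$theta_b) <= band$half_width
    node_keep <- node_keep & band$in_band
  }
  lab <- sector_of(q$phi_deg, partition$gradient_dir)
  wmean <- function(sector) {
    sel <- keep & lab == sector
    if (!any(sel)) return(NA_real_)
    sum(q$f[sel] * q$w[sel]) / sum(q$w[sel])
  }
  m_sh <- wmean("SHFSS"); m_sl <- wmean("SLFSS")
  if (!is.na(m_sl) && m_sl == 0)
    stop_gradfss("SLFSS mean FSS is zero; RAV undefined",
                 "gradfss_division_error")
  structure(list(
    mean_sh_Pa = m_sh, mean_sl_Pa = m_sl,
    ratio = m_sh / m_sl, rav = m_sh / m_sl - 1,
    n_sh = sum(node_keep & partition$label == "SHFSS"),
    n_sl = sum(node_keep & partition$label == "SLFSS"),
    band = if (is.null(band)) "whole" else sprintf("%g", band$theta_b)
  ), class = "rav_result")
}

#' @export
print.rav_result <- function(x, ...) {
  cat(sprintf(
    "<rav_result> band %s: mean SHFSS %.4g Pa, SLFSS %.4g Pa, ratio %.4f, RAV %.4f\n",
    x$band, x$mean_sh_Pa, x$mean_sl_Pa, x$ratio, x$rav))
  invisible(x)
}

#' Aggregate RAV results across replicates and conditions
#'
#' Mean and standard deviation of RAV (and of the raw ratio) per condition
#' group.
#'
#' @param results Data frame with one row per cell/condition, containing at
#'   least a `rav` column (e.g. the `rav_table` of [run_experiment()]).
#' @param grouping Character vector of grouping column names.
#' @return Data frame with one row per group: `n`, `rav_mean`, `rav_sd`,
#'   `ratio_mean` (if a `ratio` column is present).
#' @export
aggregate_replicates <- function(results, grouping) {
  stopifnot(is.data.frame(results), all(grouping %in% names(results)))
  if (nrow(results) == 0)
    stop_gradfss("no results to aggregate", "gradfss_grouping_error")
  by <- results[, grouping, drop = FALSE]
  agg <- aggregate(results$rav, by = by,
                   FUN = function(v) c(n = length(v), mean = mean(v),
                                       sd = if (length(v) > 1) sd(v) else 0))
  out <- cbind(agg[, grouping, drop = FALSE],
               n = agg$x[, "n"], rav_mean = agg$x[, "mean"],
               rav_sd = agg$x[, "sd"])
  if ("ratio" %in% names(results)) {
    agr <- aggregate(results$ratio, by = by, FUN = mean)
    out$ratio_mean <- agr$x
  }
  rownames(out) <- NULL
  out
}
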