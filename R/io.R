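## Plain-text exporters: legacy ASCII VTK PolyData for surface meshes and
## fields (readable by ParaView), and CSV node/profile tables.  Synthetic
## and solved fields share these writers, so they are interchangeable
## downstream.

#' Write a cell surface (with optional point data) as legacy VTK PolyData
#'
#' @param mesh A [mesh_cell_surface()] mesh.
#' @param path Output file path (`.vtk`).
#' @param point_data Named list of per-node numeric vectors to attach,
#'   e.g. `list(wall_fss_Pa = sfield$fss)`.
#' @return `path`, invisibly.
#' @export
write_vtk_polydata <- function(mesh, path, point_data = list()) {
  stopifnot(inherits(mesh, "cell_surface_mesh"))
  n <- nrow(mesh$nodes); m <- nrow(mesh$tris)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "cell surface mesh", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(format(mesh$nodes, digits = 12, scientific = TRUE,
                          trim = TRUE), 1, paste, collapse = " "), con)
  writeLines(sprintf("POLYGONS %d %d", m, 4 * m), con)
  writeLines(paste(3, mesh$tris[, 1] - 1, mesh$tris[, 2] - 1,
                   mesh$tris[, 3] - 1), con)
  if (length(point_data) > 0) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      stopifnot(length(v) == n)
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default",
                   format(v, digits = 12, scientific = TRUE, trim = TRUE)),
                 con)
    }
  }
  invisible(path)
}

#' Write a surface FSS field as a CSV node table
#'
#' Columns: `node_id`, `x`, `y`, `z` (m), `theta_e_deg`, `phi_deg`,
#' `area_weight` (m^2), `fss_Pa`, `valid`.
#'
#' @param sfield A `surface_fss_field`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_surface_csv <- function(sfield, path) {
  stopifnot(inherits(sfield, "surface_fss_field"))
  m <- sfield$mesh
  df <- data.frame(node_id = seq_len(nrow(m$nodes)),
                   x = m$nodes[, 1], y = m$nodes[, 2], z = m$nodes[, 3],
                   theta_e_deg = m$theta_e_deg, phi_deg = m$phi_deg,
                   area_weight = m$area_weight,
                   fss_Pa = sfield$fss, valid = sfield$valid)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a floor FSS profile as CSV
#'
#' @param profile `data.frame(x_mm, tau_wall_Pa)` (e.g.
#'   [floor_fss_profile()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(all(c("x_mm", "tau_wall_Pa") %in% names(profile)))
  write.csv(profile, path, row.names = FALSE)
  invisible(path)
}
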