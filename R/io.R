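# Exporters for standard visualization formats: legacy ASCII VTK
# structured-points files for concentration fields and ASCII STL for
# iso-surface meshes, plus the sampled-pouch CSV that joins transport
# output to the bioassay table.

#' Write a concentration field as a legacy VTK structured-points file
#'
#' Cell-centered values are written as point data on the lattice of cell
#' centers, which is how structured-points viewers expect them.
#'
#' @param field an `sr_conc_field`
#' @param path output path (.vtk)
#' @param what "time_average" or a snapshot index
#' @param name scalar field name in the file
#' @return `path`, invisibly
#' @export
write_field_vtk <- function(field, path, what = "time_average",
                            name = "concentration_mg_m3") {
  grid <- field$grid
  vals <- if (identical(what, "time_average")) field$time_average
          else field$snapshots[[what]]$values
  n <- grid$shape
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 2.0",
               "srvolume concentration field", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", n[1], n[2], n[3]),
               sprintf("ORIGIN %.9g %.9g %.9g", grid$dx / 2, grid$dx / 2,
                       grid$dx / 2),
               sprintf("SPACING %.9g %.9g %.9g", grid$dx, grid$dx, grid$dx),
               sprintf("POINT_DATA %d", prod(n)),
               sprintf("SCALARS %s float 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(formatC(as.vector(vals), format = "g", digits = 7), con)
  invisible(path)
}

#' Write a triangle mesh as ASCII STL
#'
#' @param mesh an `sr_mesh` from [extract_isosurface()]
#' @param path output path (.stl)
#' @param name solid name
#' @return `path`, invisibly
#' @export
write_stl_ascii <- function(mesh, path, name = "protection_bubble") {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (i in seq_len(nrow(f))) {
    p1 <- v[f[i, 1], ]; p2 <- v[f[i, 2], ]; p3 <- v[f[i, 3], ]
    e1 <- p2 - p1; e2 <- p3 - p1
    nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
             e1[3] * e2[1] - e1[1] * e2[3],
             e1[1] * e2[2] - e1[2] * e2[1])
    nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", nrm[1], nrm[2], nrm[3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", p1[1], p1[2], p1[3]),
                 sprintf("      vertex %.9g %.9g %.9g", p2[1], p2[2], p2[3]),
                 sprintf("      vertex %.9g %.9g %.9g", p3[1], p3[2], p3[3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Sample pouch concentrations into a joinable table
#'
#' @param field an `sr_conc_field`
#' @param sc the scene whose (non-control) pouches are sampled
#' @return data.frame: site_id, x_m, y_m, z_m, level_label, ring_label,
#'   n_mosquitoes, c_mg_m3, c_ppmv
#' @export
pouch_concentration_table <- function(field, sc) {
  act <- Filter(function(p) !p$control, sc$pouches)
  if (!length(act)) stop("scene has no non-control pouches")
  pts <- do.call(rbind, lapply(act, function(p) p$position_m))
  c_mg <- sample_at_points(field, pts)
  c_ppm <- sample_at_points(field, pts, units = "ppmv")
  data.frame(
    site_id = vapply(act, function(p) p$id, character(1)),
    x_m = pts[, 1], y_m = pts[, 2], z_m = pts[, 3],
    level_label = vapply(act, function(p) p$level_label, character(1)),
    ring_label = vapply(act, function(p) p$ring_label, character(1)),
    n_mosquitoes = vapply(act, function(p) p$n_mosquitoes, integer(1)),
    c_mg_m3 = c_mg, c_ppmv = c_ppm,
    stringsAsFactors = FALSE
  )
}

#' Write a bubble report as JSON
#'
#' @param bubble an `sr_bubble`
#' @param path output path (.json)
#' @return `path`, invisibly
#' @export
write_bubble_json <- function(bubble, path) {
  payload <- list(
    threshold_ppm = bubble$threshold_ppm,
    target_mortality = bubble$target_mortality,
    voxel_volume_m3 = bubble$voxel_volume_m3,
    mesh_volume_m3 = bubble$mesh_volume_m3,
    pouches_inside = bubble$pouches_inside,
    connected_to_sources = bubble$connected_to_sources,
    warnings = bubble$warnings
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
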