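# ---------------------------------------------------------------------------
# Output writers: legacy ASCII VTK unstructured grids and coverage CSV.
# ---------------------------------------------------------------------------

#' Write nodal fields on a mesh as a legacy ASCII VTK unstructured grid
#'
#' The (r, z) plane is written as (x, y, 0) coordinates; each named entry
#' of `fields` becomes a POINT_DATA scalar array.
#'
#' @param mesh an `mwa_mesh`.
#' @param fields named list of per-node numeric vectors.
#' @param path output `.vtk` path.
#' @export
write_vtk <- function(mesh, fields, path) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "mwablate fields", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 4 * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L,
                     mesh$tri[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(factor(mesh$region))), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", fields[[nm]]), con)
  }
  invisible(path)
}

#' Write the coverage-metrics time series of a report as CSV
#'
#' @param report an `ablation_report`.
#' @param path output `.csv` path.
#' @export
write_coverage_csv <- function(report, path) {
  utils::write.csv(report$metrics, path, row.names = FALSE)
  invisible(path)
}
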