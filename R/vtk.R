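#' Export a voxel mesh as a legacy VTK unstructured grid
#'
#' Writes an ASCII legacy-format VTK file (hexahedron cells, type 12) with
#' optional per-cell and per-node data arrays, for inspection in ParaView or
#' similar viewers.
#'
#' @param mesh a \linkS4class{VoxelMesh}.
#' @param path output file path (conventionally \code{.vtk}).
#' @param cellData named list of numeric vectors, one value per element
#'   (e.g. von Mises stress, scaled stress, the surviving fusion mask).
#' @param pointData named list of numeric matrices (nodes x 3) or vectors.
#' @return \code{path}, invisibly.
#' @export
writeVTK <- function(mesh, path, cellData = list(), pointData = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh@nodes)
  m <- nrow(mesh@elems)
  writeLines(c("# vtk DataFile Version 3.0", "voxel mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  write(t(mesh@nodes), con, ncolumns = 3)
  writeLines(sprintf("CELLS %d %d", m, 9L * m), con)
  write(t(cbind(8L, mesh@elems - 1L)), con, ncolumns = 9)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  write(rep(12L, m), con, ncolumns = 20)
  if (length(cellData)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cellData)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      write(as.numeric(cellData[[nm]]), con, ncolumns = 9)
    }
  }
  if (length(pointData)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(pointData)) {
      v <- pointData[[nm]]
      if (is.matrix(v) && ncol(v) == 3L) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        write(t(v), con, ncolumns = 3)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        write(as.numeric(v), con, ncolumns = 9)
      }
    }
  }
  invisible(path)
}
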