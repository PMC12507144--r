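#' Write points with attributes as legacy-ASCII VTK PolyData
#'
#' Minimal writer for point clouds (wall meshes, incidence maps) with
#' scalar and vector point attributes, readable by ParaView and the
#' VTK ecosystem.
#'
#' @param points n x 3 matrix (any consistent unit; mm is customary
#'   for viewers).
#' @param file output path (`.vtk`).
#' @param pointData named list of per-point attributes: numeric vectors
#'   become SCALARS (factors/characters are coded to integers), n x 3
#'   matrices become VECTORS. `NA` is written as -1.
#' @return `file`, invisibly.
#' @export
writeVTKPolyData <- function(points, file, pointData = list()) {
  n <- nrow(points)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "aortaflow point data",
               "ASCII", "DATASET POLYDATA", sprintf("POINTS %d float", n)),
             con)
  writeLines(apply(points, 1, function(p) paste(format(p, trim = TRUE),
                                                collapse = " ")), con)
  writeLines(sprintf("VERTICES %d %d", n, 2 * n), con)
  writeLines(sprintf("1 %d", seq_len(n) - 1L), con)
  if (length(pointData) > 0L) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(pointData)) {
      v <- pointData[[nm]]
      if (is.matrix(v)) {
        v[is.na(v)] <- -1
        writeLines(sprintf("VECTORS %s float", nm), con)
        writeLines(apply(v, 1, function(p)
          paste(format(p, trim = TRUE), collapse = " ")), con)
      } else {
        if (is.character(v) || is.factor(v))
          v <- as.integer(factor(v, levels = unique(v))) - 1L
        v[is.na(v)] <- -1
        writeLines(c(sprintf("SCALARS %s float 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(format(v, trim = TRUE), con)
      }
    }
  }
  invisible(file)
}
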