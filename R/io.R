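## Plain-text exports: traces, electrograms, activation maps, and a legacy
## ASCII VTK structured-points writer for sheet snapshots.

#' Write a trace as two-column delimited text
#'
#' @param trace a \linkS4class{VmTrace} or \linkS4class{EGMTrace}
#' @param file output path
#' @export
writeTrace <- function(trace, file) {
  if (is(trace, "VmTrace"))
    df <- data.frame(t_ms = trace@t, vm_mV = trace@vm)
  else if (is(trace, "EGMTrace"))
    df <- data.frame(t_ms = trace@t, phi = trace@phi)
  else stop("expected a VmTrace or EGMTrace")
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write an activation map as delimited text
#' @param map matrix or vector from \code{\link{activationMap}}
#' @param file output path
#' @export
writeActivationMap <- function(map, file) {
  write.table(as.matrix(map), file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Export a sheet Vm snapshot as legacy ASCII VTK structured points
#'
#' @param result a \linkS4class{SimulationResult} on a sheet grid
#' @param time snapshot time, ms (nearest recorded sample is used)
#' @param file output path (.vtk)
#' @export
writeVTKSnapshot <- function(result, time, file) {
  stopifnot(is(result, "SimulationResult"))
  grid <- result@grid
  if (grid@topology != "sheet") stop("VTK export is for sheet grids")
  if (!nrow(result@vm)) stop("no recorded Vm")
  i <- which.min(abs(result@times - time))
  nx <- grid@dims[1]; ny <- grid@dims[2]
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("atriasim Vm snapshot t =", result@times[i], "ms"),
               "ASCII", "DATASET STRUCTURED_POINTS",
               paste("DIMENSIONS", nx, ny, 1),
               "ORIGIN 0 0 0",
               paste("SPACING", grid@dx, grid@dx, grid@dx),
               paste("POINT_DATA", nx * ny),
               "SCALARS Vm float 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(format(result@vm[i, ], digits = 6), collapse = " "), con)
  invisible(file)
}
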