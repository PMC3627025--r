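## Legacy ASCII VTK export for visual inspection of networks and grid
## fields (ParaView-compatible). Written directly: the legacy format is a
## few header lines plus whitespace-separated numbers.

vtk_num <- function(x) formatC(as.numeric(x), digits = 9, format = "g")

#' Export grid fields as a VTK structured-points file
#'
#' @param path output file (conventionally `.vtk`).
#' @param mesh a `grid_mesh`.
#' @param scalars named list of nodal scalar fields.
#' @param tensors named list of m x 6 symmetric tensor fields (columns
#'   xx, yy, zz, xy, xz, yz).
#' @return the path, invisibly.
#' @export
write_vtk_grid <- function(path, mesh, scalars = list(), tensors = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- mesh$dims
  writeLines(c("# vtk DataFile Version 3.0", "darcypar grid fields",
               "ASCII", "DATASET STRUCTURED_POINTS",
               paste("DIMENSIONS", d[1], d[2], d[3]),
               paste("ORIGIN", paste(vtk_num(mesh$box[1, ]), collapse = " ")),
               paste("SPACING", paste(vtk_num(mesh$h), collapse = " ")),
               paste("POINT_DATA", prod(d))), con)
  for (nm in names(scalars)) {
    writeLines(c(paste("SCALARS", nm, "double 1"),
                 "LOOKUP_TABLE default"), con)
    writeLines(vtk_num(scalars[[nm]]), con)
  }
  for (nm in names(tensors)) {
    K <- tensors[[nm]]
    writeLines(paste("TENSORS", nm, "double"), con)
    full <- cbind(K[, 1], K[, 4], K[, 5],
                  K[, 4], K[, 2], K[, 6],
                  K[, 5], K[, 6], K[, 3])
    writeLines(apply(full, 1, function(r)
      paste(vtk_num(r), collapse = " ")), con)
  }
  invisible(path)
}

#' Export a vascular network as VTK polydata
#'
#' Centrelines become VTK line cells; nodal radius (and pressure, when a
#' flow solution is given) are attached as point data, vessel radius, flux
#' and compartment as cell data.
#'
#' @param path output file.
#' @param net a `vascular_network`.
#' @param flow optional `network_flow`.
#' @return the path, invisibly.
#' @export
write_vtk_network <- function(path, net, flow = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(net$nodes); v <- nrow(net$vessels)
  ia <- match(net$vessels$node_a, net$nodes$id) - 1L
  ib <- match(net$vessels$node_b, net$nodes$id) - 1L
  writeLines(c("# vtk DataFile Version 3.0", "darcypar vascular network",
               "ASCII", "DATASET POLYDATA",
               paste("POINTS", n, "double")), con)
  writeLines(paste(vtk_num(net$nodes$x), vtk_num(net$nodes$y),
                   vtk_num(net$nodes$z)), con)
  writeLines(paste("LINES", v, 3 * v), con)
  writeLines(paste(2L, ia, ib), con)
  writeLines(c(paste("POINT_DATA", n), "SCALARS radius double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(vtk_num(net$nodes$radius), con)
  if (!is.null(flow)) {
    writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
    writeLines(vtk_num(flow$pressure[as.character(net$nodes$id)]), con)
  }
  writeLines(c(paste("CELL_DATA", v), "SCALARS vessel_radius double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(vtk_num(net$vessels$radius), con)
  if (!all(is.na(net$vessels$compartment))) {
    writeLines(c("SCALARS compartment int 1", "LOOKUP_TABLE default"), con)
    writeLines(as.character(ifelse(is.na(net$vessels$compartment), -1L,
                                   net$vessels$compartment)), con)
  }
  if (!is.null(flow)) {
    writeLines(c("SCALARS flux double 1", "LOOKUP_TABLE default"), con)
    writeLines(vtk_num(flow$flux[as.character(net$vessels$id)]), con)
  }
  invisible(path)
}
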