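# Readers/writers for the network exchange format (two delimited text
# tables with explicit unit headers) and legacy-VTK exporters for
# visualization. Round-trips are bit-exact for the tabular payload.

NODE_UNITS_HEADER <- "# units: x=um y=um bc_value=mmHg|nl/min bc_po2=mmHg"
SEG_UNITS_HEADER <- "# units: diameter=um"

#' Write a network to the exchange format
#'
#' Writes \code{<stem>_nodes.tsv} and \code{<stem>_segments.tsv}: UTF-8
#' tab-delimited tables with a leading unit-declaration comment line.
#' Optional per-segment/per-node state columns are appended when states
#' are supplied.
#'
#' @param net a \code{vascular_network}.
#' @param stem output path stem.
#' @param flow optional \code{hemodynamic_state}.
#' @param oxygen optional \code{oxygen_state}.
#' @return invisibly the two file paths.
#' @export
write_network <- function(net, stem, flow = NULL, oxygen = NULL) {
  nodes <- net$nodes
  segs <- net$segments
  if (!is.null(flow)) {
    nodes$pressure <- flow$pressure[match(nodes$id, flow$node_id)]
    k <- match(segs$id, flow$segment_id)
    segs$flow <- flow$flow[k]
    segs$hematocrit <- flow$hematocrit[k]
    segs$shear <- flow$shear[k]
  }
  if (!is.null(oxygen)) {
    segs$po2 <- oxygen$vessel_po2[match(segs$id, oxygen$segment_id)]
  }
  npath <- paste0(stem, "_nodes.tsv")
  spath <- paste0(stem, "_segments.tsv")
  writeLines(NODE_UNITS_HEADER, npath)
  suppressWarnings(utils::write.table(nodes, npath, sep = "\t",
                                      row.names = FALSE, quote = FALSE,
                                      append = TRUE))
  writeLines(SEG_UNITS_HEADER, spath)
  suppressWarnings(utils::write.table(segs, spath, sep = "\t",
                                      row.names = FALSE, quote = FALSE,
                                      append = TRUE))
  invisible(c(npath, spath))
}

#' Read a network from the exchange format
#'
#' Validates referential integrity and reports offending rows; refuses
#' files without the unit-declaration header.
#'
#' @param stem path stem used in [write_network()].
#' @param domain optional \code{tissue_domain} to attach.
#' @return a \code{vascular_network}.
#' @export
read_network <- function(stem, domain = NULL) {
  npath <- paste0(stem, "_nodes.tsv")
  spath <- paste0(stem, "_segments.tsv")
  for (p in c(npath, spath)) {
    if (!file.exists(p)) stop("missing file: ", p)
    first <- readLines(p, n = 1)
    if (!startsWith(first, "# units:")) {
      stop("file lacks the unit declaration header: ", p)
    }
  }
  nodes <- utils::read.table(npath, header = TRUE, sep = "\t",
                             comment.char = "#",
                             stringsAsFactors = FALSE)
  segs <- utils::read.table(spath, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
  bad <- which(!(segs$from %in% nodes$id) | !(segs$to %in% nodes$id))
  if (length(bad) > 0) {
    stop("segment rows with dangling endpoints: row ",
         paste(bad, collapse = ", "))
  }
  vascular_network(nodes, segs, domain = domain)
}

#' Write the network as legacy-VTK polylines
#'
#' One polyline (two-point line) per segment, with diameter and any
#' supplied per-segment attributes as CELL_DATA; loadable in ParaView.
#'
#' @param net a \code{vascular_network}.
#' @param path output .vtk path.
#' @param attributes named list of per-segment numeric vectors.
#' @return invisibly the path.
#' @export
write_vtk_network <- function(net, path, attributes = list()) {
  co <- segment_coords(net)
  ns <- nrow(net$segments)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "vascular network", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", 2 * ns)), con)
  if (ns > 0) {
    for (k in seq_len(ns)) {
      writeLines(sprintf("%g %g 0 %g %g 0", co[k, 1], co[k, 2],
                         co[k, 3], co[k, 4]), con)
    }
  }
  writeLines(sprintf("LINES %d %d", ns, 3 * ns), con)
  if (ns > 0) {
    for (k in seq_len(ns)) {
      writeLines(sprintf("2 %d %d", 2 * (k - 1), 2 * k - 1), con)
    }
  }
  writeLines(sprintf("CELL_DATA %d", ns), con)
  attributes <- c(list(diameter = net$segments$diameter), attributes)
  for (an in names(attributes)) {
    writeLines(c(sprintf("SCALARS %s float 1", an),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%g", attributes[[an]]), con)
  }
  invisible(path)
}

#' Write a tissue-point field as legacy-VTK structured points
#'
#' @param domain a \code{tissue_domain}.
#' @param values numeric vector aligned with \code{domain$points}.
#' @param path output .vtk path.
#' @param name field name.
#' @param fill value used for grid cells outside the domain polygon.
#' @return invisibly the path.
#' @export
write_vtk_grid <- function(domain, values, path, name = "field",
                           fill = -1) {
  gx <- domain$grid_x; gy <- domain$grid_y
  full <- rep(fill, length(gx) * length(gy))
  full[which(domain$in_domain)] <- values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", name, "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", length(gx), length(gy)),
               sprintf("ORIGIN %g %g 0", gx[1], gy[1]),
               sprintf("SPACING %g %g 1", domain$spacing, domain$spacing),
               sprintf("POINT_DATA %d", length(full)),
               sprintf("SCALARS %s float 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%g", full), con)
  invisible(path)
}

#' Export tissue-point field as a CSV grid table
#'
#' @param domain a \code{tissue_domain}.
#' @param values numeric vector aligned with \code{domain$points}.
#' @param path output .csv path.
#' @return invisibly the path.
#' @export
write_grid_csv <- function(domain, values, path) {
  df <- cbind(domain$points, value = values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
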