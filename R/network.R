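#' Vascular network objects
#'
#' A \code{vascular_network} is the central mutable object of the simulator:
#' a planar graph of nodes (2-D positions in um) and straight segments
#' (diameter, vessel type, flow eligibility), annotated with boundary
#' conditions at the nodes where blood enters or leaves. Tortuous vessels are
#' represented as chains of short straight segments (minimum length 10 um).
#'
#' Boundary nodes carry either a pressure condition (mmHg) or a flow
#' condition (nl/min, positive into the network), plus the inflow discharge
#' hematocrit and blood PO2 (mmHg) where blood enters.
#'
#' @param nodes data.frame with columns \code{id}, \code{x}, \code{y},
#'   \code{kind} ("interior" or "boundary"), \code{bc_type} (NA, "pressure"
#'   or "flow"), \code{bc_value}, \code{bc_hematocrit}, \code{bc_po2}.
#' @param segments data.frame with columns \code{id}, \code{from}, \code{to},
#'   \code{diameter} (um), \code{type} ("arteriole", "capillary", "venule" or
#'   "sprout"), \code{flowing} (logical), \code{fixed} (logical; TRUE for
#'   bounding venules whose diameter never adapts).
#' @param domain a \code{tissue_domain}, or NULL.
#' @param sprouts data.frame of active sprout tips (see
#'   \code{\link{spawn_sprout}}), or NULL for none.
#' @return an object of class \code{vascular_network}.
#' @seealso [tissue_domain()], [solve_flow()], [simulate_angiogenesis()]
#' @export
vascular_network <- function(nodes, segments, domain = NULL, sprouts = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  need_n <- c("id", "x", "y", "kind", "bc_type", "bc_value",
              "bc_hematocrit", "bc_po2")
  for (cn in setdiff(need_n, names(nodes))) nodes[[cn]] <- NA_real_
  need_s <- c("id", "from", "to", "diameter", "type", "flowing", "fixed")
  miss <- setdiff(need_s, names(segments))
  if ("flowing" %in% miss) segments$flowing <- TRUE
  if ("fixed" %in% miss) segments$fixed <- FALSE
  if ("type" %in% miss) segments$type <- "capillary"
  miss <- setdiff(need_s, names(segments))
  if (length(miss) > 0) {
    stop("segments table lacks columns: ", paste(miss, collapse = ", "))
  }
  if (is.null(sprouts)) sprouts <- empty_sprout_table()
  net <- structure(
    list(nodes = nodes[need_n], segments = segments[need_s],
         domain = domain, sprouts = sprouts,
         next_node_id = max(0, nodes$id) + 1,
         next_segment_id = max(0, segments$id) + 1),
    class = "vascular_network")
  validate_network(net)
  net
}

empty_sprout_table <- function() {
  data.frame(id = integer(0), tip_node = integer(0),
             dir_x = numeric(0), dir_y = numeric(0),
             attach_node = integer(0), age = integer(0))
}

#' Validate structural invariants of a network
#'
#' Checks referential integrity, boundary-node degree (exactly one attached
#' segment), positive diameters and the 10 um minimum segment length.
#'
#' @param net a \code{vascular_network}.
#' @param min_length minimum admissible segment length (um).
#' @return invisibly TRUE; stops with a message on violation.
#' @export
validate_network <- function(net, min_length = 10) {
  nodes <- net$nodes; segs <- net$segments
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (anyDuplicated(segs$id)) stop("duplicate segment ids")
  bad <- !(segs$from %in% nodes$id) | !(segs$to %in% nodes$id)
  if (any(bad)) {
    stop("segment(s) with dangling endpoints: ",
         paste(segs$id[bad], collapse = ", "))
  }
  if (any(segs$from == segs$to)) stop("self-loop segment")
  if (nrow(segs) > 0 && any(segs$diameter <= 0)) stop("non-positive diameter")
  len <- segment_lengths(net)
  if (any(len < min_length - 1e-6)) {
    stop("segment(s) shorter than ", min_length, " um: ",
         paste(segs$id[len < min_length - 1e-6], collapse = ", "))
  }
  # boundary nodes carry at most one segment (exactly one while connected;
  # pruning may disconnect a boundary inflow entirely)
  deg <- node_degree(net)
  bnd <- nodes$id[nodes$kind == "boundary"]
  dbad <- bnd[deg[as.character(bnd)] > 1]
  if (length(dbad) > 0 && nrow(segs) > 0) {
    stop("boundary node(s) with more than one segment: ",
         paste(dbad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Segment lengths (um)
#' @param net a \code{vascular_network}.
#' @return numeric vector aligned with \code{net$segments}.
#' @export
segment_lengths <- function(net) {
  if (nrow(net$segments) == 0) return(numeric(0))
  i <- match(net$segments$from, net$nodes$id)
  j <- match(net$segments$to, net$nodes$id)
  sqrt((net$nodes$x[j] - net$nodes$x[i])^2 +
       (net$nodes$y[j] - net$nodes$y[i])^2)
}

#' Segment endpoint coordinate matrix
#' @keywords internal
segment_coords <- function(net) {
  i <- match(net$segments$from, net$nodes$id)
  j <- match(net$segments$to, net$nodes$id)
  cbind(x1 = net$nodes$x[i], y1 = net$nodes$y[i],
        x2 = net$nodes$x[j], y2 = net$nodes$y[j])
}

#' Node degrees
#' @return named integer vector (names are node ids).
#' @keywords internal
node_degree <- function(net) {
  tab <- table(factor(c(net$segments$from, net$segments$to),
                      levels = net$nodes$id))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Total vessel length (um)
#'
#' @param net a \code{vascular_network}.
#' @param flowing_only if TRUE, count only flow-eligible segments.
#' @export
total_vessel_length <- function(net, flowing_only = FALSE) {
  len <- segment_lengths(net)
  if (flowing_only) len <- len[net$segments$flowing]
  sum(len)
}

#' @export
print.vascular_network <- function(x, ...) {
  nb <- sum(x$nodes$kind == "boundary")
  cat("vascular_network: ", nrow(x$nodes), " nodes (", nb, " boundary), ",
      nrow(x$segments), " segments, ",
      sum(!x$segments$flowing), " non-flowing (sprout) segments\n", sep = "")
  cat(sprintf("total vessel length %.2f mm\n", total_vessel_length(x) / 1000))
  invisible(x)
}

#' Tissue domain
#'
#' A thin sheet of tissue described by a closed boundary polygon, a slab
#' thickness, and a square grid of tissue points at which oxygen demand,
#' PO2 and VEGF concentration are carried.
#'
#' @param boundary two-column matrix of polygon vertices (um).
#' @param thickness slab thickness (um), default 20.
#' @param spacing tissue-point grid spacing (um), default 50.
#' @param demand oxygen demand M0, cm3 O2 per 100 cm3 tissue per min.
#' @return an object of class \code{tissue_domain} with tissue points
#'   (interior grid points) in \code{$points}.
#' @export
tissue_domain <- function(boundary, thickness = 20, spacing = 50,
                          demand = 2) {
  boundary <- as.matrix(boundary)
  xr <- range(boundary[, 1]); yr <- range(boundary[, 2])
  gx <- seq(xr[1] + spacing / 2, xr[2] - spacing / 4, by = spacing)
  gy <- seq(yr[1] + spacing / 2, yr[2] - spacing / 4, by = spacing)
  pts <- expand.grid(x = gx, y = gy)
  keep <- points_in_polygon(pts$x, pts$y, boundary)
  structure(
    list(boundary = boundary, thickness = thickness, spacing = spacing,
         demand = demand, points = pts[keep, , drop = FALSE],
         grid_x = gx, grid_y = gy, in_domain = keep),
    class = "tissue_domain")
}

#' @export
print.tissue_domain <- function(x, ...) {
  cat(sprintf(paste0("tissue_domain: area %.3f mm2, thickness %g um, ",
                     "%d tissue points at %g um spacing, demand %g\n"),
              polygon_area(x$boundary) / 1e6, x$thickness,
              nrow(x$points), x$spacing, x$demand))
  invisible(x)
}

#' Branching angles at three-way nodes
#'
#' For every node with exactly three attached segments, the three pairwise
#' angles between the unit vectors pointing from the node along each segment.
#' The three angles at a planar node sum to 360 degrees.
#'
#' @param net a \code{vascular_network}.
#' @param flowing_only restrict to flow-eligible segments.
#' @return data.frame with \code{node}, \code{angle1}, \code{angle2},
#'   \code{angle3} (degrees, unordered).
#' @export
branching_angles <- function(net, flowing_only = FALSE) {
  segs <- net$segments
  if (flowing_only) segs <- segs[segs$flowing, , drop = FALSE]
  deg <- table(c(segs$from, segs$to))
  nodes3 <- as.numeric(names(deg)[deg == 3])
  out <- data.frame(node = numeric(0), angle1 = numeric(0),
                    angle2 = numeric(0), angle3 = numeric(0))
  for (nd in nodes3) {
    att <- segs[segs$from == nd | segs$to == nd, , drop = FALSE]
    other <- ifelse(att$from == nd, att$to, att$from)
    oi <- match(other, net$nodes$id)
    ni <- match(nd, net$nodes$id)
    ux <- net$nodes$x[oi] - net$nodes$x[ni]
    uy <- net$nodes$y[oi] - net$nodes$y[ni]
    nv <- sqrt(ux^2 + uy^2)
    ux <- ux / nv; uy <- uy / nv
    th <- atan2(uy, ux)
    th <- sort(th)
    gaps <- c(diff(th), 2 * pi - (th[3] - th[1])) * 180 / pi
    out <- rbind(out, data.frame(node = nd, angle1 = gaps[1],
                                 angle2 = gaps[2], angle3 = gaps[3]))
  }
  out
}

#' Distance from tissue points to the nearest vessel
#'
#' Exact Euclidean point-to-segment distance minimized over all segments.
#'
#' @param net a \code{vascular_network} with at least one segment.
#' @param points data.frame or matrix with columns/cols \code{x}, \code{y}
#'   (um); defaults to the network's tissue-domain points.
#' @param flowing_only restrict to flow-eligible segments.
#' @return numeric vector of distances (um).
#' @export
distance_to_nearest_vessel <- function(net, points = NULL,
                                       flowing_only = FALSE) {
  if (is.null(points)) {
    if (is.null(net$domain)) stop("no points given and network has no domain")
    points <- net$domain$points
  }
  points <- as.data.frame(points)
  segs <- net$segments
  if (flowing_only) segs <- segs[segs$flowing, , drop = FALSE]
  if (nrow(segs) == 0) stop("network has no segments")
  co <- segment_coords(net)
  if (flowing_only) co <- co[net$segments$flowing, , drop = FALSE]
  best <- rep(Inf, nrow(points))
  for (k in seq_len(nrow(co))) {
    d <- point_segment_distance(points$x, points$y,
                                co[k, 1], co[k, 2], co[k, 3], co[k, 4])$dist
    best <- pmin(best, d)
  }
  best
}

# -- internal structural helpers -------------------------------------------

new_node <- function(net, x, y, kind = "interior") {
  id <- net$next_node_id
  net$next_node_id <- id + 1
  net$nodes <- rbind(net$nodes, data.frame(
    id = id, x = x, y = y, kind = kind, bc_type = NA_character_,
    bc_value = NA_real_, bc_hematocrit = NA_real_, bc_po2 = NA_real_))
  list(net = net, id = id)
}

new_segment <- function(net, from, to, diameter, type = "capillary",
                        flowing = TRUE, fixed = FALSE) {
  id <- net$next_segment_id
  net$next_segment_id <- id + 1
  net$segments <- rbind(net$segments, data.frame(
    id = id, from = from, to = to, diameter = diameter, type = type,
    flowing = flowing, fixed = fixed))
  list(net = net, id = id)
}

drop_orphan_nodes <- function(net) {
  used <- unique(c(net$segments$from, net$segments$to,
                   net$sprouts$tip_node))
  keep <- net$nodes$id %in% used | net$nodes$kind == "boundary"
  net$nodes <- net$nodes[keep, , drop = FALSE]
  net
}
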