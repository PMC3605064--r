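# Tension-induced lateral migration of nodes. Vessels carry longitudinal
# tension proportional to diameter; the unbalanced resultant at a node
# pulls it through the interstitium, remodeling branch angles (a fresh
# 90/90/180 bifurcation relaxes toward a smoother, near-120-degree
# configuration).

#' Migration parameters
#'
#' @param lambda_t normalized-force threshold below which nodes do not move
#'   (0.05); the threshold stabilizes curved vessels.
#' @param v_max maximum migration speed, um/day (1), attained at the
#'   maximal force imbalance |f_t| = 1.
#' @return list of class \code{migration_params}.
#' @export
migration_params <- function(lambda_t = 0.05, v_max = 1) {
  structure(as.list(environment()), class = "migration_params")
}

#' Normalized tension force at nodes
#'
#' f_t = sum(D_i e_i) / sum(D_i) over the segments at each node, where e_i
#' is the unit vector from the node along segment i; |f_t| <= 1 by
#' construction.
#'
#' @param net a \code{vascular_network}.
#' @param node_ids nodes to evaluate; default all.
#' @return data.frame with \code{node}, \code{fx}, \code{fy}, \code{fmag}.
#' @export
node_tension_force <- function(net, node_ids = net$nodes$id) {
  segs <- net$segments
  co <- segment_coords(net)
  out <- data.frame(node = node_ids, fx = 0, fy = 0, fmag = 0)
  for (q in seq_along(node_ids)) {
    nd <- node_ids[q]
    att <- which(segs$from == nd | segs$to == nd)
    if (length(att) == 0) next
    sumD <- 0; fx <- 0; fy <- 0
    for (k in att) {
      if (segs$from[k] == nd) {
        ux <- co[k, 3] - co[k, 1]; uy <- co[k, 4] - co[k, 2]
      } else {
        ux <- co[k, 1] - co[k, 3]; uy <- co[k, 2] - co[k, 4]
      }
      l <- sqrt(ux^2 + uy^2)
      D <- segs$diameter[k]
      fx <- fx + D * ux / l
      fy <- fy + D * uy / l
      sumD <- sumD + D
    }
    out$fx[q] <- fx / sumD
    out$fy[q] <- fy / sumD
    out$fmag[q] <- sqrt(out$fx[q]^2 + out$fy[q]^2)
  }
  out
}

#' Migrate nodes under tension imbalance
#'
#' Interior nodes (including non-branching ones, but not sprout tips) with
#' |f_t| > lambda_t move along f_t with speed
#' v_max (|f_t| - lambda_t)/(1 - lambda_t); displacements are evaluated
#' from a frozen force field and applied synchronously, each capped so no
#' segment drops below the 10 um minimum length and no node leaves the
#' tissue domain.
#'
#' @param net a \code{vascular_network}.
#' @param params a \code{migration_params}.
#' @param dt time step (day).
#' @return updated network.
#' @export
migrate_nodes <- function(net, params = migration_params(), dt = 1) {
  fixed_kind <- net$nodes$kind == "boundary"
  tips <- net$sprouts$tip_node
  movable <- net$nodes$id[!fixed_kind & !(net$nodes$id %in% tips)]
  if (length(movable) == 0) return(net)
  f <- node_tension_force(net, movable)
  move <- f$fmag > params$lambda_t
  if (!any(move)) return(net)
  speed <- params$v_max * (f$fmag - params$lambda_t) / (1 - params$lambda_t)
  newx <- net$nodes$x
  newy <- net$nodes$y
  for (q in which(move)) {
    nd <- f$node[q]
    ni <- match(nd, net$nodes$id)
    step <- speed[q] * dt
    att <- which(net$segments$from == nd | net$segments$to == nd)
    dx <- f$fx[q] / f$fmag[q] * step
    dy <- f$fy[q] / f$fmag[q] * step
    # cap the displacement against the minimum-length constraints of the
    # attached segments: remove the component that would shrink a
    # segment below 10 um (the node slides along the constraint), with a
    # final feasibility check
    for (pass in 1:2) {
      for (k in att) {
        other <- if (net$segments$from[k] == nd) net$segments$to[k]
                 else net$segments$from[k]
        oi <- match(other, net$nodes$id)
        ux <- newx[oi] - net$nodes$x[ni]
        uy <- newy[oi] - net$nodes$y[ni]
        L <- sqrt(ux^2 + uy^2)
        ux <- ux / L; uy <- uy / L
        shrink <- dx * ux + dy * uy            # motion toward the other end
        slack <- L - MIN_SEGMENT_LENGTH
        if (shrink > slack) {
          dx <- dx - (shrink - slack) * ux
          dy <- dy - (shrink - slack) * uy
        }
      }
    }
    px <- net$nodes$x[ni] + dx
    py <- net$nodes$y[ni] + dy
    if (!is.null(net$domain) &&
        !points_in_polygon(px, py, net$domain$boundary)) next
    ok <- TRUE
    for (k in att) {
      other <- if (net$segments$from[k] == nd) net$segments$to[k]
               else net$segments$from[k]
      oi <- match(other, net$nodes$id)
      if (sqrt((px - newx[oi])^2 + (py - newy[oi])^2) <
            MIN_SEGMENT_LENGTH - 1e-9) { ok <- FALSE; break }
    }
    if (!ok) next
    newx[ni] <- px
    newy[ni] <- py
  }
  net$nodes$x <- newx
  net$nodes$y <- newy
  net
}
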