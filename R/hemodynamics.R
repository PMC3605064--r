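# Steady network hemodynamics: Poiseuille resistances with the empirical
# in-vivo apparent-viscosity law, nodal pressure solve, hematocrit
# propagation with red-cell phase separation at diverging bifurcations, and
# wall shear stress. Units: um, mmHg, nl/min, cP, dyn/cm2.

#' Poiseuille flow resistance of a segment
#'
#' R = 128 eta L / (pi D^4) converted so that Q (nl/min) = dP (mmHg) / R.
#'
#' @param L segment length (um).
#' @param D diameter (um).
#' @param eta apparent viscosity (cP).
#' @return resistance in mmHg.min/nl.
#' @export
segment_resistance <- function(L, D, eta) {
  if (any(L <= 0) || any(D <= 0)) stop("L and D must be positive")
  POISEUILLE_UNIT * 128 * eta * L / (pi * D^4)
}

#' In-vivo apparent viscosity of blood
#'
#' The empirical diameter- and hematocrit-dependent relative apparent
#' viscosity of blood flowing in microvessels in vivo (the
#' Fahraeus-Lindqvist relation with the endothelial-surface-layer
#' correction), multiplied by the plasma viscosity.
#'
#' @param D vessel diameter (um).
#' @param H_D discharge hematocrit in \[0, 1).
#' @param plasma_viscosity plasma viscosity (cP), default 1.
#' @return apparent viscosity (cP).
#' @export
apparent_viscosity <- function(D, H_D, plasma_viscosity = 1) {
  if (any(H_D < 0) || any(H_D >= 1)) stop("H_D must be in [0, 1)")
  eta45 <- 6 * exp(-0.085 * D) + 3.2 - 2.44 * exp(-0.06 * D^0.645)
  C <- (0.8 + exp(-0.075 * D)) *
    (-1 + 1 / (1 + 1e-11 * D^12)) + 1 / (1 + 1e-11 * D^12)
  wall <- (D / (D - 1.1))^2
  rel <- (1 + (eta45 - 1) * ((1 - H_D)^C - 1) / ((1 - 0.45)^C - 1) * wall) *
    wall
  plasma_viscosity * rel
}

#' Red-cell phase separation at a diverging bifurcation
#'
#' Empirical logit partition of red-cell flux between the daughters of a
#' diverging bifurcation, as a function of the fractional blood flows,
#' daughter diameters and parent diameter/hematocrit. Red-cell flux is
#' conserved exactly; daughter hematocrits are capped at 1 with the excess
#' cells routed to the other daughter.
#'
#' @param parent_H discharge hematocrit of the parent.
#' @param parent_D parent diameter (um).
#' @param daughter_D numeric(2), daughter diameters (um).
#' @param daughter_Q numeric(2), daughter flows (nl/min, positive out of the
#'   bifurcation; must sum to the parent flow).
#' @param parent_Q parent flow (nl/min); default \code{sum(daughter_Q)}.
#' @return numeric(2) daughter discharge hematocrits.
#' @export
phase_separation <- function(parent_H, parent_D, daughter_D, daughter_Q,
                             parent_Q = sum(daughter_Q)) {
  if (any(daughter_Q < 0)) stop("daughter flows must be positive out of parent")
  if (abs(sum(daughter_Q) - parent_Q) > 1e-6 * max(parent_Q, 1e-12)) {
    stop("flow imbalance at bifurcation")
  }
  if (parent_H <= 0) return(c(0, 0))
  if (parent_Q <= 0) return(c(parent_H, parent_H))
  FQB <- daughter_Q[1] / parent_Q
  X0 <- 0.4 / parent_D
  if (FQB <= X0) {
    FQE <- 0
  } else if (FQB >= 1 - X0) {
    FQE <- 1
  } else {
    A <- -6.96 * log(daughter_D[1] / daughter_D[2]) / parent_D
    B <- 1 + 6.98 * (1 - parent_H) / parent_D
    xarg <- (FQB - X0) / (1 - 2 * X0)
    logitx <- log(xarg / (1 - xarg))
    FQE <- 1 / (1 + exp(-(A + B * logitx)))
  }
  rbc <- parent_Q * parent_H
  H1 <- if (daughter_Q[1] > 0) FQE * rbc / daughter_Q[1] else 0
  H2 <- if (daughter_Q[2] > 0) (1 - FQE) * rbc / daughter_Q[2] else 0
  # cap at 1, conserving red-cell flux
  if (H1 > 1) {
    H2 <- H2 + (H1 - 1) * daughter_Q[1] / max(daughter_Q[2], 1e-12)
    H1 <- 1
  }
  if (H2 > 1) {
    H1 <- H1 + (H2 - 1) * daughter_Q[2] / max(daughter_Q[1], 1e-12)
    H2 <- min(H2, 1)
    H1 <- min(H1, 1)
  }
  c(H1, H2)
}

#' Wall shear stress of a segment
#'
#' tau_w = dP * D / (4 L), equivalently 32 eta |Q| / (pi D^3), in dyn/cm2.
#'
#' @param dP pressure drop magnitude (mmHg).
#' @param D diameter (um).
#' @param L length (um).
#' @return shear stress (dyn/cm2).
#' @export
wall_shear_stress <- function(dP, D, L) {
  abs(dP) * MMHG_TO_DYN_CM2 * D / (4 * L)
}

#' Solve steady blood flow in a network
#'
#' Assembles nodal flow conservation into a linear system for nodal
#' pressures (pressure boundary nodes as Dirichlet conditions, flow
#' boundary nodes as source terms), computes segment flows, propagates
#' discharge hematocrit from the inflows through the network with phase
#' separation at diverging bifurcations and flow-weighted mixing at
#' converging ones, and iterates the viscosity/flow/hematocrit loop to a
#' fixed point.
#'
#' @param net a \code{vascular_network} with boundary conditions assigned
#'   and at least one pressure boundary node.
#' @param tol relative convergence tolerance on flows and hematocrits.
#' @param max_iter maximum outer iterations.
#' @param damping under-relaxation factor for hematocrit updates.
#' @param plasma_viscosity plasma viscosity (cP).
#' @return object of class \code{hemodynamic_state}: per-node
#'   \code{pressure} (mmHg) and per-segment \code{flow} (nl/min, signed
#'   from -> to), \code{hematocrit}, \code{viscosity} (cP), \code{shear}
#'   (dyn/cm2), \code{dP} (mmHg), plus the node/segment id vectors.
#' @export
solve_flow <- function(net, tol = 1e-4, max_iter = 100, damping = 0.5,
                       plasma_viscosity = 1) {
  segs <- net$segments[net$segments$flowing, , drop = FALSE]
  nodes <- net$nodes
  if (nrow(segs) == 0) stop("no flow-eligible segments")
  if (!any(nodes$kind == "boundary" & !is.na(nodes$bc_type) &
             nodes$bc_type == "pressure")) {
    stop("network needs at least one pressure boundary condition")
  }
  # restrict to nodes touching flowing segments
  used <- nodes$id %in% c(segs$from, segs$to)
  nodes <- nodes[used, , drop = FALSE]
  nid <- nodes$id
  n <- length(nid)
  i <- match(segs$from, nid)
  j <- match(segs$to, nid)
  len <- {
    co <- nodes[match(segs$from, nodes$id), c("x", "y")]
    co2 <- nodes[match(segs$to, nodes$id), c("x", "y")]
    sqrt((co2$x - co$x)^2 + (co2$y - co$y)^2)
  }
  is_pressure <- nodes$kind == "boundary" & !is.na(nodes$bc_type) &
    nodes$bc_type == "pressure"
  is_flow <- nodes$kind == "boundary" & !is.na(nodes$bc_type) &
    nodes$bc_type == "flow"

  H <- rep(mean(nodes$bc_hematocrit[!is.na(nodes$bc_hematocrit)],
                na.rm = TRUE), nrow(segs))
  if (!is.finite(H[1])) H <- rep(0.4, nrow(segs))
  Q <- rep(0, nrow(segs))
  P <- rep(NA_real_, n)
  for (iter in seq_len(max_iter)) {
    eta <- apparent_viscosity(segs$diameter, pmin(H, 0.99), plasma_viscosity)
    g <- 1 / segment_resistance(len, segs$diameter, eta)
    # assemble Laplacian with Dirichlet rows for pressure nodes
    trip_i <- c(i, j, i, j)
    trip_j <- c(i, j, j, i)
    trip_x <- c(g, g, -g, -g)
    keep <- !is_pressure[trip_i]
    A <- Matrix::sparseMatrix(i = trip_i[keep], j = trip_j[keep],
                              x = trip_x[keep], dims = c(n, n))
    A <- A + Matrix::sparseMatrix(i = which(is_pressure),
                                  j = which(is_pressure),
                                  x = rep(1, sum(is_pressure)),
                                  dims = c(n, n))
    b <- rep(0, n)
    b[is_pressure] <- nodes$bc_value[is_pressure]
    b[is_flow] <- b[is_flow] + nodes$bc_value[is_flow]
    P_new <- as.numeric(Matrix::solve(A, b))
    Q_new <- g * (P_new[i] - P_new[j])
    H_new <- propagate_hematocrit(segs, nodes, i, j, Q_new, H)
    dQ <- max(abs(Q_new - Q)) / max(max(abs(Q_new)), 1e-12)
    dH <- max(abs(H_new - H))
    P <- P_new
    Q <- Q_new
    H <- H + damping * (H_new - H)
    if (iter > 1 && dQ < tol && dH < tol) {
      H <- H_new
      break
    }
    if (iter == max_iter) {
      warning(sprintf(
        "flow solve did not converge in %d iterations (dQ=%.2e dH=%.2e)",
        max_iter, dQ, dH))
    }
  }
  # final consistent pass: pressures, flows and shear all evaluated at
  # the converged hematocrit's viscosity
  eta <- apparent_viscosity(segs$diameter, pmin(H, 0.99), plasma_viscosity)
  g <- 1 / segment_resistance(len, segs$diameter, eta)
  trip_i <- c(i, j, i, j)
  trip_j <- c(i, j, j, i)
  trip_x <- c(g, g, -g, -g)
  keep <- !is_pressure[trip_i]
  A <- Matrix::sparseMatrix(i = trip_i[keep], j = trip_j[keep],
                            x = trip_x[keep], dims = c(n, n)) +
    Matrix::sparseMatrix(i = which(is_pressure), j = which(is_pressure),
                         x = rep(1, sum(is_pressure)), dims = c(n, n))
  b <- rep(0, n)
  b[is_pressure] <- nodes$bc_value[is_pressure]
  b[is_flow] <- b[is_flow] + nodes$bc_value[is_flow]
  P <- as.numeric(Matrix::solve(A, b))
  Q <- g * (P[i] - P[j])
  # re-propagate hematocrit once with the final flows so red-cell flux
  # conservation holds exactly at the reported state
  H <- propagate_hematocrit(segs, nodes, i, j, Q, H)
  dP <- P[i] - P[j]
  tau <- wall_shear_stress(dP, segs$diameter, len)
  structure(list(
    node_id = nid, pressure = P,
    segment_id = segs$id, flow = Q, hematocrit = H, viscosity = eta,
    shear = tau, dP = dP, length = len,
    from = segs$from, to = segs$to, diameter = segs$diameter),
    class = "hemodynamic_state")
}

#' @export
print.hemodynamic_state <- function(x, ...) {
  cat(sprintf(paste0("hemodynamic_state: %d nodes, %d segments; ",
                     "|Q| range %.3g-%.3g nl/min, mean H_D %.3f\n"),
              length(x$node_id), length(x$segment_id),
              min(abs(x$flow)), max(abs(x$flow)), mean(x$hematocrit)))
  invisible(x)
}

# Propagate discharge hematocrit from inflow boundaries downstream.
# Traversal follows flow direction; diverging bifurcations use the
# empirical phase-separation law, converging junctions mix by red-cell
# flux conservation; junctions of more than three vessels are resolved
# pairwise in descending-flow order.
propagate_hematocrit <- function(segs, nodes, i, j, Q, H_prev,
                                 q_eps = 1e-12) {
  ns <- nrow(segs)
  n <- nrow(nodes)
  up_node <- ifelse(Q >= 0, i, j)     # local node index blood comes from
  dn_node <- ifelse(Q >= 0, j, i)
  absQ <- abs(Q)
  H <- H_prev
  inflow_H <- nodes$bc_hematocrit
  # process nodes in topological order of flow where possible
  remaining <- rep(TRUE, ns)
  # incoming count per node: segments whose dn_node is the node
  H_assigned <- rep(FALSE, ns)
  n_in <- tabulate(dn_node[absQ > q_eps], nbins = n)
  ready_in <- integer(n)             # how many feeding segments resolved
  # boundary inflow segments: up_node is a boundary node with bc hematocrit
  node_H_flux <- rep(0, n)           # accumulated rbc flux arriving
  node_Q_in <- rep(0, n)
  # seed: nodes with no unresolved inflows (boundary inflow nodes)
  queue <- which(n_in == 0)
  guard <- 0
  while (length(queue) > 0 && guard < 10 * (ns + n)) {
    guard <- guard + 1
    nd <- queue[1]; queue <- queue[-1]
    # hematocrit delivered to node nd
    H_nd <- if (node_Q_in[nd] > q_eps) {
      node_H_flux[nd] / node_Q_in[nd]
    } else if (!is.na(inflow_H[nd])) {
      inflow_H[nd]
    } else {
      NA_real_
    }
    out_segs <- which(up_node == nd & absQ > q_eps)
    if (length(out_segs) == 0) next
    if (is.na(H_nd)) H_nd <- 0
    H_nd <- min(H_nd, 1)
    if (length(out_segs) == 1) {
      H_out <- H_nd
      H[out_segs] <- H_out
    } else {
      # resolve pairwise in descending flow order
      ord <- out_segs[order(-absQ[out_segs])]
      remQ <- sum(absQ[ord]); remH <- H_nd
      # parent diameter: the largest feeding segment, else largest daughter
      in_segs <- which(dn_node == nd & absQ > q_eps)
      pD <- if (length(in_segs) > 0) max(segs$diameter[in_segs])
            else max(segs$diameter[ord])
      k <- 1
      while (k < length(ord)) {
        d1 <- ord[k]
        Q1 <- absQ[d1]
        Q2 <- remQ - Q1
        d2D <- if (k + 1 == length(ord)) segs$diameter[ord[k + 1]]
               else max(segs$diameter[ord[(k + 1):length(ord)]])
        hh <- phase_separation(remH, pD, c(segs$diameter[d1], d2D),
                               c(Q1, Q2), remQ)
        H[d1] <- hh[1]
        remH <- hh[2]
        remQ <- Q2
        k <- k + 1
      }
      H[ord[length(ord)]] <- remH
    }
    for (s in out_segs) {
      if (!H_assigned[s]) {
        H_assigned[s] <- TRUE
        tgt <- dn_node[s]
        node_H_flux[tgt] <- node_H_flux[tgt] + absQ[s] * H[s]
        node_Q_in[tgt] <- node_Q_in[tgt] + absQ[s]
        ready_in[tgt] <- ready_in[tgt] + 1
        if (ready_in[tgt] >= n_in[tgt]) queue <- c(queue, tgt)
      }
    }
  }
  # segments with negligible flow keep previous hematocrit
  H[absQ <= q_eps] <- H_prev[absQ <= q_eps]
  pmin(pmax(H, 0), 1)
}
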