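# Stochastic sprout formation on existing vessels, persistent-direction
# elongation with filopodia-mediated homing toward nearby vessels, and
# connection/suppression handling.

#' Angiogenesis parameters
#'
#' @param dt time step (day).
#' @param D_s diameter of new, non-flowing sprouts (um).
#' @param C_th threshold VEGF concentration for sprouting (pM).
#' @param C_th50 half-saturation increment of the sprouting rate (pM).
#' @param k_sprout maximal sprout formation rate per vessel length per time
#'   (um-1 day-1); 0.002 corresponds to 2 mm-1 day-1.
#' @param V_g sprout elongation rate (um/day).
#' @param k_V sensitivity of growth direction to nearby vessels (um-1).
#' @param R_max filopodia sensing radius (um).
#' @param theta_max half-angle of the sensing sector (rad).
#' @param sigma_s variance (rad2) of the per-step Gaussian growth-direction
#'   randomization.
#' @param substep elongation increment (um) between connection checks.
#' @return list of class \code{angiogenesis_params}.
#' @export
angiogenesis_params <- function(dt = 1, D_s = 10, C_th = 0.8, C_th50 = 0.5,
                                k_sprout = 0.002, V_g = 50, k_V = 10,
                                R_max = 100, theta_max = pi / 3,
                                sigma_s = 0.1, substep = 5) {
  structure(as.list(environment()), class = "angiogenesis_params")
}

#' Sprout formation probability of a segment
#'
#' The local sprouting rate per unit length is zero at or below the VEGF
#' threshold C_th and rises with the excess concentration, saturating at
#' k_sprout: rate(C) = k_sprout (C - C_th) / ((C - C_th) + C_th50). The
#' per-segment, per-step probability is rate x length x dt, capped at 1.
#'
#' @param C_G local VEGF concentration (pM).
#' @param segment_length segment length (um).
#' @param params an \code{angiogenesis_params}.
#' @return probability in \[0, 1\].
#' @export
sprout_formation_probability <- function(C_G, segment_length,
                                         params = angiogenesis_params()) {
  ex <- pmax(C_G - params$C_th, 0)
  rate <- params$k_sprout * ex / (ex + params$C_th50)
  rate[ex == 0] <- 0
  pmin(rate * segment_length * params$dt, 1)
}

#' Create a sprout on a segment
#'
#' Attaches a new sprout at the given point of the parent segment
#' (sampled uniformly by the caller). If the point lies within 10 um of an
#' end node of the parent, the attachment moves to that node; if that node
#' is a network boundary node or an existing branch point, the sprout is
#' suppressed. The initial direction is perpendicular to the parent, the
#' sign chosen with equal probability. New sprouts have diameter D_s and a
#' first segment of 10 um is laid immediately so the tip is a real node.
#'
#' @param net a \code{vascular_network}.
#' @param segment_id parent segment id.
#' @param t_frac position along the parent in \[0, 1\].
#' @param params an \code{angiogenesis_params}.
#' @return list \code{net}, \code{outcome} ("sprouted" or "suppressed").
#' @export
spawn_sprout <- function(net, segment_id, t_frac,
                         params = angiogenesis_params()) {
  si <- match(segment_id, net$segments$id)
  if (is.na(si)) stop("no such segment")
  seg <- net$segments[si, ]
  fi <- match(seg$from, net$nodes$id)
  toi <- match(seg$to, net$nodes$id)
  L <- sqrt((net$nodes$x[toi] - net$nodes$x[fi])^2 +
            (net$nodes$y[toi] - net$nodes$y[fi])^2)
  s <- t_frac * L
  ux <- (net$nodes$x[toi] - net$nodes$x[fi]) / L
  uy <- (net$nodes$y[toi] - net$nodes$y[fi]) / L
  attach <- NA_integer_
  if (s < MIN_SEGMENT_LENGTH) attach <- seg$from
  if (L - s < MIN_SEGMENT_LENGTH) attach <- seg$to
  if (!is.na(attach)) {
    ai <- match(attach, net$nodes$id)
    deg <- sum(net$segments$from == attach | net$segments$to == attach)
    if (net$nodes$kind[ai] == "boundary" || deg >= 3) {
      return(list(net = net, outcome = "suppressed"))
    }
    ax <- net$nodes$x[ai]; ay <- net$nodes$y[ai]
    anode <- attach
  } else {
    ax <- net$nodes$x[fi] + (s / L) * (net$nodes$x[toi] - net$nodes$x[fi])
    ay <- net$nodes$y[fi] + (s / L) * (net$nodes$y[toi] - net$nodes$y[fi])
    nn <- new_node(net, ax, ay)
    net <- nn$net
    anode <- nn$id
    # split parent at the attachment point
    net$segments$to[match(segment_id, net$segments$id)] <- anode
    ns <- new_segment(net, anode, seg$to, seg$diameter, seg$type,
                      seg$flowing, seg$fixed)
    net <- ns$net
  }
  sgn <- if (stats::runif(1) < 0.5) 1 else -1
  dx <- -uy * sgn; dy <- ux * sgn
  # lay the first 10 um of the sprout so the tip is a node
  tipx <- ax + dx * MIN_SEGMENT_LENGTH
  tipy <- ay + dy * MIN_SEGMENT_LENGTH
  if (!is.null(net$domain) &&
      !points_in_polygon(tipx, tipy, net$domain$boundary)) {
    # flip toward the interior; if both sides leave the domain, suppress
    dx <- -dx; dy <- -dy
    tipx <- ax + dx * MIN_SEGMENT_LENGTH
    tipy <- ay + dy * MIN_SEGMENT_LENGTH
    if (!points_in_polygon(tipx, tipy, net$domain$boundary)) {
      return(list(net = net, outcome = "suppressed"))
    }
  }
  tn <- new_node(net, tipx, tipy)
  net <- tn$net
  ns <- new_segment(net, anode, tn$id, params$D_s, "sprout",
                    flowing = FALSE)
  net <- ns$net
  sp_id <- if (nrow(net$sprouts) > 0) max(net$sprouts$id) + 1 else 1
  net$sprouts <- rbind(net$sprouts, data.frame(
    id = sp_id, tip_node = tn$id, dir_x = dx, dir_y = dy,
    attach_node = anode, age = 0))
  list(net = net, outcome = "sprouted", sign = sgn)
}

#' Filopodia homing vector of a sprout tip
#'
#' Attraction toward vessels lying within a sector of radius R_max and
#' half-angle theta_max about the current growth direction. Each in-sector
#' piece of vessel contributes f(r) g(theta) toward itself, with
#' f(r) = 1 - r/R_max and g(theta) = 1 - |theta|/theta_max, both vanishing
#' at the sector edge; line integrals use midpoint quadrature on <= 5 um
#' sub-elements. The sprout's own chain is excluded.
#'
#' @param net a \code{vascular_network}.
#' @param tip_x,tip_y tip position (um).
#' @param dir_x,dir_y unit growth direction.
#' @param exclude_segments segment ids excluded from attraction (own chain).
#' @param params an \code{angiogenesis_params}.
#' @return numeric(2) attraction vector (um-weighted).
#' @export
homing_vector <- function(net, tip_x, tip_y, dir_x, dir_y,
                          exclude_segments = integer(0),
                          params = angiogenesis_params()) {
  segs <- net$segments
  co <- segment_coords(net)
  V <- c(0, 0)
  for (k in seq_len(nrow(segs))) {
    if (segs$id[k] %in% exclude_segments) next
    # quick reject by bounding distance
    d <- point_segment_distance(tip_x, tip_y, co[k, 1], co[k, 2],
                                co[k, 3], co[k, 4])$dist
    if (d >= params$R_max) next
    L <- sqrt((co[k, 3] - co[k, 1])^2 + (co[k, 4] - co[k, 2])^2)
    nsub <- max(1, ceiling(L / 5))
    tm <- (seq_len(nsub) - 0.5) / nsub
    qx <- co[k, 1] + tm * (co[k, 3] - co[k, 1])
    qy <- co[k, 2] + tm * (co[k, 4] - co[k, 2])
    rx <- qx - tip_x; ry <- qy - tip_y
    r <- sqrt(rx^2 + ry^2)
    ok <- r > 1e-9 & r < params$R_max
    if (!any(ok)) next
    cth <- (rx * dir_x + ry * dir_y) / r
    theta <- acos(pmin(pmax(cth, -1), 1))
    ok <- ok & theta < params$theta_max
    if (!any(ok)) next
    w <- (1 - r[ok] / params$R_max) *
      (1 - theta[ok] / params$theta_max) * (L / nsub)
    V <- V + c(sum(w * rx[ok] / r[ok]), sum(w * ry[ok] / r[ok]))
  }
  V
}

# segment ids forming the sprout chain ending at tip (walk through sprout
# segments), used to exclude self-attraction; includes segments at the
# attachment node
sprout_chain_segments <- function(net, tip_node) {
  out <- integer(0)
  nd <- tip_node
  seen <- numeric(0)
  repeat {
    seen <- c(seen, nd)
    att <- which((net$segments$from == nd | net$segments$to == nd) &
                   !(net$segments$id %in% out))
    spr <- att[net$segments$type[att] == "sprout"]
    if (length(spr) == 0) break
    out <- c(out, net$segments$id[spr])
    nxt <- setdiff(unique(c(net$segments$from[spr], net$segments$to[spr])),
                   seen)
    if (length(nxt) == 0) break
    nd <- nxt[1]
  }
  out
}

#' Advance a sprout by one time step
#'
#' The growth direction is rotated by a Gaussian random angle (zero mean,
#' variance sigma_s) representing matrix heterogeneity, then combined with
#' the homing attraction: d' = normalize(d + k_V V). The tip then advances
#' V_g dt in 5 um increments; after each increment, if another segment lies
#' within 5 um a connection is formed, and a tip crossing the tissue
#' boundary suppresses the sprout.
#'
#' @param net a \code{vascular_network}.
#' @param sprout_id id in \code{net$sprouts}.
#' @param vegf_state unused by the growth rule (growth is not biased up the
#'   VEGF gradient); accepted for interface uniformity.
#' @param params an \code{angiogenesis_params}.
#' @return list \code{net}, \code{outcome} ("growing", "connected" or
#'   "suppressed").
#' @export
advance_sprout <- function(net, sprout_id, vegf_state = NULL,
                           params = angiogenesis_params()) {
  spi <- match(sprout_id, net$sprouts$id)
  if (is.na(spi)) stop("no such sprout")
  sp <- net$sprouts[spi, ]
  tip <- match(sp$tip_node, net$nodes$id)
  tx <- net$nodes$x[tip]; ty <- net$nodes$y[tip]
  d <- c(sp$dir_x, sp$dir_y)
  ang <- stats::rnorm(1, 0, sqrt(params$sigma_s))
  d <- as.numeric(rotate_vec(d[1], d[2], ang))
  excl <- sprout_chain_segments(net, sp$tip_node)
  V <- homing_vector(net, tx, ty, d[1], d[2], excl, params)
  d <- d + params$k_V * V
  d <- d / sqrt(sum(d^2))
  n_sub <- round(params$V_g * params$dt / params$substep)
  # the day's growth is laid as one new straight segment from the old tip
  start_node <- sp$tip_node
  sx <- tx; sy <- ty
  adv <- 0
  for (ss in seq_len(n_sub)) {
    nx <- sx + d[1] * (adv + params$substep)
    ny <- sy + d[2] * (adv + params$substep)
    if (!is.null(net$domain) &&
        (!points_in_polygon(nx, ny, net$domain$boundary, tol = 0) ||
         segment_crosses_polygon(sx, sy, nx, ny, net$domain$boundary))) {
      net <- remove_sprout_chain(net, sp$tip_node)
      return(list(net = net, outcome = "suppressed"))
    }
    adv <- adv + params$substep
    # proximity check against all segments except the sprout's own chain
    # and segments touching the current tip node
    tgt <- .nearest_foreign_segment(net, nx, ny, start_node, excl)
    if (!is.null(tgt) && tgt$dist < params$substep) {
      net <- .grow_tip(net, spi, sx, sy, d, adv, params)
      sp2 <- net$sprouts[net$sprouts$id == sprout_id, ]
      res <- add_sprout_connection(net, sp2$tip_node, tgt$id)
      return(list(net = res$net, outcome = res$outcome))
    }
  }
  net <- .grow_tip(net, spi, sx, sy, d, adv, params)
  net$sprouts$age[net$sprouts$id == sprout_id] <-
    net$sprouts$age[net$sprouts$id == sprout_id] + 1
  list(net = net, outcome = "growing")
}

.nearest_foreign_segment <- function(net, px, py, tip_node, excl) {
  segs <- net$segments
  co <- segment_coords(net)
  best <- Inf; best_id <- NA_integer_
  for (k in seq_len(nrow(segs))) {
    if (segs$id[k] %in% excl) next
    if (segs$from[k] == tip_node || segs$to[k] == tip_node) next
    d <- point_segment_distance(px, py, co[k, 1], co[k, 2],
                                co[k, 3], co[k, 4])$dist
    if (d < best) { best <- d; best_id <- segs$id[k] }
  }
  if (is.na(best_id)) return(NULL)
  list(id = best_id, dist = best)
}

# advance the tip node by `adv` um along d, appending a new segment from
# the previous tip (merged with the trailing segment when collinear growth
# would create a short piece)
.grow_tip <- function(net, spi, sx, sy, d, adv, params) {
  if (adv <= 0) return(net)
  sp <- net$sprouts[spi, ]
  tipid <- sp$tip_node
  nx <- sx + d[1] * adv
  ny <- sy + d[2] * adv
  if (adv < MIN_SEGMENT_LENGTH) {
    # too short for a new segment: displace the tip node, unless that
    # would leave the trailing segment under the minimum length
    ti <- match(tipid, net$nodes$id)
    trail <- which(net$segments$from == tipid | net$segments$to == tipid)
    prev <- if (net$segments$from[trail[1]] == tipid)
      net$segments$to[trail[1]] else net$segments$from[trail[1]]
    pi_ <- match(prev, net$nodes$id)
    if (sqrt((nx - net$nodes$x[pi_])^2 + (ny - net$nodes$y[pi_])^2) >=
          MIN_SEGMENT_LENGTH) {
      net$nodes$x[ti] <- nx
      net$nodes$y[ti] <- ny
    }
  } else {
    nn <- new_node(net, nx, ny)
    net <- nn$net
    ns <- new_segment(net, tipid, nn$id, params$D_s, "sprout",
                      flowing = FALSE)
    net <- ns$net
    net$sprouts$tip_node[spi] <- nn$id
  }
  net$sprouts$dir_x[spi] <- d[1]
  net$sprouts$dir_y[spi] <- d[2]
  net
}
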