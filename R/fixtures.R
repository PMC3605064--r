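# Seed-network synthesis. The simulator starts from a minimal "skeleton":
# a bounding venular loop enclosing the tissue domain, fed by two
# arterioles, with five boundary nodes carrying the printed boundary
# conditions. The observed network's exact geometry is not numerically
# published, so the generator reproduces the topology class and boundary
# data, not coordinates. Also provides deterministic toy networks for unit
# and oracle tests.

#' Boundary-condition specification of the seed skeleton
#'
#' @param area tissue area, mm2 (4.23).
#' @param thickness slab thickness, um (20).
#' @param aspect width/height ratio of the rectangular domain.
#' @param demand oxygen demand M0, cm3 O2/100 cm3/min.
#' @param arteriole_pressure fixed pressure of the first feeding arteriole,
#'   mmHg (59.09).
#' @param arteriole_hematocrit inflow hematocrit of the arterioles (0.3742).
#' @param arteriole_po2 arteriolar inflow PO2, mmHg (75).
#' @param arteriole_flow inflow of the second feeding arteriole, nl/min (15).
#' @param venule_flow inflow of each bounding venule, nl/min (28.1).
#' @param venule_hematocrit venular inflow hematocrit (0.4).
#' @param venule_po2 venular inflow PO2, mmHg (38).
#' @param outflow_pressure pressure at the single outflow, mmHg (15).
#' @param arteriole_D diameter range (um) of the arteriolar taper.
#' @param venule_D diameter range (um) of the venular taper (outflow end
#'   first); bounding venules keep fixed diameters.
#' @param capillary_D initial capillary diameter (um).
#' @return list of class \code{skeleton_spec}.
#' @export
skeleton_spec <- function(area = 4.23, thickness = 20, aspect = 1.25,
                          demand = 2,
                          arteriole_pressure = 59.09,
                          arteriole_hematocrit = 0.3742,
                          arteriole_po2 = 75, arteriole_flow = 15,
                          venule_flow = 28.1, venule_hematocrit = 0.4,
                          venule_po2 = 38, outflow_pressure = 15,
                          arteriole_D = c(25, 12), venule_D = c(35, 20),
                          capillary_D = 8) {
  structure(as.list(environment()), class = "skeleton_spec")
}

#' Generate the seed skeleton network
#'
#' Builds a rectangular tissue domain of the requested area whose boundary
#' is traced by two fixed-diameter venules converging at a single outflow
#' on the left edge, with two feeding arterioles entering from the right
#' edge and reaching the venules through initial capillary paths. Exactly
#' five boundary nodes carry the boundary conditions. Interior vertex
#' positions are jittered slightly (seeded) for geometric realism; the
#' same seed reproduces the skeleton bit for bit.
#'
#' @param spec a \code{skeleton_spec}.
#' @param seed integer seed for the jitter.
#' @param jitter jitter amplitude (um) applied to interior polyline
#'   vertices.
#' @return a \code{vascular_network} with its \code{tissue_domain}.
#' @export
generate_skeleton <- function(spec = skeleton_spec(), seed = 1,
                              jitter = 15) {
  W <- sqrt(spec$area * 1e6 * spec$aspect)
  H <- spec$area * 1e6 / W
  boundary <- rbind(c(0, 0), c(W, 0), c(W, H), c(0, H))
  dom <- tissue_domain(boundary, thickness = spec$thickness,
                       demand = spec$demand)
  streams <- rng_streams(seed, "fixture")
  jit <- function(n) with_stream(streams, "fixture",
                                 stats::runif(n, -jitter, jitter))

  nodes <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      kind = character(0), bc_type = character(0),
                      bc_value = numeric(0), bc_hematocrit = numeric(0),
                      bc_po2 = numeric(0))
  nid <- 0
  add_node <- function(x, y, kind = "interior", bc_type = NA,
                       bc_value = NA, bc_h = NA, bc_po2 = NA) {
    nid <<- nid + 1
    nodes <<- rbind(nodes, data.frame(
      id = nid, x = x, y = y, kind = kind, bc_type = bc_type,
      bc_value = bc_value, bc_hematocrit = bc_h, bc_po2 = bc_po2))
    nid
  }
  segs <- data.frame(id = integer(0), from = integer(0), to = integer(0),
                     diameter = numeric(0), type = character(0),
                     flowing = logical(0), fixed = logical(0))
  sid <- 0
  add_seg <- function(from, to, D, type, fixed = FALSE) {
    sid <<- sid + 1
    segs <<- rbind(segs, data.frame(
      id = sid, from = from, to = to, diameter = D, type = type,
      flowing = TRUE, fixed = fixed))
    sid
  }
  chain <- function(node_ids, Ds, type, fixed = FALSE) {
    for (k in seq_len(length(node_ids) - 1)) {
      add_seg(node_ids[k], node_ids[k + 1], Ds[k], type, fixed)
    }
  }
  taper <- function(n, from, to) seq(from, to, length.out = n)

  # five boundary nodes
  O <- add_node(0, H / 2, "boundary", "pressure", spec$outflow_pressure)
  VB1 <- add_node(W, H, "boundary", "flow", spec$venule_flow,
                  spec$venule_hematocrit, spec$venule_po2)
  VB2 <- add_node(W, 0, "boundary", "flow", spec$venule_flow,
                  spec$venule_hematocrit, spec$venule_po2)
  A1 <- add_node(W, 0.65 * H, "boundary", "pressure",
                 spec$arteriole_pressure, spec$arteriole_hematocrit,
                 spec$arteriole_po2)
  A2 <- add_node(W, 0.35 * H, "boundary", "flow", spec$arteriole_flow,
                 spec$arteriole_hematocrit, spec$arteriole_po2)

  # venular loop along the domain boundary (fixed diameters)
  J <- add_node(60, H / 2)                       # junction feeding outflow
  v1 <- c(VB1,
          add_node(0.65 * W, H), add_node(0.35 * W, H), add_node(0, H),
          add_node(0, 0.75 * H), J)
  v2 <- c(VB2,
          add_node(0.6 * W, 0), add_node(0.3 * W, 0), add_node(0, 0),
          add_node(0, 0.25 * H), J)
  dv <- taper(5, spec$venule_D[2], spec$venule_D[1])
  chain(v1, dv, "venule", fixed = TRUE)
  chain(v2, dv, "venule", fixed = TRUE)
  add_seg(J, O, spec$venule_D[1], "venule", fixed = TRUE)

  # arteriole 1: enters right edge, runs toward the centre
  a1 <- c(A1,
          add_node(0.85 * W + jit(1), 0.62 * H + jit(1)),
          add_node(0.70 * W + jit(1), 0.56 * H + jit(1)),
          add_node(0.55 * W + jit(1), 0.50 * H + jit(1)))
  chain(a1, taper(3, spec$arteriole_D[1], spec$arteriole_D[2]),
        "arteriole")
  a1t <- a1[length(a1)]
  # arteriole 2: enters lower right
  a2 <- c(A2,
          add_node(0.85 * W + jit(1), 0.30 * H + jit(1)),
          add_node(0.70 * W + jit(1), 0.26 * H + jit(1)))
  chain(a2, taper(2, spec$arteriole_D[1] * 0.8, spec$arteriole_D[2]),
        "arteriole")
  a2t <- a2[length(a2)]

  # initial capillary paths linking arteriolar tips to the venular loop
  c1 <- c(a1t, add_node(0.45 * W + jit(1), 0.72 * H + jit(1)),
          v1[3])                                  # to top venule vertex
  chain(c1, rep(spec$capillary_D, 2), "capillary")
  c2 <- c(a1t, add_node(0.40 * W + jit(1), 0.30 * H + jit(1)),
          v2[3])                                  # to bottom venule vertex
  chain(c2, rep(spec$capillary_D, 2), "capillary")
  c3 <- c(a2t, add_node(0.62 * W + jit(1), 0.12 * H + jit(1)),
          v2[2])
  chain(c3, rep(spec$capillary_D, 2), "capillary")

  vascular_network(nodes, segs, domain = dom)
}

#' Deterministic toy networks for tests and mechanism experiments
#'
#' @param kind one of "single_segment", "Y_bifurcation", "parallel_loop",
#'   "shunt_pair", "grid_mesh".
#' @param demand tissue oxygen demand for the attached domain.
#' @return a \code{vascular_network} (with a small \code{tissue_domain}).
#' @export
toy_network <- function(kind = c("single_segment", "Y_bifurcation",
                                 "parallel_loop", "shunt_pair",
                                 "grid_mesh"),
                        demand = 2) {
  kind <- match.arg(kind)
  N <- function(...) data.frame(...)
  if (kind == "single_segment") {
    nodes <- rbind(
      N(id = 1, x = 0, y = 250, kind = "boundary", bc_type = "pressure",
        bc_value = 59.09, bc_hematocrit = 0.45, bc_po2 = 75),
      N(id = 2, x = 500, y = 250, kind = "boundary", bc_type = "pressure",
        bc_value = 15, bc_hematocrit = NA, bc_po2 = NA))
    segs <- N(id = 1, from = 1, to = 2, diameter = 20, type = "capillary",
              flowing = TRUE, fixed = FALSE)
    dom <- tissue_domain(rbind(c(0, 0), c(500, 0), c(500, 500), c(0, 500)),
                         demand = demand)
  } else if (kind == "Y_bifurcation") {
    nodes <- rbind(
      N(id = 1, x = 0, y = 250, kind = "boundary", bc_type = "pressure",
        bc_value = 50, bc_hematocrit = 0.45, bc_po2 = 75),
      N(id = 2, x = 250, y = 250, kind = "interior", bc_type = NA,
        bc_value = NA, bc_hematocrit = NA, bc_po2 = NA),
      N(id = 3, x = 500, y = 374, kind = "boundary", bc_type = "pressure",
        bc_value = 20, bc_hematocrit = NA, bc_po2 = NA),
      N(id = 4, x = 500, y = 126, kind = "boundary", bc_type = "pressure",
        bc_value = 20, bc_hematocrit = NA, bc_po2 = NA))
    segs <- rbind(
      N(id = 1, from = 1, to = 2, diameter = 9, type = "capillary",
        flowing = TRUE, fixed = FALSE),
      N(id = 2, from = 2, to = 3, diameter = 7, type = "capillary",
        flowing = TRUE, fixed = FALSE),
      N(id = 3, from = 2, to = 4, diameter = 7, type = "capillary",
        flowing = TRUE, fixed = FALSE))
    dom <- tissue_domain(rbind(c(0, 0), c(500, 0), c(500, 500), c(0, 500)),
                         demand = demand)
  } else if (kind == "parallel_loop") {
    nodes <- rbind(
      N(id = 1, x = 0, y = 250, kind = "boundary", bc_type = "pressure",
        bc_value = 40, bc_hematocrit = 0.45, bc_po2 = 75),
      N(id = 2, x = 100, y = 250, kind = "interior", bc_type = NA,
        bc_value = NA, bc_hematocrit = NA, bc_po2 = NA),
      N(id = 3, x = 250, y = 350, kind = "interior", bc_type = NA,
        bc_value = NA, bc_hematocrit = NA, bc_po2 = NA),
      N(id = 4, x = 250, y = 150, kind = "interior", bc_type = NA,
        bc_value = NA, bc_hematocrit = NA, bc_po2 = NA),
      N(id = 5, x = 400, y = 250, kind = "interior", bc_type = NA,
        bc_value = NA, bc_hematocrit = NA, bc_po2 = NA),
      N(id = 6, x = 500, y = 250, kind = "boundary", bc_type = "pressure",
        bc_value = 20, bc_hematocrit = NA, bc_po2 = NA))
    segs <- rbind(
      N(id = 1, from = 1, to = 2, diameter = 15, type = "arteriole",
        flowing = TRUE, fixed = FALSE),
      N(id = 2, from = 2, to = 3, diameter = 10, type = "capillary",
        flowing = TRUE, fixed = FALSE),
      N(id = 3, from = 3, to = 5, diameter = 10, type = "capillary",
        flowing = TRUE, fixed = FALSE),
      N(id = 4, from = 2, to = 4, diameter = 10, type = "capillary",
        flowing = TRUE, fixed = FALSE),
      N(id = 5, from = 4, to = 5, diameter = 10, type = "capillary",
        flowing = TRUE, fixed = FALSE),
      N(id = 6, from = 5, to = 6, diameter = 15, type = "venule",
        flowing = TRUE, fixed = FALSE))
    dom <- tissue_domain(rbind(c(0, 0), c(500, 0), c(500, 500), c(0, 500)),
                         demand = demand)
  } else if (kind == "shunt_pair") {
    # short direct arteriole-venule path versus long path through distal
    # (hypoxic) tissue
    nodes <- rbind(
      N(id = 1, x = 0, y = 300, kind = "boundary", bc_type = "pressure",
        bc_value = 59.09, bc_hematocrit = 0.4, bc_po2 = 75),
      N(id = 2, x = 150, y = 300, kind = "interior", bc_type = NA,
        bc_value = NA, bc_hematocrit = NA, bc_po2 = NA),
      N(id = 3, x = 350, y = 300, kind = "interior", bc_type = NA,
        bc_value = NA, bc_hematocrit = NA, bc_po2 = NA),
      N(id = 4, x = 350, y = 520, kind = "interior", bc_type = NA,
        bc_value = NA, bc_hematocrit = NA, bc_po2 = NA),
      N(id = 5, x = 750, y = 520, kind = "interior", bc_type = NA,
        bc_value = NA, bc_hematocrit = NA, bc_po2 = NA),
      N(id = 6, x = 750, y = 80, kind = "interior", bc_type = NA,
        bc_value = NA, bc_hematocrit = NA, bc_po2 = NA),
      N(id = 7, x = 350, y = 80, kind = "interior", bc_type = NA,
        bc_value = NA, bc_hematocrit = NA, bc_po2 = NA),
      N(id = 8, x = 150, y = 80, kind = "interior", bc_type = NA,
        bc_value = NA, bc_hematocrit = NA, bc_po2 = NA),
      N(id = 9, x = 0, y = 80, kind = "boundary", bc_type = "pressure",
        bc_value = 15, bc_hematocrit = NA, bc_po2 = NA))
    segs <- rbind(
      N(id = 1, from = 1, to = 2, diameter = 20, type = "arteriole",
        flowing = TRUE, fixed = FALSE),
      N(id = 2, from = 2, to = 3, diameter = 12, type = "arteriole",
        flowing = TRUE, fixed = FALSE),
      # long exchange path through distal tissue
      N(id = 3, from = 3, to = 4, diameter = 10, type = "capillary",
        flowing = TRUE, fixed = FALSE),
      N(id = 4, from = 4, to = 5, diameter = 10, type = "capillary",
        flowing = TRUE, fixed = FALSE),
      N(id = 5, from = 5, to = 6, diameter = 10, type = "capillary",
        flowing = TRUE, fixed = FALSE),
      N(id = 6, from = 6, to = 7, diameter = 10, type = "capillary",
        flowing = TRUE, fixed = FALSE),
      # short shunt
      N(id = 7, from = 3, to = 7, diameter = 10, type = "capillary",
        flowing = TRUE, fixed = FALSE),
      N(id = 8, from = 7, to = 8, diameter = 14, type = "venule",
        flowing = TRUE, fixed = FALSE),
      N(id = 9, from = 8, to = 9, diameter = 18, type = "venule",
        flowing = TRUE, fixed = FALSE))
    dom <- tissue_domain(rbind(c(0, 0), c(900, 0), c(900, 600), c(0, 600)),
                         demand = demand)
  } else {
    # grid_mesh: 5 x 5 capillary lattice, inlet/outlet at opposite corners
    sp <- 100
    nn <- expand.grid(ix = 0:4, iy = 0:4)
    nodes <- data.frame(id = seq_len(nrow(nn)) + 2,
                        x = nn$ix * sp + 50, y = nn$iy * sp + 50,
                        kind = "interior", bc_type = NA_character_,
                        bc_value = NA_real_, bc_hematocrit = NA_real_,
                        bc_po2 = NA_real_)
    idx <- function(ix, iy) 2 + ix + 1 + iy * 5
    segs <- NULL
    sid <- 0
    for (iy in 0:4) for (ix in 0:3) {
      sid <- sid + 1
      segs <- rbind(segs, N(id = sid, from = idx(ix, iy),
                            to = idx(ix + 1, iy), diameter = 8,
                            type = "capillary", flowing = TRUE,
                            fixed = FALSE))
    }
    for (iy in 0:3) for (ix in 0:4) {
      sid <- sid + 1
      segs <- rbind(segs, N(id = sid, from = idx(ix, iy),
                            to = idx(ix, iy + 1), diameter = 8,
                            type = "capillary", flowing = TRUE,
                            fixed = FALSE))
    }
    nodes <- rbind(
      N(id = 1, x = 0, y = 50, kind = "boundary", bc_type = "pressure",
        bc_value = 40, bc_hematocrit = 0.45, bc_po2 = 75),
      N(id = 2, x = 500, y = 450, kind = "boundary", bc_type = "pressure",
        bc_value = 15, bc_hematocrit = NA, bc_po2 = NA),
      nodes)
    segs <- rbind(segs,
                  N(id = sid + 1, from = 1, to = idx(0, 0), diameter = 12,
                    type = "arteriole", flowing = TRUE, fixed = FALSE),
                  N(id = sid + 2, from = idx(4, 4), to = 2, diameter = 12,
                    type = "venule", flowing = TRUE, fixed = FALSE))
    dom <- tissue_domain(rbind(c(0, 0), c(500, 0), c(500, 500), c(0, 500)),
                         demand = demand)
  }
  vascular_network(nodes, segs, domain = dom)
}
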