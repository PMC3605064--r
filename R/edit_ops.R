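# Structural edit operations: sprout-to-vessel connection and cascade
# pruning. Both preserve the 10 um minimum segment length and the rule that
# every flow-eligible segment lies on a path between two boundary nodes.

MIN_SEGMENT_LENGTH <- 10

#' Connect a sprout tip to a nearby segment
#'
#' When a growing tip comes within 5 um of another vessel, a connection is
#' formed at the nearest point of that vessel. The target segment is split at
#' the intercept; the intercept is moved along the target if needed so that
#' no resulting segment is shorter than 10 um (snapping to an existing
#' endpoint node when the target is too short to split). If the intercept
#' would land on a network boundary node the connection is suppressed and
#' the sprout removed. On success the whole sprout chain becomes a
#' flow-eligible capillary chain.
#'
#' The tip-to-intercept link is realized by extending the sprout's trailing
#' segment to the intercept node, so the connection never creates a
#' sub-minimum segment.
#'
#' @param net a \code{vascular_network}.
#' @param tip_node id of the sprout tip node.
#' @param target_segment id of the segment to connect to.
#' @return list \code{net} (updated network) and \code{outcome} one of
#'   "connected" or "suppressed".
#' @export
add_sprout_connection <- function(net, tip_node, target_segment) {
  si <- match(target_segment, net$segments$id)
  if (is.na(si)) stop("target segment ", target_segment, " not in network")
  ti <- match(tip_node, net$nodes$id)
  seg <- net$segments[si, ]
  fi <- match(seg$from, net$nodes$id)
  toi <- match(seg$to, net$nodes$id)
  p <- point_segment_distance(net$nodes$x[ti], net$nodes$y[ti],
                              net$nodes$x[fi], net$nodes$y[fi],
                              net$nodes$x[toi], net$nodes$y[toi])
  L <- sqrt((net$nodes$x[toi] - net$nodes$x[fi])^2 +
            (net$nodes$y[toi] - net$nodes$y[fi])^2)
  s <- p$t * L   # arclength of intercept from the 'from' end
  snap <- NA_integer_
  if (L < 2 * MIN_SEGMENT_LENGTH) {
    # too short to split: attach to the nearer endpoint node
    snap <- if (s < L / 2) seg$from else seg$to
  } else if (s < MIN_SEGMENT_LENGTH) {
    if (s < MIN_SEGMENT_LENGTH / 2) snap <- seg$from
    else s <- MIN_SEGMENT_LENGTH
  } else if (L - s < MIN_SEGMENT_LENGTH) {
    if (L - s < MIN_SEGMENT_LENGTH / 2) snap <- seg$to
    else s <- L - MIN_SEGMENT_LENGTH
  }
  if (!is.na(snap)) {
    ki <- match(snap, net$nodes$id)
    if (net$nodes$kind[ki] == "boundary") {
      return(list(net = remove_sprout_chain(net, tip_node),
                  outcome = "suppressed"))
    }
    inode <- snap
  } else {
    frac <- s / L
    ix <- net$nodes$x[fi] + frac * (net$nodes$x[toi] - net$nodes$x[fi])
    iy <- net$nodes$y[fi] + frac * (net$nodes$y[toi] - net$nodes$y[fi])
    nn <- new_node(net, ix, iy)
    net <- nn$net
    inode <- nn$id
    # split target: replace with two halves sharing diameter/type/flags
    net$segments$to[match(target_segment, net$segments$id)] <- inode
    ns <- new_segment(net, inode, seg$to, seg$diameter, seg$type,
                      seg$flowing, seg$fixed)
    net <- ns$net
  }
  # extend the sprout's trailing segment to the intercept node
  trail <- which(net$segments$from == tip_node | net$segments$to == tip_node)
  if (length(trail) != 1) stop("tip node must have exactly one segment")
  k <- trail
  prev_node <- if (net$segments$from[k] == tip_node) net$segments$to[k]
               else net$segments$from[k]
  # degenerate anastomoses (connection onto the sprout's own previous node,
  # or duplicating an existing edge with coincident geometry) are suppressed
  dup <- which((net$segments$from == prev_node & net$segments$to == inode) |
                 (net$segments$to == prev_node & net$segments$from == inode))
  if (inode == prev_node || length(dup) > 0) {
    return(list(net = remove_sprout_chain(net, tip_node),
                outcome = "suppressed"))
  }
  if (net$segments$from[k] == tip_node) net$segments$from[k] <- inode
  else net$segments$to[k] <- inode
  net$nodes <- net$nodes[-match(tip_node, net$nodes$id), , drop = FALSE]
  # the merged non-flowing component becomes flow-eligible once it is
  # anchored to the flowing network at two or more distinct nodes (a
  # pressure difference can then drive flow through it); merging chains
  # with a single anchor stay non-flowing sprout material
  if (.component_anchor_count(net, inode) >= 2) {
    net <- promote_sprout_chain(net, inode)
  }
  net$sprouts <- net$sprouts[net$sprouts$tip_node != tip_node, , drop = FALSE]
  list(net = net, outcome = "connected")
}

# Count the distinct nodes of the sprout-segment component containing
# start_node that also touch at least one flow-eligible segment.
.component_anchor_count <- function(net, start_node) {
  comp_nodes <- start_node
  frontier <- start_node
  seen_seg <- integer(0)
  while (length(frontier) > 0) {
    nd <- frontier[1]; frontier <- frontier[-1]
    att <- which((net$segments$from == nd | net$segments$to == nd) &
                   net$segments$type == "sprout" &
                   !(net$segments$id %in% seen_seg))
    for (k in att) {
      seen_seg <- c(seen_seg, net$segments$id[k])
      nxt <- if (net$segments$from[k] == nd) net$segments$to[k]
             else net$segments$from[k]
      if (!(nxt %in% comp_nodes)) {
        comp_nodes <- c(comp_nodes, nxt)
        frontier <- c(frontier, nxt)
      }
    }
  }
  n_anchor <- 0
  for (nd in comp_nodes) {
    att <- which((net$segments$from == nd | net$segments$to == nd) &
                   net$segments$flowing)
    if (length(att) > 0) n_anchor <- n_anchor + 1
  }
  n_anchor
}

# Walk back from a node through sprout-type segments, converting the chain
# to flowing capillaries.
promote_sprout_chain <- function(net, start_node) {
  frontier <- start_node
  while (length(frontier) > 0) {
    nd <- frontier[1]; frontier <- frontier[-1]
    att <- which((net$segments$from == nd | net$segments$to == nd) &
                   net$segments$type == "sprout")
    for (k in att) {
      net$segments$type[k] <- "capillary"
      net$segments$flowing[k] <- TRUE
      nxt <- if (net$segments$from[k] == nd) net$segments$to[k]
             else net$segments$from[k]
      frontier <- c(frontier, nxt)
    }
  }
  net
}

# Remove the whole non-flowing chain ending at a tip node, and the sprout
# record; used when growth is suppressed.
remove_sprout_chain <- function(net, tip_node) {
  nd <- tip_node
  repeat {
    att <- which((net$segments$from == nd | net$segments$to == nd) &
                   net$segments$type == "sprout")
    if (length(att) != 1) break
    k <- att
    nxt <- if (net$segments$from[k] == nd) net$segments$to[k]
           else net$segments$from[k]
    net$segments <- net$segments[-k, , drop = FALSE]
    net$nodes <- net$nodes[net$nodes$id != nd, , drop = FALSE]
    deg_next <- sum(net$segments$from == nxt | net$segments$to == nxt) +
      sum(net$sprouts$tip_node == nxt & nxt != tip_node)
    if (deg_next >= 2 || net$nodes$kind[match(nxt, net$nodes$id)] == "boundary")
      break
    if (!any(net$segments$type[net$segments$from == nxt |
                               net$segments$to == nxt] == "sprout")) break
    nd <- nxt
  }
  net$sprouts <- net$sprouts[net$sprouts$tip_node != tip_node, , drop = FALSE]
  net <- drop_orphan_nodes(net)
  net
}

#' Prune segments and cascade removal of dead flow pathways
#'
#' Removes the given segments (typically those whose adapted diameter fell
#' below the 3 um red-cell passage minimum), then removes every
#' flow-eligible segment that no longer lies on any path between two
#' distinct boundary nodes (its flow necessarily ceases). Non-flowing sprout
#' chains attached to removed nodes are removed as well; orphan interior
#' nodes are dropped.
#'
#' @param net a \code{vascular_network}.
#' @param segment_ids ids of segments to remove (may be empty; cascade
#'   analysis still runs).
#' @return updated network.
#' @export
prune_segments <- function(net, segment_ids = integer(0)) {
  if (length(segment_ids) > 0) {
    net$segments <- net$segments[!(net$segments$id %in% segment_ids), ,
                                 drop = FALSE]
  }
  keep_flow <- flow_capable_segments(net)
  dead <- net$segments$flowing & !keep_flow
  if (any(dead)) {
    net$segments <- net$segments[!dead, , drop = FALSE]
  }
  # drop sprouts whose chain lost its anchor to the surviving network
  if (nrow(net$sprouts) > 0) {
    live <- net$nodes$id
    repeat {
      tips <- net$sprouts$tip_node
      bad <- rep(FALSE, length(tips))
      for (i in seq_along(tips)) {
        bad[i] <- !sprout_chain_anchored(net, tips[i])
      }
      if (!any(bad)) break
      for (tp in tips[bad]) net <- remove_sprout_chain(net, tp)
    }
  }
  net <- drop_orphan_nodes(net)
  net
}

# A sprout chain is anchored if walking from the tip along sprout segments
# reaches a node that has at least one non-sprout segment.
sprout_chain_anchored <- function(net, tip_node) {
  nd <- tip_node
  seen <- numeric(0)
  repeat {
    if (nd %in% seen) return(FALSE)
    seen <- c(seen, nd)
    att <- which(net$segments$from == nd | net$segments$to == nd)
    if (length(att) == 0) return(FALSE)
    if (any(net$segments$type[att] != "sprout")) return(TRUE)
    spr <- att[net$segments$type[att] == "sprout"]
    nxt <- setdiff(unique(c(net$segments$from[spr], net$segments$to[spr])),
                   seen)
    if (length(nxt) == 0) return(FALSE)
    nd <- nxt[1]
  }
}

#' Which flow-eligible segments can carry flow
#'
#' A segment can carry flow only if it lies on some simple path between two
#' distinct boundary nodes. Computed from the block-cut tree of the
#' flow-eligible subgraph: an edge's biconnected block must lie on the
#' minimal subtree spanning the boundary nodes.
#'
#' @param net a \code{vascular_network}.
#' @return logical vector aligned with \code{net$segments} (FALSE for
#'   non-flowing sprout segments).
#' @export
flow_capable_segments <- function(net) {
  segs <- net$segments
  out <- rep(FALSE, nrow(segs))
  fl <- which(segs$flowing)
  if (length(fl) == 0) return(out)
  ids <- as.character(net$nodes$id)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(segs$from[fl]),
               to = as.character(segs$to[fl])),
    directed = FALSE,
    vertices = data.frame(name = ids))
  bnd <- as.character(net$nodes$id[net$nodes$kind == "boundary"])
  bnd <- bnd[igraph::degree(g, bnd) > 0]
  if (length(bnd) < 2) return(out)
  bc <- igraph::biconnected_components(g)
  nb <- length(bc$components)
  if (nb == 0) return(out)
  # map each flow edge to its block
  edge_block <- integer(igraph::ecount(g))
  for (b in seq_len(nb)) edge_block[bc$component_edges[[b]]] <- b
  # build block-cut tree: vertices = blocks (1..nb) and cut vertices
  cuts <- bc$articulation_points
  cut_names <- igraph::V(g)$name[cuts]
  tree_edges <- NULL
  for (b in seq_len(nb)) {
    members <- igraph::V(g)$name[bc$components[[b]]]
    in_cut <- members[members %in% cut_names]
    if (length(in_cut) > 0) {
      tree_edges <- rbind(tree_edges,
                          data.frame(from = paste0("B", b),
                                     to = paste0("C", in_cut)))
    }
  }
  tvnames <- unique(c(paste0("B", seq_len(nb)),
                      if (length(cut_names)) paste0("C", cut_names)))
  if (is.null(tree_edges)) {
    tree <- igraph::make_empty_graph(directed = FALSE) +
      igraph::vertices(tvnames)
  } else {
    tree <- igraph::graph_from_data_frame(tree_edges, directed = FALSE,
                                          vertices = data.frame(name = tvnames))
  }
  # locate each boundary node in the tree (boundary nodes have degree 1 so
  # are never cut vertices; they belong to exactly one block)
  mark <- character(length(bnd))
  vmem_block <- lapply(seq_len(nb), function(b) igraph::V(g)$name[bc$components[[b]]])
  for (i in seq_along(bnd)) {
    for (b in seq_len(nb)) {
      if (bnd[i] %in% vmem_block[[b]]) { mark[i] <- paste0("B", b); break }
    }
  }
  mark <- mark[nzchar(mark)]
  if (length(unique(mark)) == 0) return(out)
  # minimal subtree spanning marked tree vertices: iteratively strip
  # unmarked leaves, within each connected tree component keeping only
  # components holding >= 2 distinct boundary nodes
  comp <- igraph::components(tree)$membership
  mark_comp <- comp[mark]
  n_bnd_comp <- table(mark_comp)  # counts boundary nodes per tree component
  good_comp <- as.numeric(names(n_bnd_comp)[n_bnd_comp >= 2])
  keepv <- names(comp)[comp %in% good_comp]
  sub <- igraph::induced_subgraph(tree, keepv)
  marks_in <- mark[mark %in% igraph::V(sub)$name]
  repeat {
    degs <- igraph::degree(sub)
    leaves <- names(degs)[degs <= 1]
    # a leaf block stays if it contains a boundary node
    strip <- setdiff(leaves, unique(marks_in))
    if (length(strip) == 0) break
    sub <- igraph::delete_vertices(sub, strip)
    if (igraph::vcount(sub) == 0) break
  }
  live_blocks <- as.integer(sub_names <- sub("^B", "",
    grep("^B", igraph::V(sub)$name, value = TRUE)))
  usable <- edge_block %in% live_blocks
  out[fl] <- usable
  out
}
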