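# Daily time-step orchestration. Within a day: (1) flow and hematocrit,
# (2) oxygen field, (3) VEGF field, (4) stochastic sprout formation,
# (5) sprout elongation and connection, (6) diameter adaptation and
# pruning of flowing segments, (7) tension-induced node migration.
# Fields therefore reflect the current structure before stochastic
# growth, and adaptation uses the current day's hemodynamics.

#' Advance the simulation by one day
#'
#' @param state list with elements \code{net} (a \code{vascular_network}),
#'   \code{oxygen} (previous \code{oxygen_state} or NULL) and \code{day}.
#' @param config a \code{simulation_config}.
#' @param streams an \code{rng_streams}.
#' @return updated state with a \code{record} entry (one-row data.frame of
#'   step metrics).
#' @export
simulation_step <- function(state, config, streams) {
  net <- state$net
  day <- state$day
  oxy_par <- config$oxygen
  oxy_par$M0 <- demand_at(config$demand_schedule, day, config$oxygen$M0)
  net$domain$demand <- oxy_par$M0

  flow <- solve_flow(net, tol = config$flow_tol,
                     max_iter = config$flow_max_iter)
  oxy <- solve_oxygen(net, flow, net$domain, oxy_par,
                      warm_start = state$oxygen)
  veg <- solve_vegf(oxy, net$domain, config$vegf)

  n_sprouted <- n_connected <- n_suppressed <- 0L
  if (config$sprouting_on) {
    # stochastic sprout formation: one uniformly sampled point on every
    # segment (flowing vessels and non-flowing sprout material alike)
    segs <- net$segments
    lens <- segment_lengths(net)
    co <- segment_coords(net)
    draws <- with_stream(streams, "sprout",
                         stats::runif(2 * nrow(segs)))
    for (k in seq_len(nrow(segs))) {
      tf <- draws[2 * k - 1]
      px <- co[k, 1] + tf * (co[k, 3] - co[k, 1])
      py <- co[k, 2] + tf * (co[k, 4] - co[k, 2])
      cg <- local_concentration(veg, px, py)
      pr <- sprout_formation_probability(cg, lens[k], config$angio)
      if (draws[2 * k] < pr) {
        res <- with_stream(streams, "sprout",
                           spawn_sprout(net, segs$id[k], tf, config$angio))
        net <- res$net
        if (res$outcome == "sprouted") n_sprouted <- n_sprouted + 1L
        else n_suppressed <- n_suppressed + 1L
      }
    }
    # sprout elongation (iterate over a frozen id list; connections and
    # suppressions mutate the sprout table)
    ids <- net$sprouts$id
    for (sp_id in ids) {
      if (!(sp_id %in% net$sprouts$id)) next
      res <- with_stream(streams, "direction",
                         advance_sprout(net, sp_id, veg, config$angio))
      net <- res$net
      if (res$outcome == "connected") n_connected <- n_connected + 1L
      if (res$outcome == "suppressed") n_suppressed <- n_suppressed + 1L
    }
  }

  n_pruned <- 0L
  if (config$adaptation_on) {
    # adapt using the (pre-growth) converged flow and oxygen state
    po2 <- oxy$vessel_po2
    noise <- with_stream(streams, "ks",
                         stats::rnorm(length(flow$segment_id), 0,
                                      config$adapt$ran_ks))
    stim <- adaptation_stimuli(flow, po2, config$adapt, noise = noise)
    upd <- update_diameters(net, stim, dt = config$angio$dt, config$adapt)
    net <- upd$net
    if (length(upd$prune_ids) > 0 || TRUE) {
      n_before <- nrow(net$segments)
      net <- prune_segments(net, upd$prune_ids)
      n_pruned <- n_before - nrow(net$segments)
    }
  }

  if (config$migration_on) {
    net <- migrate_nodes(net, config$migration, dt = config$angio$dt)
  }

  rec <- data.frame(
    day = day + 1,
    total_length_mm = total_vessel_length(net) / 1000,
    flowing_length_mm = total_vessel_length(net, flowing_only = TRUE) / 1000,
    sprout_length_mm = (total_vessel_length(net) -
      total_vessel_length(net, flowing_only = TRUE)) / 1000,
    inflow_nlmin = total_inflow(net, flow),
    mean_po2 = mean(oxy$tissue_po2),
    hypoxic_fraction_pct = 100 * oxy$hypoxic_fraction,
    mean_vessel_distance = mean(distance_to_nearest_vessel(net)),
    n_segments = nrow(net$segments),
    n_sprouts_active = nrow(net$sprouts),
    sprouts_formed = n_sprouted,
    sprouts_connected = n_connected,
    sprouts_suppressed = n_suppressed,
    segments_pruned = n_pruned,
    demand = oxy_par$M0)

  list(net = net, oxygen = oxy, vegf = veg, flow = flow, day = day + 1,
       record = rec)
}

#' Total network inflow (nl/min)
#'
#' Sum over arterial boundary nodes of the flow entering the network
#' (positive net outflow from the node into its segment). Venular boundary
#' inflows are excluded by default so the value measures the perfusion of
#' the exchange network, matching the network-level "flow rate" summary.
#'
#' @param net a \code{vascular_network}.
#' @param flow a \code{hemodynamic_state}.
#' @param include_venules also count inflow through venule-type boundary
#'   segments.
#' @export
total_inflow <- function(net, flow, include_venules = FALSE) {
  nid <- flow$node_id
  bnd <- which(net$nodes$kind[match(nid, net$nodes$id)] == "boundary")
  total <- 0
  for (b in bnd) {
    ks <- which(flow$from == nid[b] | flow$to == nid[b])
    if (length(ks) == 0) next
    if (!include_venules) {
      si <- match(flow$segment_id[ks[1]], net$segments$id)
      if (!is.na(si) && net$segments$type[si] == "venule") next
    }
    out_ <- sum(flow$flow[flow$from == nid[b]]) -
      sum(flow$flow[flow$to == nid[b]])
    if (out_ > 0) total <- total + out_
  }
  total
}

#' Run a simulation
#'
#' Runs the daily step to the configured horizon, accumulating step
#' records. The trajectory is a pure function of (config, seed).
#'
#' @param net starting \code{vascular_network} (e.g. from
#'   [generate_skeleton()]); its domain supplies the tissue grid.
#' @param config a \code{simulation_config}.
#' @param progress print a line every \code{progress} days (0 = silent).
#' @return list of class \code{simulation_result}: \code{net} (final
#'   network), \code{records} (data.frame, one row per day), \code{oxygen},
#'   \code{vegf}, \code{flow} (final states), \code{config}.
#' @export
simulate_angiogenesis <- function(net, config = simulation_config(),
                                  progress = 0) {
  streams <- rng_streams(config$seed)
  state <- list(net = net, oxygen = NULL, day = 0)
  records <- NULL
  if (config$days == 0) {
    flow <- solve_flow(net, tol = config$flow_tol,
                       max_iter = config$flow_max_iter)
    oxy <- solve_oxygen(net, flow, net$domain, config$oxygen)
    return(structure(list(net = net, records = NULL, oxygen = oxy,
                          flow = flow, vegf = NULL, config = config),
                     class = "simulation_result"))
  }
  for (d in seq_len(config$days)) {
    state <- simulation_step(state, config, streams)
    records <- rbind(records, state$record)
    if (progress > 0 && d %% progress == 0) {
      message(sprintf("day %d: L=%.2f mm, hypox=%.2f%%, sprouts=%d",
                      d, state$record$total_length_mm,
                      state$record$hypoxic_fraction_pct,
                      state$record$n_sprouts_active))
    }
  }
  structure(list(net = state$net, records = records, oxygen = state$oxygen,
                 vegf = state$vegf, flow = state$flow, config = config),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf(paste0("simulation_result: %d days; final total length ",
                     "%.2f mm, hypoxic fraction %.2f%%\n"),
              if (is.null(n)) 0 else n,
              if (is.null(n)) total_vessel_length(x$net) / 1000
              else x$records$total_length_mm[n],
              if (is.null(n)) 100 * x$oxygen$hypoxic_fraction
              else x$records$hypoxic_fraction_pct[n]))
  invisible(x)
}
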