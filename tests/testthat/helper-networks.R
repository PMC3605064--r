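# Small hand-built networks used across test files.

# straight horizontal vessel with a sprout tip node nearby, for
# connection-operation tests
make_connection_fixture <- function(tip_x, tip_y, trail_len = 30) {
  # sprout chain 4 -> 3 (tip) rooted on the flowing feeder 5 -> 4 -> ...
  nodes <- data.frame(
    id = 1:5,
    x = c(0, 100, tip_x, tip_x - trail_len, tip_x - trail_len),
    y = c(0, 0, tip_y, tip_y, tip_y + 100),
    kind = c("boundary", "boundary", "interior", "interior", "boundary"),
    bc_type = c("pressure", "pressure", NA, NA, "pressure"),
    bc_value = c(40, 20, NA, NA, 38),
    bc_hematocrit = c(0.4, NA, NA, NA, 0.4),
    bc_po2 = c(75, NA, NA, NA, 60))
  segments <- data.frame(
    id = 1:3,
    from = c(1, 4, 5), to = c(2, 3, 4),
    diameter = c(12, 10, 11),
    type = c("capillary", "sprout", "capillary"),
    flowing = c(TRUE, FALSE, TRUE),
    fixed = FALSE)
  net <- vascular_network(nodes, segments)
  net$sprouts <- data.frame(id = 1, tip_node = 3, dir_x = 0, dir_y = -1,
                            attach_node = 4, age = 1)
  net
}

# two boundary nodes joined through a chain of interior nodes
make_chain_network <- function(xs, ys, D = 10, p_in = 40, p_out = 20) {
  n <- length(xs)
  nodes <- data.frame(
    id = seq_len(n), x = xs, y = ys,
    kind = c("boundary", rep("interior", n - 2), "boundary"),
    bc_type = c("pressure", rep(NA, n - 2), "pressure"),
    bc_value = c(p_in, rep(NA, n - 2), p_out),
    bc_hematocrit = c(0.45, rep(NA, n - 1)),
    bc_po2 = c(75, rep(NA, n - 1)))
  segments <- data.frame(
    id = seq_len(n - 1), from = seq_len(n - 1), to = 2:n,
    diameter = D, type = "capillary", flowing = TRUE, fixed = FALSE)
  vascular_network(nodes, segments)
}

# cache for expensive simulation runs shared between test files
shared_runs <- new.env(parent = emptyenv())

cached_run <- function(name, fn) {
  if (is.null(shared_runs[[name]])) shared_runs[[name]] <- fn()
  shared_runs[[name]]
}

# standard reduced-scale simulation used by mechanism-contrast tests
contrast_sim <- function(seed, days, area = 0.53, demand = 2, ...) {
  net <- generate_skeleton(skeleton_spec(area = area, demand = demand),
                           seed = seed)
  cfg <- simulation_config(days = days, seed = seed,
                           oxygen = oxygen_params(M0 = demand), ...)
  suppressWarnings(simulate_angiogenesis(net, cfg))
}

# shunt-pair adaptation experiment: evolve flow/oxygen/adaptation (no
# sprouting) and report the fate of the long path versus the shunt
run_shunt_experiment <- function(k_c, days = 60) {
  net <- toy_network("shunt_pair")
  par_a <- adaptation_params(k_c = k_c, ran_ks = 0)
  oxy <- NULL
  for (d in seq_len(days)) {
    f <- solve_flow(net)
    oxy <- suppressWarnings(
      solve_oxygen(net, f, net$domain, warm_start = oxy))
    stim <- adaptation_stimuli(f, oxy$vessel_po2, par_a, noise = 0)
    upd <- update_diameters(net, stim, 1, par_a)
    net <- prune_segments(upd$net, upd$prune_ids)
    if (!any(net$segments$id %in% 3:6) || !any(net$segments$id == 7))
      break
  }
  long_alive <- all(3:6 %in% net$segments$id)
  shunt_alive <- 7 %in% net$segments$id
  list(
    long = long_alive, shunt = shunt_alive,
    d_long = if (long_alive)
      mean(net$segments$diameter[net$segments$id %in% 3:6]) else 0,
    d_shunt = if (shunt_alive)
      net$segments$diameter[net$segments$id == 7] else 0)
}
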