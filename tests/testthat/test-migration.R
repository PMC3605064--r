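test_that("tension force vanishes for balanced nodes", {
  # straight-through node: two collinear equal-diameter segments
  net <- make_chain_network(c(0, 100, 200), c(0, 0, 0))
  f <- node_tension_force(net, 2)
  expect_equal(f$fmag, 0, tolerance = 1e-12)
  # symmetric 120-degree Y with equal diameters
  th <- c(0, 2 * pi / 3, 4 * pi / 3)
  nodes <- data.frame(id = 1:4, x = c(0, 100 * cos(th)),
                      y = c(0, 100 * sin(th)),
                      kind = c("interior", rep("boundary", 3)),
                      bc_type = NA, bc_value = NA, bc_hematocrit = NA,
                      bc_po2 = NA)
  segs <- data.frame(id = 1:3, from = 1, to = 2:4, diameter = 10,
                     type = "capillary", flowing = TRUE, fixed = FALSE)
  netY <- vascular_network(nodes, segs)
  expect_equal(node_tension_force(netY, 1)$fmag, 0, tolerance = 1e-12)
})

test_that("a right-angle corner pulls along the bisector at sqrt(2)/2", {
  net <- make_chain_network(c(0, 100, 100), c(0, 0, 100))
  f <- node_tension_force(net, 2)
  expect_equal(f$fmag, sqrt(2) / 2, tolerance = 1e-12)
  # bisector direction: (-1, 1)/sqrt(2) from the corner
  expect_equal(f$fx / f$fmag, -sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(f$fy / f$fmag, sqrt(2) / 2, tolerance = 1e-12)
})

test_that("nodes below the threshold do not move; speed caps at v_max", {
  p <- migration_params()
  # |f| exactly at the threshold: no displacement
  speed <- function(fmag) {
    if (fmag <= p$lambda_t) 0
    else p$v_max * (fmag - p$lambda_t) / (1 - p$lambda_t)
  }
  expect_equal(speed(p$lambda_t), 0)
  expect_equal(speed(1), p$v_max)
  # nearly-straight chain node stays put
  net <- make_chain_network(c(0, 100, 200), c(0, 2, 0))
  f <- node_tension_force(net, 2)
  expect_lt(f$fmag, p$lambda_t)
  out <- migrate_nodes(net, p, dt = 1)
  expect_equal(out$nodes$x, net$nodes$x)
  expect_equal(out$nodes$y, net$nodes$y)
})

test_that("a fresh 90/90/180 bifurcation relaxes toward 120 degrees", {
  nodes <- data.frame(id = 1:4, x = c(0, 100, 200, 100),
                      y = c(0, 0, 0, 100),
                      kind = c("boundary", "interior", "boundary",
                               "boundary"),
                      bc_type = NA, bc_value = NA, bc_hematocrit = NA,
                      bc_po2 = NA)
  segs <- data.frame(id = 1:3, from = c(1, 2, 2), to = c(2, 3, 4),
                     diameter = 10, type = "capillary", flowing = TRUE,
                     fixed = FALSE)
  net <- vascular_network(nodes, segs)
  p <- migration_params()
  ang0 <- sort(unlist(branching_angles(net)[1, 2:4]))
  for (d in 1:60) net <- migrate_nodes(net, p, dt = 1)
  ang <- sort(unlist(branching_angles(net)[1, 2:4]))
  # the 180-degree angle decreases, the 90-degree angles open up
  expect_lt(max(ang), max(ang0))
  expect_gt(min(ang), min(ang0))
})

test_that("migration alone never lengthens the network and stalls", {
  # zig-zag chain under tension shortens until forces drop below lambda_t
  net <- make_chain_network(c(0, 80, 160, 240, 320),
                            c(0, 60, 0, 60, 0))
  p <- migration_params()
  len <- total_vessel_length(net)
  for (d in 1:400) {
    net <- migrate_nodes(net, p, dt = 1)
    len_new <- total_vessel_length(net)
    expect_lte(len_new, len + 1e-9)
    len <- len_new
  }
  f <- node_tension_force(net, net$nodes$id[net$nodes$kind == "interior"])
  # close to stalling: every interior node near or below the threshold
  expect_true(all(f$fmag <= p$lambda_t + 0.05))
})

test_that("boundary nodes and sprout tips are immobile", {
  net <- make_chain_network(c(0, 100, 100), c(0, 0, 100))
  net$sprouts <- data.frame(id = 1, tip_node = 3, dir_x = 0, dir_y = 1,
                            attach_node = 2, age = 0)
  p <- migration_params()
  out <- migrate_nodes(net, p, dt = 1)
  moved <- which(out$nodes$x != net$nodes$x | out$nodes$y != net$nodes$y)
  expect_equal(out$nodes$id[moved], 2)
})
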