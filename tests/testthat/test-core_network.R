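test_that("sprout connection splits the target at the intercept", {
  # tip 4 um below the midpoint of a 100 um segment
  net <- make_connection_fixture(tip_x = 50, tip_y = 4)
  res <- add_sprout_connection(net, tip_node = 3, target_segment = 1)
  expect_equal(res$outcome, "connected")
  out <- res$net
  lens <- segment_lengths(out)
  halves <- lens[out$segments$type == "capillary" &
                   out$segments$diameter == 12]
  expect_equal(sort(halves), c(50, 50))
  # one connecting segment reaching the new node on the target
  expect_true(all(lens >= 10 - 1e-9))
  # chain became flow-eligible
  expect_true(all(out$segments$flowing))
  expect_equal(nrow(out$sprouts), 0)
})

test_that("intercepts near a target endpoint are moved to keep 10 um", {
  net <- make_connection_fixture(tip_x = 6, tip_y = 4)
  res <- add_sprout_connection(net, 3, 1)
  expect_equal(res$outcome, "connected")
  lens <- segment_lengths(res$net)
  expect_true(all(lens >= 10 - 1e-9))
  # the split point sits exactly at the minimum distance from the end
  halves <- sort(lens[res$net$segments$diameter == 12])
  expect_equal(halves[1], 10)
})

test_that("connection onto a boundary node suppresses the sprout", {
  # tip nearest point within snapping range of boundary node 1 (at x=0)
  net <- make_connection_fixture(tip_x = 2, tip_y = 4)
  n_before <- nrow(net$segments)
  res <- add_sprout_connection(net, 3, 1)
  expect_equal(res$outcome, "suppressed")
  # sprout chain removed, target untouched
  expect_equal(nrow(res$net$sprouts), 0)
  expect_equal(sum(res$net$segments$type == "sprout"), 0)
  expect_equal(sum(res$net$segments$diameter == 12), 1)
})

test_that("pruning cascades to segments whose flow must cease", {
  # main path with a dead-end side branch hanging off an interior node
  nodes <- data.frame(
    id = 1:5,
    x = c(0, 100, 200, 100, 300), y = c(0, 0, 0, 80, 0),
    kind = c("boundary", "interior", "interior", "interior", "boundary"),
    bc_type = c("pressure", NA, NA, NA, "pressure"),
    bc_value = c(40, NA, NA, NA, 20),
    bc_hematocrit = c(0.4, NA, NA, NA, NA),
    bc_po2 = c(75, NA, NA, NA, NA))
  segs <- data.frame(id = 1:4, from = c(1, 2, 2, 3), to = c(2, 3, 4, 5),
                     diameter = 10, type = "capillary", flowing = TRUE,
                     fixed = FALSE)
  net <- vascular_network(nodes, segs)
  # segment 3 (2->4) is already a dead end: removed by the cascade
  out <- prune_segments(net, integer(0))
  expect_false(4 %in% c(out$segments$from, out$segments$to))
  # pruning one branch of a parallel loop keeps the other flowing
  loop <- toy_network("parallel_loop")
  out2 <- prune_segments(loop, 2)   # kills upper path via node 3
  expect_false(3 %in% out2$segments$id)
  expect_true(all(c(1, 4, 5, 6) %in% out2$segments$id))
  capable <- flow_capable_segments(out2)
  expect_true(all(capable[out2$segments$flowing]))
})

test_that("segments at exactly the pruning diameter are retained", {
  net <- toy_network("single_segment")
  net$segments$diameter <- 3.0
  stim <- data.frame(segment_id = 1, S_tot = 0)
  upd <- update_diameters(net, stim, dt = 1, adaptation_params())
  expect_length(upd$prune_ids, 0)
  expect_equal(upd$net$segments$diameter, 3.0)
})

test_that("branching angles cover perpendicular and symmetric cases", {
  # fresh perpendicular sprout on a straight vessel
  nodes <- data.frame(id = 1:4, x = c(0, 100, 200, 100),
                      y = c(0, 0, 0, 100),
                      kind = c("boundary", "interior", "boundary",
                               "boundary"),
                      bc_type = NA, bc_value = NA, bc_hematocrit = NA,
                      bc_po2 = NA)
  segs <- data.frame(id = 1:3, from = c(1, 2, 2), to = c(2, 3, 4),
                     diameter = 10, type = "capillary", flowing = TRUE,
                     fixed = FALSE)
  ang <- branching_angles(vascular_network(nodes, segs))
  expect_equal(sort(round(unname(unlist(ang[1, 2:4])))), c(90, 90, 180))
  # symmetric Y: 120/120/120
  th <- c(0, 2 * pi / 3, 4 * pi / 3)
  nodes2 <- data.frame(id = 1:4,
                       x = c(0, 100 * cos(th)), y = c(0, 100 * sin(th)),
                       kind = c("interior", rep("boundary", 3)),
                       bc_type = NA, bc_value = NA, bc_hematocrit = NA,
                       bc_po2 = NA)
  segs2 <- data.frame(id = 1:3, from = 1, to = 2:4, diameter = 10,
                      type = "capillary", flowing = TRUE, fixed = FALSE)
  ang2 <- branching_angles(vascular_network(nodes2, segs2))
  expect_equal(unlist(ang2[1, 2:4]), rep(120, 3), ignore_attr = TRUE)
  # angles at any 3-way node sum to 360
  expect_equal(sum(ang[1, 2:4]), 360)
})

test_that("nearest-vessel distances match the brute-force oracle", {
  set.seed(11)
  net <- toy_network("grid_mesh")
  px <- runif(40, 0, 500); py <- runif(40, 0, 500)
  d <- distance_to_nearest_vessel(net, data.frame(x = px, y = py))
  co <- angioadapt:::segment_coords(net)
  brute <- vapply(seq_along(px), function(i) {
    min(vapply(seq_len(nrow(co)), function(k) {
      angioadapt:::point_segment_distance(px[i], py[i], co[k, 1],
                                          co[k, 2], co[k, 3],
                                          co[k, 4])$dist
    }, numeric(1)))
  }, numeric(1))
  expect_equal(d, brute, tolerance = 1e-12)
  # perpendicular-foot case
  net2 <- make_chain_network(c(0, 100), c(0, 0))
  expect_equal(distance_to_nearest_vessel(
    net2, data.frame(x = 50, y = 25)), 25)
  expect_equal(distance_to_nearest_vessel(
    net2, data.frame(x = 30, y = 0)), 0)
})

test_that("edits preserve structural invariants", {
  net <- make_connection_fixture(tip_x = 37, tip_y = 4.5)
  len_before <- total_vessel_length(net)
  res <- add_sprout_connection(net, 3, 1)
  expect_true(validate_network(res$net))
  expect_true(all(flow_capable_segments(res$net)[res$net$segments$flowing]))
  # pruning never increases total vessel length
  loop <- toy_network("parallel_loop")
  expect_lte(total_vessel_length(prune_segments(loop, 2)),
             total_vessel_length(loop))
})
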