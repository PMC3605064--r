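test_that("sprouting rate has a threshold and saturates", {
  p <- angiogenesis_params()
  expect_equal(sprout_formation_probability(p$C_th, 100, p), 0)
  expect_equal(sprout_formation_probability(0.2, 100, p), 0)
  # half-saturation one increment above threshold
  expect_equal(sprout_formation_probability(p$C_th + p$C_th50, 100, p),
               p$k_sprout / 2 * 100 * p$dt)
  # saturation: long segment at huge concentration caps at 1
  expect_equal(sprout_formation_probability(1e6, 1000, p), 1)
  # monotone in concentration
  pr <- sprout_formation_probability(seq(0.8, 10, by = 0.1), 50, p)
  expect_true(all(diff(pr) >= 0))
})

test_that("sprout spawning respects node snapping and suppression", {
  p <- angiogenesis_params()
  # sample 3 um from the parent's interior endpoint: attach at that node
  net <- make_chain_network(c(0, 100, 200), c(0, 0, 0))
  set.seed(1)
  res <- spawn_sprout(net, 1, t_frac = 0.97, p)
  expect_equal(res$outcome, "sprouted")
  sp <- res$net$sprouts
  expect_equal(sp$attach_node, 2)
  # attachment moved to an existing node: no parent split happened
  expect_equal(sum(res$net$segments$diameter == 10 &
                     res$net$segments$type != "sprout"), 2)
  # spawning onto an existing 3-way branch point is suppressed
  nodes <- data.frame(id = 1:4, x = c(0, 100, 200, 100),
                      y = c(0, 0, 0, 100),
                      kind = c("boundary", "interior", "boundary",
                               "boundary"),
                      bc_type = c("pressure", NA, "pressure", "pressure"),
                      bc_value = c(40, NA, 20, 20),
                      bc_hematocrit = c(0.4, NA, NA, NA),
                      bc_po2 = c(75, NA, NA, NA))
  segs <- data.frame(id = 1:3, from = c(1, 2, 2), to = c(2, 3, 4),
                     diameter = 10, type = "capillary", flowing = TRUE,
                     fixed = FALSE)
  net3 <- vascular_network(nodes, segs)
  res3 <- spawn_sprout(net3, 1, t_frac = 0.97, p)
  expect_equal(res3$outcome, "suppressed")
  # boundary-node attachment suppressed as well
  res4 <- spawn_sprout(net3, 1, t_frac = 0.02, p)
  expect_equal(res4$outcome, "suppressed")
})

test_that("initial sprout direction is perpendicular with a fair sign", {
  p <- angiogenesis_params()
  set.seed(42)
  signs <- integer(0)
  for (i in 1:200) {
    net <- make_chain_network(c(0, 100, 200), c(0, 0, 0))
    res <- spawn_sprout(net, 1, t_frac = 0.5, p)
    sp <- res$net$sprouts
    # perpendicular to the x-axis parent
    expect_equal(abs(sp$dir_y), 1)
    expect_equal(sp$dir_x, 0)
    signs <- c(signs, sign(sp$dir_y))
  }
  frac <- mean(signs > 0)
  expect_gt(frac, 0.5 - 3 * sqrt(0.25 / 200))
  expect_lt(frac, 0.5 + 3 * sqrt(0.25 / 200))
})

test_that("homing vanishes outside the sector and respects symmetry", {
  p <- angiogenesis_params()
  net <- make_chain_network(c(0, 100, 200), c(500, 500, 500))
  # tip far from everything
  V0 <- homing_vector(net, 5000, 5000, 1, 0, integer(0), p)
  expect_equal(V0, c(0, 0))
  # a short target at r >= R_max straight ahead contributes nothing
  nodesR <- data.frame(id = 1:2, x = c(100, 100), y = c(95, 105),
                       kind = "boundary", bc_type = "pressure",
                       bc_value = c(40, 20), bc_hematocrit = NA,
                       bc_po2 = NA)
  segsR <- data.frame(id = 1, from = 1, to = 2, diameter = 10,
                      type = "capillary", flowing = TRUE, fixed = FALSE)
  netR <- vascular_network(nodesR, segsR)
  VR <- homing_vector(netR, 0, 100, 1, 0, integer(0), p)
  expect_equal(sqrt(sum(VR^2)), 0, tolerance = 1e-6)
  # two identical targets symmetric about the growth axis
  nodes <- data.frame(id = 1:4, x = c(50, 60, 50, 60),
                      y = c(40, 40, -40, -40),
                      kind = "boundary",
                      bc_type = "pressure", bc_value = c(40, 20, 40, 20),
                      bc_hematocrit = NA, bc_po2 = NA)
  segs <- data.frame(id = 1:2, from = c(1, 3), to = c(2, 4),
                     diameter = 10, type = "capillary", flowing = TRUE,
                     fixed = FALSE)
  netS <- vascular_network(nodes, segs)
  VS <- homing_vector(netS, 0, 0, 1, 0, integer(0), p)
  expect_equal(VS[2], 0, tolerance = 1e-9)
  expect_gt(VS[1], 0)
})

test_that("straight growth without noise advances 50 um per day", {
  p <- angiogenesis_params(sigma_s = 0, k_V = 0)
  net <- make_chain_network(c(0, 300, 600), c(0, 0, 0))
  net$domain <- tissue_domain(rbind(c(-100, -700), c(700, -700),
                                    c(700, 100), c(-100, 100)))
  res <- spawn_sprout(net, 1, t_frac = 0.5, p)
  net <- res$net
  tip0 <- net$nodes[match(net$sprouts$tip_node, net$nodes$id), ]
  res2 <- advance_sprout(net, net$sprouts$id[1], NULL, p)
  expect_equal(res2$outcome, "growing")
  net2 <- res2$net
  tip1 <- net2$nodes[match(net2$sprouts$tip_node, net2$nodes$id), ]
  d <- sqrt((tip1$x - tip0$x)^2 + (tip1$y - tip0$y)^2)
  expect_equal(d, p$V_g * p$dt)
})

test_that("strong homing rotates growth toward an off-axis target", {
  p <- angiogenesis_params(sigma_s = 0, k_V = 10)
  # target segment 30 degrees off-axis, 60 um away from the tip
  ang <- 30 * pi / 180
  cx <- 60 * cos(ang); cy <- 60 * sin(ang)
  nodes <- data.frame(id = 1:2, x = c(cx, cx + 20 * sin(ang)),
                      y = c(cy, cy - 20 * cos(ang)),
                      kind = "boundary", bc_type = "pressure",
                      bc_value = c(40, 20), bc_hematocrit = NA,
                      bc_po2 = NA)
  segs <- data.frame(id = 1, from = 1, to = 2, diameter = 10,
                     type = "capillary", flowing = TRUE, fixed = FALSE)
  netT <- vascular_network(nodes, segs)
  V <- homing_vector(netT, 0, 0, 1, 0, integer(0), p)
  d_new <- c(1, 0) + p$k_V * V
  d_new <- d_new / sqrt(sum(d_new^2))
  ang_before <- ang
  ang_after <- abs(atan2(d_new[2], d_new[1]) - ang)
  expect_lt(ang_after, ang_before)
})

test_that("tips crossing the tissue boundary suppress the sprout", {
  p <- angiogenesis_params(sigma_s = 0, k_V = 0)
  net <- make_chain_network(c(0, 300, 600), c(30, 30, 30))
  net$domain <- tissue_domain(rbind(c(-100, 0), c(700, 0),
                                    c(700, 80), c(-100, 80)))
  set.seed(7)
  res <- spawn_sprout(net, 1, t_frac = 0.5, p)
  net <- res$net
  # whichever perpendicular sign was drawn, the tip exits the 80 um strip
  # within one 50 um day
  res2 <- advance_sprout(net, net$sprouts$id[1], NULL, p)
  expect_equal(res2$outcome, "suppressed")
  expect_equal(nrow(res2$net$sprouts), 0)
  expect_equal(sum(res2$net$segments$type == "sprout"), 0)
})

test_that("growth events never connect a sprout to its own chain", {
  p <- angiogenesis_params(sigma_s = 0.3)
  net <- make_chain_network(c(0, 300, 600), c(0, 0, 0))
  net$domain <- tissue_domain(rbind(c(-200, -800), c(900, -800),
                                    c(900, 800), c(-200, 800)))
  set.seed(12)
  res <- spawn_sprout(net, 1, t_frac = 0.5, p)
  net <- res$net
  for (d in 1:6) {
    if (nrow(net$sprouts) == 0) break
    res <- advance_sprout(net, net$sprouts$id[1], NULL, p)
    net <- res$net
    expect_true(res$outcome %in% c("growing", "suppressed"))
  }
  expect_true(validate_network(net))
})
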