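# End-to-end engine behavior on a reduced tissue domain (about 0.5 mm2)
# kept small so full multi-day simulations stay fast.

small_skeleton <- function(seed = 3, demand = 2) {
  generate_skeleton(skeleton_spec(area = 0.53, demand = demand),
                    seed = seed)
}

test_that("demand schedules parse and apply stepwise", {
  sch <- parse_demand_schedule("0:0.5,50:1.5")
  expect_equal(sch$day, c(0, 50))
  expect_equal(sch$demand, c(0.5, 1.5))
  expect_equal(angioadapt:::demand_at(sch, 10, 2), 0.5)
  expect_equal(angioadapt:::demand_at(sch, 50, 2), 1.5)
  expect_equal(angioadapt:::demand_at(sch, 200, 2), 1.5)
  cfg <- simulation_config(demand_schedule = "0:0.5,50:1.5")
  expect_s3_class(cfg$demand_schedule, "data.frame")
})

test_that("a zero-day run returns initial metrics only", {
  net <- small_skeleton()
  res <- simulate_angiogenesis(net, simulation_config(days = 0, seed = 1))
  expect_null(res$records)
  expect_s3_class(res$oxygen, "oxygen_state")
  expect_identical(res$net$segments, net$segments)
})

test_that("trajectories are a pure function of config and seed", {
  net <- small_skeleton()
  cfg <- simulation_config(days = 3, seed = 11)
  r1 <- simulate_angiogenesis(net, cfg)
  r2 <- simulate_angiogenesis(net, cfg)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$net$segments, r2$net$segments)
  r3 <- simulate_angiogenesis(net, simulation_config(days = 3, seed = 12))
  expect_false(identical(r1$records$total_length_mm,
                         r3$records$total_length_mm))
})

test_that("structure is frozen when every mechanism is off", {
  net <- small_skeleton()
  cfg <- simulation_config(days = 2, seed = 2, sprouting_on = FALSE,
                           adaptation_on = FALSE, migration_on = FALSE)
  res <- simulate_angiogenesis(net, cfg)
  expect_identical(res$net$segments, net$segments)
  expect_identical(res$net$nodes, net$nodes)
  expect_equal(nrow(res$records), 2)
})

test_that("without adaptation all new vessels keep the 10 um bore", {
  net <- small_skeleton()
  cfg <- simulation_config(days = 8, seed = 5, adaptation_on = FALSE)
  res <- simulate_angiogenesis(net, cfg)
  # with adaptation off no diameter ever changes: every segment either
  # keeps a seed diameter (splits inherit their parent's) or carries the
  # 10 um bore of sprout-derived growth
  expect_gt(nrow(res$net$segments), nrow(net$segments))
  expect_true(all(res$net$segments$diameter %in%
                    c(net$segments$diameter, 10)))
  expect_true(any(res$net$segments$diameter == 10))
  old <- res$net$segments[res$net$segments$id %in% net$segments$id, ]
  expect_equal(old$diameter,
               net$segments$diameter[match(old$id, net$segments$id)])
})

test_that("no sprouts form when VEGF stays below threshold", {
  net <- small_skeleton(demand = 0.02)   # nearly no demand: no hypoxia
  cfg <- simulation_config(days = 2, seed = 3,
                           oxygen = oxygen_params(M0 = 0.02),
                           adaptation_on = FALSE, migration_on = FALSE)
  res <- simulate_angiogenesis(net, cfg)
  expect_equal(sum(res$records$sprouts_formed), 0)
  expect_identical(res$net$segments, net$segments)
})

test_that("sprout counts track the summed formation probabilities", {
  net <- small_skeleton()
  f <- solve_flow(net)
  o <- solve_oxygen(net, f)
  v <- solve_vegf(o, net$domain)
  p <- angiogenesis_params()
  lens <- segment_lengths(net)
  co <- angioadapt:::segment_coords(net)
  # expectation over uniform point sampling, approximated at midpoints
  pr <- vapply(seq_len(nrow(net$segments)), function(k) {
    cg <- local_concentration(v, (co[k, 1] + co[k, 3]) / 2,
                              (co[k, 2] + co[k, 4]) / 2)
    sprout_formation_probability(cg, lens[k], p)
  }, numeric(1))
  expected <- sum(pr)
  # count attempted sprout events over many independent step draws
  n_rep <- 40
  formed <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    streams <- rng_streams(1000 + r)
    state <- list(net = net, oxygen = NULL, day = 0)
    cfg <- simulation_config(days = 1, seed = 1000 + r,
                             adaptation_on = FALSE, migration_on = FALSE)
    st <- simulation_step(state, cfg, streams)
    formed[r] <- st$record$sprouts_formed + st$record$sprouts_suppressed
  }
  m <- mean(formed)
  se <- sd(formed) / sqrt(n_rep)
  expect_lt(abs(m - expected), max(4 * se, 0.75))
})
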