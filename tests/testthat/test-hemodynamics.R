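test_that("Poiseuille resistance follows the fourth-power law and units", {
  R0 <- segment_resistance(100, 10, 2)
  expect_equal(segment_resistance(100, 20, 2), R0 / 16)
  expect_equal(segment_resistance(200, 10, 2), 2 * R0)
  # independent SI evaluation converted to mmHg.min/nl
  R_si <- 128 * (2e-3) * (100e-6) / (pi * (10e-6)^4)   # Pa s / m3
  R_expect <- R_si * (1e-12 / 60) / 133.322
  expect_equal(R0, R_expect, tolerance = 1e-6)
  expect_error(segment_resistance(0, 10, 2))
  expect_error(segment_resistance(100, -1, 2))
})

test_that("in-vivo viscosity law has the expected structure", {
  # cell-free limit equals the law's plasma baseline
  D <- c(6, 10, 25, 60)
  expect_equal(apparent_viscosity(D, 0), (D / (D - 1.1))^2)
  # strictly increasing in hematocrit at fixed diameter
  for (d in D) {
    eta <- apparent_viscosity(d, seq(0, 0.8, by = 0.05))
    expect_true(all(diff(eta) > 0))
  }
  # diameter dependence at H=0.45: steep rise in the smallest vessels and
  # a broad minimum before the large-vessel limit
  expect_lt(apparent_viscosity(40, 0.45), apparent_viscosity(300, 0.45))
  expect_gt(apparent_viscosity(7, 0.45), apparent_viscosity(40, 0.45))
  expect_error(apparent_viscosity(10, 1))
})

test_that("phase separation conserves red-cell flux exactly", {
  expect_equal(phase_separation(0, 20, c(10, 10), c(5, 5)), c(0, 0))
  # identical daughters with equal flows split evenly
  h <- phase_separation(0.45, 20, c(10, 10), c(5, 5))
  expect_equal(h[1], h[2])
  set.seed(5)
  for (i in 1:50) {
    pd <- runif(1, 8, 40)
    dd <- runif(2, 5, pd)
    Q <- runif(2, 0.05, 20)
    H <- runif(1, 0.05, 0.7)
    hh <- phase_separation(H, pd, dd, Q)
    expect_true(all(hh >= 0 & hh <= 1))
    expect_equal(sum(hh * Q), H * sum(Q), tolerance = 1e-12)
  }
  expect_error(phase_separation(0.4, 20, c(10, 10), c(5, 6),
                                parent_Q = 20))
})

test_that("single-segment flow is Ohmic", {
  net <- toy_network("single_segment")
  f <- solve_flow(net)
  eta <- apparent_viscosity(20, f$hematocrit[1])
  R <- segment_resistance(500, 20, eta)
  expect_equal(f$flow[1], (59.09 - 15) / R, tolerance = 1e-6)
  expect_equal(f$hematocrit[1], 0.45)
})

test_that("equal parallel paths split flow evenly", {
  net <- toy_network("parallel_loop")
  f <- solve_flow(net)
  q_up <- abs(f$flow[match(2, f$segment_id)])
  q_dn <- abs(f$flow[match(4, f$segment_id)])
  expect_equal(q_up, q_dn, tolerance = 1e-6)
  # conservation at the junction
  expect_equal(q_up + q_dn, abs(f$flow[match(1, f$segment_id)]),
               tolerance = 1e-6)
})

test_that("solver matches a dense direct solve in the cell-free limit", {
  net <- toy_network("grid_mesh")
  net$nodes$bc_hematocrit[!is.na(net$nodes$bc_hematocrit)] <- 0
  f <- solve_flow(net)
  # oracle: dense resistive solve with the same per-segment viscosities
  oracle <- dense_flow_oracle_eta(net)
  expect_equal(f$pressure[match(oracle$node_id, f$node_id)],
               oracle$pressure, tolerance = 1e-9)
  expect_equal(f$flow, oracle$flow[match(f$segment_id,
                                         oracle$segment_id)],
               tolerance = 1e-9)
})

test_that("interior nodes conserve mass and boundaries conserve RBC flux", {
  net <- toy_network("grid_mesh")
  f <- solve_flow(net)
  nid <- f$node_id
  kind <- net$nodes$kind[match(nid, net$nodes$id)]
  for (n in which(kind == "interior")) {
    bal <- sum(f$flow[f$from == nid[n]]) - sum(f$flow[f$to == nid[n]])
    expect_lt(abs(bal), 1e-6 * mean(abs(f$flow)))
  }
  # global RBC conservation across the network boundary
  rbc_in <- rbc_out <- 0
  for (n in which(kind == "boundary")) {
    out_ <- sum(f$flow[f$from == nid[n]] * f$hematocrit[f$from == nid[n]]) -
      sum(f$flow[f$to == nid[n]] * f$hematocrit[f$to == nid[n]])
    if (out_ > 0) rbc_in <- rbc_in + out_ else rbc_out <- rbc_out - out_
  }
  expect_equal(rbc_in, rbc_out, tolerance = 1e-6)
})

test_that("both shear-stress forms agree on solved segments", {
  net <- toy_network("Y_bifurcation")
  f <- solve_flow(net)
  # cgs evaluation: eta in poise, Q in cm3/s, D in cm -> dyn/cm2
  tau_q <- 32 * (f$viscosity * 1e-2) * (abs(f$flow) * 1e-6 / 60) /
    (pi * (f$diameter * 1e-4)^3)
  expect_equal(f$shear, tau_q, tolerance = 1e-6)
  # linearity in Q at fixed geometry
  expect_equal(wall_shear_stress(2, 10, 100),
               2 * wall_shear_stress(1, 10, 100))
  expect_equal(wall_shear_stress(0, 10, 100), 0)
})

test_that("missing pressure reference is rejected", {
  net <- toy_network("single_segment")
  net$nodes$bc_type <- "flow"
  expect_error(solve_flow(net), "pressure")
})
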