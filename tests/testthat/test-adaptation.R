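test_that("shear set point rises smoothly with pressure and saturates", {
  expect_gt(pressure_shear_setpoint(60), pressure_shear_setpoint(25))
  expect_lt(abs(pressure_shear_setpoint(100) /
                  pressure_shear_setpoint(200) - 1), 0.1)
  tau <- pressure_shear_setpoint(seq(10, 120, by = 1))
  expect_true(all(diff(tau) > 0))
  expect_true(all(abs(diff(tau)) < 5))   # no jumps on a 1 mmHg grid
})

test_that("metabolic signal normalization and oxygen sensitivity", {
  p <- adaptation_params()
  expect_equal(metabolic_signal_local(p$P_O2_ref, p), 0)
  expect_equal(metabolic_signal_local(150, p), 0)
  expect_equal(metabolic_signal_local(0, p), 1)
  # steeper response at low PO2 for N = 2 than N = 1
  eps <- 0.01
  d2 <- abs(metabolic_signal_local(5 + eps, p, N = 2) -
              metabolic_signal_local(5 - eps, p, N = 2)) / (2 * eps)
  d1 <- abs(metabolic_signal_local(5 + eps, p, N = 1) -
              metabolic_signal_local(5 - eps, p, N = 1)) / (2 * eps)
  expect_gt(d2, d1)
})

test_that("downstream convection conserves the metabolic flux", {
  p <- adaptation_params()
  # zero signal everywhere stays zero
  net <- toy_network("Y_bifurcation")
  f <- solve_flow(net)
  conv0 <- convect_metabolic(f, rep(0, length(f$segment_id)), p)
  expect_equal(conv0$S_m, rep(0, length(f$segment_id)))
  # single unbranched path accumulates sum(J_m l)
  chain <- make_chain_network(c(0, 150, 300, 450), c(0, 0, 0, 0))
  fc <- solve_flow(chain)
  Jm <- c(0.2, 0.5, 0.8)[match(fc$segment_id, 1:3)]
  convc <- convect_metabolic(fc, Jm, p)
  expect_equal(max(convc$J_acc), sum(Jm * fc$length))
  # at a diverging node the daughters' accumulated fluxes sum to the
  # parent total (tested on the Y and the mesh)
  for (kind in c("Y_bifurcation", "grid_mesh")) {
    nk <- toy_network(kind)
    fk <- solve_flow(nk)
    Jk <- rep(0.5, length(fk$segment_id))
    ck <- convect_metabolic(fk, Jk, p)
    topo <- angioadapt:::.flow_topology(fk)
    for (nd in seq_len(topo$n)) {
      ins <- which(topo$dn == nd & topo$live)
      outs <- which(topo$up == nd & topo$live)
      if (length(ins) > 0 && length(outs) > 1) {
        expect_equal(sum(ck$J_acc[outs] - Jk[outs] * fk$length[outs]),
                     sum(ck$J_acc[ins]), tolerance = 1e-9)
      }
    }
  }
})

test_that("conducted responses decay exponentially and saturate", {
  p <- adaptation_params()
  # long chain: the far-upstream segment sees the downstream injection
  # attenuated by exp(-s/L_c)
  n <- 11
  xs <- seq(0, 5000, length.out = n)
  chain <- make_chain_network(xs, rep(0, n))
  f <- solve_flow(chain)
  S_m <- rep(0, length(f$segment_id))
  src <- which.max(f$length * 0 + seq_along(f$segment_id))  # last segment
  S_m[src] <- 1
  cond <- conduct_upstream(f, S_m, p)
  lam <- p$L_c
  l <- f$length[1]
  # ratio between successive upstream segments follows the decay factor
  Jc <- cond$J_c
  ratios <- Jc[1:(src - 2)] / Jc[2:(src - 1)]
  expect_equal(ratios, rep(exp(-l / lam), src - 2), tolerance = 1e-6)
  # saturation: S_c = J_c/(J_c + J_01)
  expect_equal(cond$S_c, Jc / (Jc + p$J_01))
  expect_equal(1000 / (1000 + p$J_01), 0.5)
  expect_true(all(cond$S_c >= 0 & cond$S_c < 1))
})

test_that("diameter updates follow the geometric recurrence", {
  p <- adaptation_params()
  net <- toy_network("single_segment")
  # S_tot = 0 leaves the diameter unchanged
  stim0 <- data.frame(segment_id = 1, S_tot = 0)
  expect_equal(update_diameters(net, stim0, 1, p)$net$segments$diameter,
               20)
  # constant S_tot = -0.1 shrinks by (1 - 0.1/4.5) each step
  D <- 20
  for (k in 1:5) {
    stim <- data.frame(segment_id = 1, S_tot = -0.1)
    net <- update_diameters(net, stim, 1, p)$net
    D <- D * (1 - 0.1 / p$T_adapt)
    expect_equal(net$segments$diameter, D)
  }
  # fixed-diameter segments never change
  netf <- toy_network("single_segment")
  netf$segments$fixed <- TRUE
  stim <- data.frame(segment_id = 1, S_tot = 5)
  expect_equal(update_diameters(netf, stim, 1, p)$net$segments$diameter,
               20)
})

test_that("identical segments under identical stimuli change identically", {
  p <- adaptation_params(ran_ks = 0)
  net <- toy_network("parallel_loop")
  f <- solve_flow(net)
  stim <- adaptation_stimuli(f, rep(40, length(f$segment_id)), p,
                             noise = rep(0, length(f$segment_id)))
  # the two symmetric limbs receive equal stimuli
  i2 <- match(2, stim$segment_id); i4 <- match(4, stim$segment_id)
  expect_equal(stim$S_tot[i2], stim$S_tot[i4], tolerance = 1e-9)
  # exported decomposition reassembles into S_tot exactly
  recomposed <- stim$shear_term - stim$pressure_term +
    p$k_m * stim$S_m + p$k_c * stim$S_c - (p$k_s + stim$ks_noise)
  expect_equal(recomposed, stim$S_tot)
})

test_that("a single vessel under fixed pressures reaches a stable bore", {
  p <- adaptation_params()
  net <- toy_network("single_segment")
  Ds <- numeric(250)
  for (i in 1:250) {
    f <- solve_flow(net)
    stim <- adaptation_stimuli(f, vessel_po2 = 40, params = p, noise = 0)
    net <- update_diameters(net, stim, 1, p)$net
    Ds[i] <- net$segments$diameter
  }
  # converged: negligible late drift, no divergence or collapse
  expect_lt(abs(Ds[250] - Ds[200]), 0.01)
  expect_gt(Ds[250], 3)
  expect_lt(Ds[250], 60)
})

test_that("conducted responses keep long pathways open against shunts", {
  # arteriole-venule pair with a short shunt and a long exchange path:
  # adaptation with the default conducted strength keeps the long path,
  # while a weak conducted response lets the shunt win
  strong <- cached_run("shunt_strong", function()
    run_shunt_experiment(2.45))
  weak <- cached_run("shunt_weak", function()
    run_shunt_experiment(0.5))
  expect_true(strong$long)
  expect_true(weak$shunt)
  expect_gt(weak$d_shunt, weak$d_long)
  expect_gt(strong$d_long, weak$d_long)
})
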