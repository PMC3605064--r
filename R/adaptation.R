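# Structural diameter adaptation of flowing segments: wall-shear and
# pressure responses, an oxygen-dependent metabolic signal convected
# downstream, a conducted response propagated upstream along vessel walls
# with exponential decay, a stochastic shrinking tendency, and the pruning
# trigger at the 3 um red-cell passage minimum.

#' Structural adaptation parameters
#'
#' @param tau_ref reference (offset) wall shear stress, dyn/cm2 (0.103).
#' @param P_O2_ref reference oxygen level of the metabolic signal, mmHg
#'   (93.2).
#' @param L_c conducted-response length constant, um (17300).
#' @param Q_ref reference flow of the metabolic signal, nl/min (0.198).
#' @param J_01 conducted-response saturation constant, um (1000).
#' @param k_p pressure sensitivity (0.68).
#' @param k_m metabolic sensitivity (0.70).
#' @param k_c conducted-response sensitivity (2.45).
#' @param k_s shrinking tendency (2.549).
#' @param ran_ks standard deviation of the per-segment, per-step Gaussian
#'   perturbation of k_s (0.1).
#' @param T_adapt structural adaptation time scale, day (4.5).
#' @param N_oxy oxygen-sensitivity exponent of the metabolic signal (2).
#' @param D_min pruning diameter threshold, um (3): red-cell passage
#'   minimum; segments strictly below it are pruned.
#' @return list of class \code{adaptation_params}.
#' @export
adaptation_params <- function(tau_ref = 0.103, P_O2_ref = 93.2,
                              L_c = 17300, Q_ref = 0.198, J_01 = 1000,
                              k_p = 0.68, k_m = 0.70, k_c = 2.45,
                              k_s = 2.549, ran_ks = 0.1, T_adapt = 4.5,
                              N_oxy = 2, D_min = 3) {
  structure(as.list(environment()), class = "adaptation_params")
}

#' Shear-stress set point as a function of intravascular pressure
#'
#' The empirical sigmoidal dependence of wall shear stress on intravascular
#' pressure observed in microvascular beds,
#' tau_e(P) = 100 - 86 exp(-5000 (log10(log10 P))^5.4), P in mmHg
#' (valid above ~10 mmHg), tau_e in dyn/cm2.
#'
#' @param P intravascular pressure (mmHg).
#' @return set-point shear stress (dyn/cm2).
#' @export
pressure_shear_setpoint <- function(P) {
  P <- pmax(P, 10.001)
  100 - 86 * exp(-5000 * (log10(log10(P)))^5.4)
}

#' Local metabolic signal of a vessel
#'
#' J_m decreases from 1 at PO2 = 0 to 0 at PO2 >= P_O2_ref:
#' J_m = (max(0, 1 - P/P_O2_ref))^N. The exponent N = 2 steepens the
#' response at low PO2 relative to N = 1.
#'
#' @param P_O2 vessel blood PO2 (mmHg).
#' @param params an \code{adaptation_params}.
#' @param N oxygen-sensitivity exponent; defaults to \code{params$N_oxy}.
#' @return J_m, dimensionless in \[0, 1\].
#' @export
metabolic_signal_local <- function(P_O2, params = adaptation_params(),
                                   N = params$N_oxy) {
  pmax(0, 1 - pmax(P_O2, 0) / params$P_O2_ref)^N
}

# order flowing segments so every segment appears after all segments
# feeding its upstream node (flow DAG topological order); returns a list
# with per-segment upstream/downstream local node indices
.flow_topology <- function(flow, q_eps = 1e-10) {
  nid <- flow$node_id
  n <- length(nid)
  i <- match(flow$from, nid)
  j <- match(flow$to, nid)
  up <- ifelse(flow$flow >= 0, i, j)
  dn <- ifelse(flow$flow >= 0, j, i)
  absQ <- abs(flow$flow)
  live <- absQ > q_eps
  n_in <- tabulate(dn[live], nbins = n)
  done <- integer(n)
  queue <- which(n_in == 0)
  order_seg <- integer(0)
  guard <- 0
  while (length(queue) > 0 && guard < 10 * (n + length(i))) {
    guard <- guard + 1
    nd <- queue[1]; queue <- queue[-1]
    outs <- which(up == nd & live)
    for (s in outs) {
      order_seg <- c(order_seg, s)
      tgt <- dn[s]
      done[tgt] <- done[tgt] + 1
      if (done[tgt] >= n_in[tgt] && n_in[tgt] > 0) queue <- c(queue, tgt)
    }
  }
  if (length(order_seg) < sum(live)) {
    stop("cyclic flow orientation: cannot order segments along flow")
  }
  list(up = up, dn = dn, absQ = absQ, live = live, order = order_seg,
       n = n)
}

#' Convect the metabolic signal downstream
#'
#' Each segment generates J_m l_seg; the running total is carried with the
#' flow, split at diverging nodes in proportion to outflow and summed at
#' converging nodes. The local metabolic stimulus is the saturating
#' S_m = log10(1 + J_acc / (Q + Q_ref)), increasing with accumulated flux
#' and decreasing with flow.
#'
#' @param flow a \code{hemodynamic_state}.
#' @param J_m per-segment local metabolic signal.
#' @param params an \code{adaptation_params}.
#' @return list with per-segment \code{J_acc} (um) and \code{S_m}.
#' @export
convect_metabolic <- function(flow, J_m, params = adaptation_params()) {
  topo <- .flow_topology(flow)
  ns <- length(flow$segment_id)
  node_out_Q <- rep(0, topo$n)
  node_flux <- rep(0, topo$n)
  for (s in which(topo$live)) {
    node_out_Q[topo$up[s]] <- node_out_Q[topo$up[s]] + topo$absQ[s]
  }
  J_acc <- rep(0, ns)
  for (s in topo$order) {
    inflow <- if (node_out_Q[topo$up[s]] > 0) {
      node_flux[topo$up[s]] * topo$absQ[s] / node_out_Q[topo$up[s]]
    } else 0
    J_acc[s] <- inflow + J_m[s] * flow$length[s]
    node_flux[topo$dn[s]] <- node_flux[topo$dn[s]] + J_acc[s]
  }
  S_m <- log10(1 + J_acc / (topo$absQ + params$Q_ref))
  S_m[!topo$live] <- 0
  list(J_acc = J_acc, S_m = S_m)
}

#' Propagate the conducted response upstream
#'
#' Each segment injects S_m l_seg; the signal travels against the flow,
#' decaying as exp(-s/L_c) over path length s. Where several conducted
#' streams meet they are summed; where conduction must split among several
#' upstream vessels it is divided equally. The conducted stimulus is the
#' saturating S_c = J_c / (J_c + J_01), in \[0, 1).
#'
#' @param flow a \code{hemodynamic_state}.
#' @param S_m per-segment metabolic stimulus from [convect_metabolic()].
#' @param params an \code{adaptation_params}.
#' @return list with per-segment \code{J_c} (um) and \code{S_c}.
#' @export
conduct_upstream <- function(flow, S_m, params = adaptation_params()) {
  topo <- .flow_topology(flow)
  ns <- length(flow$segment_id)
  # process in reverse flow order: a segment is handled after all segments
  # downstream of its downstream node
  node_sig <- rep(0, topo$n)       # conducted signal waiting at a node
  node_n_up <- rep(0, topo$n)      # number of upstream (feeding) segments
  for (s in which(topo$live)) {
    node_n_up[topo$dn[s]] <- node_n_up[topo$dn[s]] + 1
  }
  J_c <- rep(0, ns)
  lam <- params$L_c
  for (s in rev(topo$order)) {
    l <- flow$length[s]
    # signal arriving at the downstream end of s (shared equally among the
    # segments feeding that node)
    J_in <- if (node_n_up[topo$dn[s]] > 0) {
      node_sig[topo$dn[s]] / node_n_up[topo$dn[s]]
    } else 0
    # midpoint value: decayed incoming plus own injection integrated from
    # both halves of the segment
    own_mid <- 2 * S_m[s] * lam * (1 - exp(-l / (2 * lam)))
    J_c[s] <- J_in * exp(-l / (2 * lam)) + own_mid
    # signal passed to the upstream node of s
    own_up <- S_m[s] * lam * (1 - exp(-l / lam))
    node_sig[topo$up[s]] <- node_sig[topo$up[s]] +
      J_in * exp(-l / lam) + own_up
  }
  S_c <- J_c / (J_c + params$J_01)
  list(J_c = J_c, S_c = S_c)
}

#' Compute the per-segment adaptation stimulus breakdown
#'
#' S_tot = log10(tau_w + tau_ref) - k_p log10(tau_e(P)) + k_m S_m
#'       + k_c S_c - (k_s + eps), with eps ~ N(0, ran_ks) redrawn per
#' segment per step. Fixed-diameter segments receive stimuli but are not
#' updated.
#'
#' @param flow a \code{hemodynamic_state}.
#' @param vessel_po2 per-segment blood PO2 (mmHg), aligned with
#'   \code{flow$segment_id}.
#' @param params an \code{adaptation_params}.
#' @param noise optional per-segment k_s perturbation (for reproducibility
#'   in tests); defaults to fresh Gaussian draws.
#' @return data.frame with the stimulus decomposition per segment.
#' @export
adaptation_stimuli <- function(flow, vessel_po2,
                               params = adaptation_params(),
                               noise = NULL) {
  ns <- length(flow$segment_id)
  if (is.null(noise)) noise <- stats::rnorm(ns, 0, params$ran_ks)
  P_mid <- {
    nid <- flow$node_id
    (flow$pressure[match(flow$from, nid)] +
       flow$pressure[match(flow$to, nid)]) / 2
  }
  J_m <- metabolic_signal_local(ifelse(is.na(vessel_po2), 0, vessel_po2),
                                params)
  conv <- convect_metabolic(flow, J_m, params)
  cond <- conduct_upstream(flow, conv$S_m, params)
  shear_term <- log10(flow$shear + params$tau_ref)
  pressure_term <- params$k_p * log10(pressure_shear_setpoint(P_mid))
  S_tot <- shear_term - pressure_term + params$k_m * conv$S_m +
    params$k_c * cond$S_c - (params$k_s + noise)
  data.frame(segment_id = flow$segment_id,
             shear_term = shear_term,
             pressure_term = pressure_term,
             J_m = J_m, S_m = conv$S_m, J_acc = conv$J_acc,
             J_c = cond$J_c, S_c = cond$S_c,
             ks_noise = noise, S_tot = S_tot)
}

#' Update segment diameters and flag prunable segments
#'
#' Applies dD = D S_tot dt / T_adapt synchronously to all flowing,
#' non-fixed segments and returns the ids of segments whose new diameter
#' falls strictly below the red-cell passage minimum (3 um).
#'
#' @param net a \code{vascular_network}.
#' @param stimuli output of [adaptation_stimuli()].
#' @param dt time step (day).
#' @param params an \code{adaptation_params}.
#' @return list \code{net} (updated diameters) and \code{prune_ids}.
#' @export
update_diameters <- function(net, stimuli, dt = 1,
                             params = adaptation_params()) {
  si <- match(stimuli$segment_id, net$segments$id)
  upd <- !net$segments$fixed[si] & net$segments$flowing[si]
  D <- net$segments$diameter[si]
  D_new <- D + D * stimuli$S_tot * dt / params$T_adapt
  D_new[!upd] <- D[!upd]
  D_new <- pmax(D_new, 0.1)
  net$segments$diameter[si] <- D_new
  prune <- stimuli$segment_id[upd & D_new < params$D_min]
  list(net = net, prune_ids = prune)
}
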