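# Independent numerical oracles.
#
# oxygen_fd_oracle: finite-difference discretization of the steady tissue
# oxygen diffusion equation (fine grid, Neumann far boundary on a padded
# box emulating the free-space kernel, Peaceman-type subgrid correction at
# the vessel lines), coupled to the package's intravascular marching. Used
# to validate the Green's-function field solver.
#
# vegf_bessel_oracle: free-space modified-Helmholtz kernel (Bessel K0)
# superposition for the VEGF field, validating the sparse direct solver.

oxygen_fd_oracle <- function(net, flow, domain, params = oxygen_params(),
                             h = 6.25, pad = 1000, max_iter = 80,
                             tol = 0.05) {
  par <- params
  par$P_cap <- max(net$nodes$bc_po2, 60, na.rm = TRUE)
  K <- par$krogh
  h_slab <- domain$thickness * 1e-4            # cm
  xr <- range(domain$boundary[, 1]) + c(-pad, pad)
  yr <- range(domain$boundary[, 2]) + c(-pad, pad)
  gx <- seq(xr[1], xr[2], by = h)
  gy <- seq(yr[1], yr[2], by = h)
  nx <- length(gx); ny <- length(gy)
  nn <- nx * ny
  idx <- function(i, j) as.integer((j - 1) * nx + i)
  g_lap <- K * h_slab
  ii <- jj <- integer(0); xx <- numeric(0)
  ivec <- rep(seq_len(nx), ny)
  jvec <- rep(seq_len(ny), each = nx)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    i2 <- ivec + d[1]; j2 <- jvec + d[2]
    has <- i2 >= 1 & i2 <= nx & j2 >= 1 & j2 <= ny
    from <- idx(ivec, jvec)[has]; to <- idx(i2, j2)[has]
    ii <- c(ii, from, from)
    jj <- c(jj, from, to)
    xx <- c(xx, rep(g_lap, sum(has)), rep(-g_lap, sum(has)))
  }
  Lap <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nn, nn))

  # dimensionless 5-point lattice Green function (unit source, far-field
  # matched to the continuum -ln(r)/2pi), used to translate grid values
  # near deposited sources into continuum wall/point values
  Ulat <- .lattice_green_table(60)
  u_lat <- function(dx, dy) .lattice_green_interp(Ulat, dx, dy)

  # map fine nodes to tissue cells
  pts <- domain$points
  gxm <- rep(gx, ny); gym <- rep(gy, each = nx)
  cell_of <- rep(NA_integer_, nn)
  for (k in seq_len(nrow(pts))) {
    sel <- which(abs(gxm - pts$x[k]) <= domain$spacing / 2 &
                   abs(gym - pts$y[k]) <= domain$spacing / 2)
    cell_of[sel] <- k
  }
  in_cell <- !is.na(cell_of)
  cell_nodes <- split(which(in_cell), cell_of[in_cell])
  center_node <- vapply(seq_len(nrow(pts)), function(k) {
    idx(which.min(abs(gx - pts$x[k])), which.min(abs(gy - pts$y[k])))
  }, integer(1))
  A_cell <- (domain$spacing * 1e-4)^2
  a_dem <- (par$M0 / 100 / 60) * h_slab * A_cell
  a_eq <- domain$spacing / sqrt(pi)            # equivalent disc radius

  # vessel elements, their grid deposition and true subpoint positions
  el <- .discretize_vessels_oracle(net, flow, par)
  nv <- length(el$x)
  dep_nodes <- vector("list", nv)
  dep_x <- dep_y <- dep_w <- dep_e <- dep_nd <- c()
  for (e in seq_len(nv)) {
    npt <- max(2, ceiling(el$len[e] / (h / 2)))
    tt <- (seq_len(npt) - 0.5) / npt - 0.5
    px <- el$x[e] + tt * el$len[e] * el$ux[e]
    py <- el$y[e] + tt * el$len[e] * el$uy[e]
    nd <- idx(pmin(pmax(round((px - gx[1]) / h) + 1, 1), nx),
              pmin(pmax(round((py - gy[1]) / h) + 1, 1), ny))
    dep_nodes[[e]] <- table(nd) / npt
    dep_x <- c(dep_x, px); dep_y <- c(dep_y, py)
    dep_w <- c(dep_w, rep(1 / npt, npt)); dep_e <- c(dep_e, rep(e, npt))
    dep_nd <- c(dep_nd, nd)
  }
  dep_nx <- gxm[dep_nd]; dep_ny <- gym[dep_nd]   # node coordinates
  k_wall <- vapply(seq_len(nv), function(e) {
    nu <- stats::approx(par$nusselt_D, par$nusselt, xout = el$diam[e],
                        rule = 2)$y
    nu * pi * par$K_plasma * el$len[e] * 1e-4
  }, numeric(1))
  R_c <- 60                                      # correction window (um)
  # lattice-to-continuum correction of a point sink's own evaluation:
  # the discrete problem evaluates a sink's field at itself through the
  # equivalent-disc convention (-ln a_eq + 1/2), while the lattice value
  # at the deposited node corresponds to U(0,0)
  conv_self <- (-log(a_eq / h) + 0.5) / (2 * pi)
  U00 <- .lattice_green_interp(Ulat, 0, 0)
  sink_self_corr <- function(s_vec) {
    -s_vec * (conv_self - U00) / (K * h_slab)
  }

  # continuum-vs-lattice correction for an evaluation point (ex, ey) at
  # an effective radius a from the deposited line mass, given source
  # strengths q (per element); returns mmHg
  local_corr <- function(ex, ey, a, q) {
    d_true <- sqrt((dep_x - ex)^2 + (dep_y - ey)^2)
    nearp <- which(d_true < R_c)
    if (length(nearp) == 0) return(0)
    q_p <- q[dep_e[nearp]] * dep_w[nearp]
    cont <- -log(sqrt(d_true[nearp]^2 + a^2) / h) / (2 * pi)
    lat <- u_lat((dep_nx[nearp] - ex) / h, (dep_ny[nearp] - ey) / h)
    sum(q_p * (cont - lat)) / (K * h_slab)
  }
  grid_interp <- function(P, ex, ey) {
    i <- pmin(pmax(floor((ex - gx[1]) / h) + 1, 1), nx - 1)
    j <- pmin(pmax(floor((ey - gy[1]) / h) + 1, 1), ny - 1)
    tx <- (ex - gx[i]) / h; ty <- (ey - gy[j]) / h
    P[idx(i, j)] * (1 - tx) * (1 - ty) + P[idx(i + 1, j)] * tx * (1 - ty) +
      P[idx(i, j + 1)] * (1 - tx) * ty + P[idx(i + 1, j + 1)] * tx * ty
  }

  Pfd <- rep(30, nn)
  Pb_elem <- rep(max(net$nodes$bc_po2, na.rm = TRUE), nv)
  q <- rep(0, nv)
  corr <- rep(0, nv)
  for (iter in seq_len(max_iter)) {
    # implicit linearized Michaelis-Menten sinks, lumped per 50 um cell
    # clamp the linearization point: the Michaelis-Menten sink vanishes
    # in anoxic cells and must never act as a phantom source
    Pc <- pmax(Pfd[center_node], 0)
    s_c <- a_dem * Pc / (par$P_half + Pc)
    m_c <- a_dem * par$P_half / (par$P_half + Pc)^2
    ii2 <- jj2 <- integer(0); xx2 <- numeric(0)
    rhs <- rep(0, nn)
    for (k in seq_along(cell_nodes)) {
      nodes_k <- cell_nodes[[k]]
      w <- 1 / length(nodes_k)
      rhs[nodes_k] <- rhs[nodes_k] - w * (s_c[k] - m_c[k] * Pc[k])
      ii2 <- c(ii2, nodes_k)
      jj2 <- c(jj2, rep(center_node[k], length(nodes_k)))
      xx2 <- c(xx2, rep(w * m_c[k], length(nodes_k)))
    }
    # semi-implicit Robin vessel coupling on the deposit nodes
    for (e in seq_len(nv)) {
      nd <- as.integer(names(dep_nodes[[e]]))
      w <- as.numeric(dep_nodes[[e]])
      ii2 <- c(ii2, nd); jj2 <- c(jj2, nd); xx2 <- c(xx2, k_wall[e] * w)
      rhs[nd] <- rhs[nd] + k_wall[e] * w * (Pb_elem[e] - corr[e])
    }
    A <- Lap + Matrix::sparseMatrix(i = ii2, j = jj2, x = xx2,
                                    dims = c(nn, nn))
    P_new <- as.numeric(Matrix::solve(A, rhs))
    for (e in seq_len(nv)) {
      nd <- as.integer(names(dep_nodes[[e]]))
      w <- as.numeric(dep_nodes[[e]])
      q[e] <- sum(k_wall[e] * w * (Pb_elem[e] - P_new[nd] - corr[e]))
    }
    # update the wall correction from the current source strengths:
    # P_wall = P_grid(midpoint) + local lattice-to-continuum correction
    corr_new <- vapply(seq_len(nv), function(e) {
      a <- max(el$diam[e] / 2, 1e-3)
      local_corr(el$x[e], el$y[e], a, q) +
        grid_interp(P_new, el$x[e], el$y[e]) -
        sum(as.numeric(dep_nodes[[e]]) *
              P_new[as.integer(names(dep_nodes[[e]]))])
    }, numeric(1))
    corr <- corr + 0.5 * (corr_new - corr)
    Pb <- .march_blood_po2(net, flow, el, q, par)
    dP <- max(abs(P_new - Pfd))
    dPb <- max(abs(Pb$elem - Pb_elem))
    Pb_elem <- Pb_elem + 0.7 * (Pb$elem - Pb_elem)
    Pfd <- P_new
    if (isTRUE(getOption("angioadapt.oracle.trace"))) {
      cat(sprintf("fd it %d dP=%.3f dPb=%.3f sumq=%.4g\n", iter, dP, dPb,
                  sum(q)))
    }
    if (dP < tol && dPb < tol && iter > 2) break
  }
  # tissue values at the tissue points: grid value plus the vessel
  # near-field correction
  tissue_po2 <- vapply(seq_len(nrow(pts)), function(k) {
    Pfd[center_node[k]] +
      local_corr(pts$x[k], pts$y[k], 1e-3, q)
  }, numeric(1))
  tissue_po2 <- pmax(tissue_po2, 0)
  list(tissue_po2 = tissue_po2, grid = Pfd, vessel_po2_elem = Pb_elem,
       q = q, iterations = iter)
}

# 5-point lattice Green function on a (2m+1)^2 patch: unit source at the
# centre, Dirichlet boundary set to the continuum -ln(r)/2pi
.lattice_green_table <- function(m = 60) {
  n <- 2 * m + 1
  nn <- n * n
  idx <- function(i, j) as.integer((j - 1) * n + i)
  iv <- rep(seq_len(n), n); jv <- rep(seq_len(n), each = n)
  bnd <- iv == 1 | iv == n | jv == 1 | jv == n
  ii <- jj <- integer(0); xx <- numeric(0)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    i2 <- iv + d[1]; j2 <- jv + d[2]
    has <- i2 >= 1 & i2 <= n & j2 >= 1 & j2 <= n & !bnd
    from <- idx(iv, jv)[has]; to <- idx(i2, j2)[has]
    ii <- c(ii, from, from); jj <- c(jj, from, to)
    xx <- c(xx, rep(1, sum(has)), rep(-1, sum(has)))
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nn, nn))
  A <- A + Matrix::sparseMatrix(i = which(bnd), j = which(bnd),
                                x = rep(1, sum(bnd)), dims = c(nn, nn))
  b <- rep(0, nn)
  r <- sqrt((iv - m - 1)^2 + (jv - m - 1)^2)
  b[bnd] <- -log(r[bnd]) / (2 * pi)
  b[idx(m + 1L, m + 1L)] <- b[idx(m + 1L, m + 1L)] + 1
  U <- as.numeric(Matrix::solve(A, b))
  list(U = matrix(U, n, n), m = m)
}

.lattice_green_interp <- function(tab, dx, dy) {
  m <- tab$m
  ax <- abs(dx); ay <- abs(dy)
  out <- numeric(length(ax))
  far <- pmax(ax, ay) >= m - 1
  if (any(far)) {
    out[far] <- -log(pmax(sqrt(ax[far]^2 + ay[far]^2), 0.5)) / (2 * pi)
  }
  if (any(!far)) {
    i <- floor(ax[!far]); j <- floor(ay[!far])
    tx <- ax[!far] - i; ty <- ay[!far] - j
    U <- tab$U
    c00 <- U[cbind(i + m + 1, j + m + 1)]
    c10 <- U[cbind(i + m + 2, j + m + 1)]
    c01 <- U[cbind(i + m + 1, j + m + 2)]
    c11 <- U[cbind(i + m + 2, j + m + 2)]
    out[!far] <- c00 * (1 - tx) * (1 - ty) + c10 * tx * (1 - ty) +
      c01 * (1 - tx) * ty + c11 * tx * ty
  }
  out
}

# element table in the layout .march_blood_po2 expects, plus unit vectors
.discretize_vessels_oracle <- function(net, flow, par) {
  el <- angioadapt:::.discretize_vessels(net, flow, par)
  nv <- length(el$x)
  ux <- uy <- numeric(nv)
  co <- angioadapt:::segment_coords(net)[net$segments$flowing, ,
                                         drop = FALSE]
  for (k in seq_along(flow$segment_id)) {
    ix <- el$seg_elems[[k]]
    if (is.null(ix) || length(ix) == 0) next
    dx <- co[k, 3] - co[k, 1]; dy <- co[k, 4] - co[k, 2]
    nrm <- sqrt(dx^2 + dy^2)
    ux[ix] <- dx / nrm; uy[ix] <- dy / nrm
  }
  el$ux <- ux; el$uy <- uy
  el
}

# free-space Bessel-kernel superposition for the VEGF increment produced
# by per-cell release rates (pM/s); returns concentration at query points
vegf_bessel_oracle <- function(release, domain, params = vegf_params(),
                               qx, qy) {
  L <- sqrt(params$D_G / params$K_G) / 1e-4     # um
  A_cell <- (domain$spacing * 1e-4)^2           # cm2
  a_eq <- domain$spacing / sqrt(pi)             # um
  pts <- domain$points
  out <- numeric(length(qx))
  # C(r) = (S / (2 pi D_G)) K0(r/L), S = release * area (pM cm2/s)
  pref <- A_cell / (2 * pi * params$D_G)
  for (i in seq_along(qx)) {
    r <- sqrt((pts$x - qx[i])^2 + (pts$y - qy[i])^2)
    ker <- numeric(length(r))
    far <- r > a_eq / 2
    ker[far] <- besselK(r[far] / L, 0)
    if (any(!far)) {
      # average of K0 over the equivalent disc (self cell)
      aL <- a_eq / L
      ker[!far] <- 2 * (1 - aL * besselK(aL, 1)) / aL^2
    }
    out[i] <- sum(pref * release * ker)
  }
  out
}

# dense direct resistive-network solve: oracle for the sparse flow
# solver (viscosity fixed per segment at the cell-free value of the law,
# matching a zero-hematocrit solve)
dense_flow_oracle_eta <- function(net) {
  segs <- net$segments[net$segments$flowing, , drop = FALSE]
  eta <- apparent_viscosity(segs$diameter, 0)
  nodes <- net$nodes[net$nodes$id %in% c(segs$from, segs$to), ,
                     drop = FALSE]
  nid <- nodes$id
  n <- length(nid)
  i <- match(segs$from, nid); j <- match(segs$to, nid)
  co_from <- nodes[match(segs$from, nodes$id), c("x", "y")]
  co_to <- nodes[match(segs$to, nodes$id), c("x", "y")]
  len <- sqrt((co_to$x - co_from$x)^2 + (co_to$y - co_from$y)^2)
  g <- 1 / segment_resistance(len, segs$diameter, eta)
  A <- matrix(0, n, n)
  b <- rep(0, n)
  for (k in seq_along(g)) {
    A[i[k], i[k]] <- A[i[k], i[k]] + g[k]
    A[j[k], j[k]] <- A[j[k], j[k]] + g[k]
    A[i[k], j[k]] <- A[i[k], j[k]] - g[k]
    A[j[k], i[k]] <- A[j[k], i[k]] - g[k]
  }
  for (r in which(nodes$kind == "boundary" & nodes$bc_type == "pressure")) {
    A[r, ] <- 0
    A[r, r] <- 1
    b[r] <- nodes$bc_value[r]
  }
  for (r in which(nodes$kind == "boundary" & nodes$bc_type == "flow")) {
    b[r] <- b[r] + nodes$bc_value[r]
  }
  P <- solve(A, b)
  list(node_id = nid, pressure = P, flow = g * (P[i] - P[j]),
       segment_id = segs$id)
}
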