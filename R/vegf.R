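# Steady-state VEGF concentration field: hypoxia-dependent release by
# parenchymal cells, diffusion, and first-order degradation (a modified
# Helmholtz problem on the tissue-point grid, zero-flux boundary).

#' VEGF field parameters
#'
#' @param D_G diffusivity, cm2/s (1.13e-6).
#' @param M_G0 basal release rate, pM/s (1.97e-3).
#' @param K_G degradation rate constant, 1/s (2.82e-3); the diffusion
#'   length scale is \code{sqrt(D_G/K_G)} = 200 um.
#' @param C_th sprouting threshold concentration, pM (0.8).
#' @param C_th50 half-saturation increment of the sprouting rate, pM (0.5).
#' @param P_release PO2 (mmHg) below which release rises above basal;
#'   release is basal above it and reaches 6x basal at PO2 = 0.
#' @return list of class \code{vegf_params}.
#' @export
vegf_params <- function(D_G = 1.13e-6, M_G0 = 1.97e-3, K_G = 2.82e-3,
                        C_th = 0.8, C_th50 = 0.5, P_release = 20) {
  p <- as.list(environment())
  p$L_diff <- sqrt(D_G / K_G) / UM_TO_CM   # um
  structure(p, class = "vegf_params")
}

#' VEGF release rate as a function of tissue PO2
#'
#' Monotone non-increasing in PO2: basal rate M_G0 in well-oxygenated
#' tissue (PO2 >= \code{P_release}), rising linearly to 6 M_G0 at PO2 = 0,
#' so that attainable steady uniform concentrations span M_G0/K_G to
#' 6 M_G0/K_G (0.7 to 4.2 pM).
#'
#' @param P_O2 tissue PO2 (mmHg).
#' @param params a \code{vegf_params}.
#' @return release rate, pM/s.
#' @export
release_rate <- function(P_O2, params = vegf_params()) {
  P <- pmax(P_O2, 0)
  frac <- pmax(0, 1 - P / params$P_release)
  params$M_G0 * (1 + 5 * frac)
}

#' Solve the steady VEGF reaction-diffusion field
#'
#' Solves D_G lap(C) - K_G C + M_G(PO2) = 0 on the tissue-point grid with
#' zero-flux boundaries by a direct sparse solve; exchange of VEGF with
#' vessels is neglected.
#'
#' @param oxygen_state an \code{oxygen_state}, or a numeric vector of tissue
#'   PO2 values aligned with the domain's tissue points.
#' @param domain a \code{tissue_domain}.
#' @param params a \code{vegf_params}.
#' @return object of class \code{vegf_state}: \code{concentration} (pM per
#'   tissue point), \code{above_threshold} (logical), \code{points}.
#' @export
solve_vegf <- function(oxygen_state, domain, params = vegf_params()) {
  Pt <- if (inherits(oxygen_state, "oxygen_state")) oxygen_state$tissue_po2
        else as.numeric(oxygen_state)
  pts <- domain$points
  nt <- nrow(pts)
  if (length(Pt) != nt) stop("PO2 vector does not match tissue points")
  M <- release_rate(Pt, params)
  h <- domain$spacing * UM_TO_CM
  w <- params$D_G / h^2
  # masked 5-point Laplacian with mirrored (zero-flux) missing neighbours
  key <- paste(round(pts$x, 6), round(pts$y, 6))
  idx <- seq_len(nt)
  names(idx) <- key
  sp <- domain$spacing
  trip_i <- trip_j <- integer(0)
  trip_x <- numeric(0)
  diag_acc <- rep(params$K_G, nt)
  for (d in list(c(sp, 0), c(-sp, 0), c(0, sp), c(0, -sp))) {
    nb <- idx[paste(round(pts$x + d[1], 6), round(pts$y + d[2], 6))]
    has <- !is.na(nb)
    trip_i <- c(trip_i, which(has))
    trip_j <- c(trip_j, nb[has])
    trip_x <- c(trip_x, rep(-w, sum(has)))
    diag_acc[has] <- diag_acc[has] + w
  }
  A <- Matrix::sparseMatrix(i = c(trip_i, seq_len(nt)),
                            j = c(trip_j, seq_len(nt)),
                            x = c(trip_x, diag_acc), dims = c(nt, nt))
  C <- as.numeric(Matrix::solve(A, M))
  C <- pmax(C, 0)
  structure(list(concentration = C, points = pts,
                 above_threshold = C > params$C_th,
                 params = params, domain = domain),
            class = "vegf_state")
}

#' @export
print.vegf_state <- function(x, ...) {
  cat(sprintf("vegf_state: %d points, C_G %.2f-%.2f pM, %.1f%% above threshold\n",
              length(x$concentration), min(x$concentration),
              max(x$concentration), 100 * mean(x$above_threshold)))
  invisible(x)
}

#' Interpolate the VEGF field at arbitrary positions
#'
#' Bilinear interpolation of the grid concentration at query positions;
#' cells with a missing (out-of-domain) corner fall back to the mean of the
#' available corners.
#'
#' @param vegf_state a \code{vegf_state}.
#' @param x,y query coordinates (um).
#' @return concentrations, pM.
#' @export
local_concentration <- function(vegf_state, x, y) {
  dom <- vegf_state$domain
  gx <- dom$grid_x; gy <- dom$grid_y
  nxg <- length(gx); nyg <- length(gy)
  grid <- matrix(NA_real_, nxg, nyg)
  pt <- vegf_state$points
  gi <- round((pt$x - gx[1]) / dom$spacing) + 1
  gj <- round((pt$y - gy[1]) / dom$spacing) + 1
  grid[cbind(gi, gj)] <- vegf_state$concentration
  ix <- findInterval(x, gx, all.inside = TRUE)
  iy <- findInterval(y, gy, all.inside = TRUE)
  out <- numeric(length(x))
  for (k in seq_along(x)) {
    i <- ix[k]; j <- iy[k]
    tx <- (x[k] - gx[i]) / dom$spacing
    ty <- (y[k] - gy[j]) / dom$spacing
    tx <- min(max(tx, 0), 1); ty <- min(max(ty, 0), 1)
    c00 <- grid[i, j]; c10 <- grid[min(i + 1, nxg), j]
    c01 <- grid[i, min(j + 1, nyg)]; c11 <- grid[min(i + 1, nxg), min(j + 1, nyg)]
    corners <- c(c00, c10, c01, c11)
    wts <- c((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
    if (anyNA(corners)) {
      ok <- !is.na(corners)
      out[k] <- if (any(ok)) sum(corners[ok] * wts[ok]) / sum(wts[ok]) else 0
    } else {
      out[k] <- sum(corners * wts)
    }
  }
  out
}
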