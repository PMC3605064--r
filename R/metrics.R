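# Network-level summary statistics: total length, tissue-to-vessel
# distances, perfusion, oxygenation and branching-angle distributions,
# plus replicate (multi-seed) aggregation.

#' Summarize a solved network state
#'
#' @param net a \code{vascular_network}.
#' @param oxygen an \code{oxygen_state}.
#' @param flow a \code{hemodynamic_state}.
#' @param domain a \code{tissue_domain}; defaults to \code{net$domain}.
#' @param distance_bin,po2_bin,angle_bin histogram bin widths (um, mmHg,
#'   degrees).
#' @return list of class \code{network_summary}: scalar fields
#'   \code{total_length_mm}, \code{mean_vessel_distance_um},
#'   \code{flow_nlmin}, \code{mean_tissue_po2}, \code{hypoxic_fraction_pct},
#'   and frequency tables \code{distance_hist}, \code{po2_hist},
#'   \code{angle_hist} (each with \code{mid} and \code{freq} summing to 1).
#' @export
summarize_network <- function(net, oxygen, flow, domain = NULL,
                              distance_bin = 10, po2_bin = 5,
                              angle_bin = 10) {
  if (is.null(domain)) domain <- net$domain
  if (is.null(domain) || nrow(domain$points) == 0) {
    stop("tissue domain with tissue points required")
  }
  dist <- distance_to_nearest_vessel(net, domain$points)
  ang <- branching_angles(net)
  angv <- if (nrow(ang) > 0) unlist(ang[c("angle1", "angle2", "angle3")])
          else numeric(0)
  mk_hist <- function(v, w) {
    if (length(v) == 0) return(data.frame(mid = numeric(0),
                                          freq = numeric(0)))
    br <- seq(0, max(v, w) + w, by = w)
    h <- hist(v, breaks = br, plot = FALSE)
    data.frame(mid = h$mids, freq = h$counts / length(v))
  }
  structure(list(
    total_length_mm = total_vessel_length(net) / 1000,
    mean_vessel_distance_um = mean(dist),
    flow_nlmin = total_inflow(net, flow),
    mean_tissue_po2 = mean(oxygen$tissue_po2),
    hypoxic_fraction_pct = 100 * mean(oxygen$tissue_po2 < 1),
    n_branch_points = nrow(ang),
    distance_hist = mk_hist(dist, distance_bin),
    po2_hist = mk_hist(oxygen$tissue_po2, po2_bin),
    angle_hist = mk_hist(angv, angle_bin)),
    class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(paste0("network_summary: length %.2f mm | mean vessel ",
                     "distance %.1f um | flow %.1f nl/min | mean PO2 ",
                     "%.1f mmHg | hypoxic %.3f%%\n"),
              x$total_length_mm, x$mean_vessel_distance_um, x$flow_nlmin,
              x$mean_tissue_po2, x$hypoxic_fraction_pct))
  invisible(x)
}

#' Mean and standard deviation of summaries across seeded replicates
#'
#' Runs the provided function once per seed and aggregates every numeric
#' scalar field of the returned summaries.
#'
#' @param run_fn function(seed) returning a \code{network_summary} or a
#'   named list/one-row data.frame of numeric scalars.
#' @param seeds integer vector of seeds (length >= 2).
#' @return data.frame with columns \code{field}, \code{mean}, \code{sd},
#'   \code{n}.
#' @export
replicate_stats <- function(run_fn, seeds) {
  if (length(seeds) < 2) stop("need at least 2 seeds")
  rows <- lapply(seeds, function(s) {
    r <- run_fn(s)
    r <- unclass(r)
    num <- vapply(r, function(v) is.numeric(v) && length(v) == 1,
                  logical(1))
    unlist(r[num])
  })
  m <- do.call(rbind, rows)
  data.frame(field = colnames(m),
             mean = apply(m, 2, mean),
             sd = apply(m, 2, stats::sd),
             n = length(seeds), row.names = NULL)
}
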