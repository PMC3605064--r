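#' Simulation configuration
#'
#' Bundles all model parameters, run controls and mechanism toggles for a
#' simulation. Toggles default to the full model; knockouts (no adaptation,
#' no migration, weakened conducted response, altered sprout rate) are the
#' standard mechanism experiments.
#'
#' @param days run length in days (the time step is 1 day).
#' @param seed master RNG seed.
#' @param oxygen an \code{oxygen_params}.
#' @param vegf a \code{vegf_params}.
#' @param angio an \code{angiogenesis_params}.
#' @param adapt an \code{adaptation_params}.
#' @param migration a \code{migration_params}.
#' @param adaptation_on,migration_on,sprouting_on mechanism toggles.
#' @param demand_schedule named schedule of oxygen demand: either a single
#'   number or a string "0:0.5,50:1.5" applying 0.5 from day 0 and 1.5
#'   from day 50, or a data.frame with columns \code{day}, \code{demand}.
#' @param flow_tol,flow_max_iter flow-solver controls.
#' @param record_every record a step summary every this many days.
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(days = 200, seed = 1,
                              oxygen = oxygen_params(),
                              vegf = vegf_params(),
                              angio = angiogenesis_params(),
                              adapt = adaptation_params(),
                              migration = migration_params(),
                              adaptation_on = TRUE,
                              migration_on = TRUE,
                              sprouting_on = TRUE,
                              demand_schedule = NULL,
                              flow_tol = 1e-4, flow_max_iter = 100,
                              record_every = 1) {
  cfg <- as.list(environment())
  if (is.character(cfg$demand_schedule)) {
    cfg$demand_schedule <- parse_demand_schedule(cfg$demand_schedule)
  } else if (is.numeric(cfg$demand_schedule) &&
             length(cfg$demand_schedule) == 1) {
    cfg$demand_schedule <- data.frame(day = 0,
                                      demand = cfg$demand_schedule)
  }
  structure(cfg, class = "simulation_config")
}

#' Parse a demand step-schedule string
#'
#' "0:0.5,50:1.5" means demand 0.5 from day 0 and 1.5 from day 50 onward.
#'
#' @param text schedule string.
#' @return data.frame with columns \code{day}, \code{demand}.
#' @export
parse_demand_schedule <- function(text) {
  parts <- strsplit(strsplit(text, ",")[[1]], ":")
  df <- data.frame(day = vapply(parts, function(p) as.numeric(p[1]),
                                numeric(1)),
                   demand = vapply(parts, function(p) as.numeric(p[2]),
                                   numeric(1)))
  df[order(df$day), , drop = FALSE]
}

demand_at <- function(schedule, day, default) {
  if (is.null(schedule) || nrow(schedule) == 0) return(default)
  ix <- which(schedule$day <= day)
  if (length(ix) == 0) return(default)
  schedule$demand[max(ix)]
}
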