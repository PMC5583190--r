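#' Predator-attack protocol parameters
#'
#' The predator is an extra agent that does not take part in the alignment
#' consensus. It moves `speed_factor` times faster than the swarming agents,
#' always straight toward the nearest alive agent (periodic minimum-image
#' direction). Agents strictly within the danger-detection radius `r_detect`
#' override their heading with the direction pointing away from the
#' predator; that fleeing heading then propagates through the alignment
#' rule. Agents strictly within `r_catch` of the predator are removed
#' ("caught") and logged.
#'
#' Defaults tie the radii to the swarm geometry. The danger-detection
#' radius is a tenth of the box side (`0.1 * L`), the scale of the danger
#' region relative to the computation box in collective-escape
#' visualizations: it covers several mean spacings, so a local subgroup
#' perceives the threat directly and the rest must rely on socially
#' transmitted heading information. The catch radius is half the mean
#' nearest-neighbor spacing of a Poisson configuration at density `rho`
#' (`0.25 / sqrt(rho)`): comfortably below the typical inter-agent
#' distance, so a catch requires the predator to overtake an individual
#' rather than sweep up bystanders.
#'
#' @param config the [swarm_config()] the predator will attack (used for
#'   the radius defaults).
#' @param speed_factor predator speed / agent speed; default 1.4.
#' @param r_detect danger-detection radius.
#' @param r_catch catch radius (must be < `r_detect`).
#' @param intro_step iteration at which the predator appears; default 2000.
#' @param n_steps total iterations per run; default 5000.
#' @param n_runs independent runs per experiment condition; default 500.
#' @return an object of class `"predator_config"`.
#' @export
predator_config <- function(config, speed_factor = 1.4,
                            r_detect = NULL, r_catch = NULL,
                            intro_step = 2000, n_steps = 5000,
                            n_runs = 500) {
  rho <- config$n_agents / config$box_length^2
  if (is.null(r_detect)) r_detect <- 0.1 * config$box_length
  if (is.null(r_catch)) r_catch <- 0.25 / sqrt(rho)
  stopifnot(speed_factor > 0, r_catch < r_detect, intro_step < n_steps,
            r_catch > 0)
  structure(list(speed_factor = speed_factor, r_detect = r_detect,
                 r_catch = r_catch, intro_step = as.integer(intro_step),
                 n_steps = as.integer(n_steps), n_runs = as.integer(n_runs)),
            class = "predator_config")
}

#' @export
print.predator_config <- function(x, ...) {
  cat(sprintf(
    "predator_config: speed factor %.2f, R_D = %.3g, R_C = %.3g,\n",
    x$speed_factor, x$r_detect, x$r_catch))
  cat(sprintf("  introduced at step %d of %d, %d runs\n",
              x$intro_step, x$n_steps, x$n_runs))
  invisible(x)
}

#' One predator pursuit step
#'
#' Moves the predator a distance `speed_factor * v0 * dt` along the
#' minimum-image direction to the nearest alive agent. If the predator sits
#' exactly on that agent the direction is undefined and it holds position.
#'
#' @param pred_pos length-2 predator position.
#' @param state a `swarm_state`.
#' @param v0 agent speed.
#' @param speed_factor predator speed multiplier.
#' @param L box side.
#' @param dt timestep.
#' @return the new predator position, wrapped into the box.
#' @export
predator_step <- function(pred_pos, state, v0, speed_factor, L, dt = 1) {
  al <- which(state$alive)
  if (length(al) == 0) stop("no alive agents: run over")
  d <- periodic_distance(matrix(pred_pos, length(al), 2, byrow = TRUE),
                         state$pos[al, , drop = FALSE], L)
  i <- al[which.min(d)]
  dmin <- min(d)
  if (dmin == 0) return(pred_pos)
  dir <- periodic_displacement(pred_pos, state$pos[i, ], L) / dmin
  (pred_pos + speed_factor * v0 * dt * dir) %% L
}

#' Fleeing-heading overrides near a predator
#'
#' Every alive agent strictly within `r_detect` of the predator replaces its
#' velocity with `v0` times the unit vector pointing away from the predator;
#' this takes precedence over the alignment update, and the overridden
#' heading is what neighbors align to. An agent exactly at the predator
#' position keeps its previous heading.
#'
#' @param state a `swarm_state`.
#' @param pred_pos length-2 predator position.
#' @param r_detect danger-detection radius (strict `<`).
#' @param L box side.
#' @return list with `fleeing` (logical per agent) and `theta` (headings
#'   with the overrides applied).
#' @export
flee_override <- function(state, pred_pos, r_detect, L) {
  n <- nrow(state$pos)
  d <- periodic_distance(matrix(pred_pos, n, 2, byrow = TRUE), state$pos, L)
  fleeing <- state$alive & d < r_detect
  theta <- state$theta
  idx <- which(fleeing & d > 0)
  if (length(idx)) {
    disp <- periodic_displacement(matrix(pred_pos, length(idx), 2,
                                         byrow = TRUE),
                                  state$pos[idx, , drop = FALSE], L)
    theta[idx] <- atan2(disp[, 2], disp[, 1])
  }
  list(fleeing = fleeing, theta = theta)
}

#' Remove caught agents
#'
#' Marks every alive agent strictly within `r_catch` of the predator as
#' dead; all such agents share the same catch iteration.
#'
#' @param state a `swarm_state`.
#' @param pred_pos length-2 predator position.
#' @param r_catch catch radius.
#' @param L box side.
#' @return list with `state` (updated) and `catches` (data.frame `t`, `id`;
#'   zero rows if nothing was caught).
#' @export
catch_and_remove <- function(state, pred_pos, r_catch, L) {
  n <- nrow(state$pos)
  d <- periodic_distance(matrix(pred_pos, n, 2, byrow = TRUE), state$pos, L)
  hit <- which(state$alive & d < r_catch)
  state$alive[hit] <- FALSE
  list(state = state,
       catches = data.frame(t = rep(state$t, length(hit)), id = hit))
}

#' Single predator-attack run
#'
#' Runs the Vicsek dynamics for `n_steps` iterations; after `intro_step` a
#' predator appears at a uniformly random position and hunts as described in
#' [predator_config()]. Returns the ordered catch log.
#'
#' @param config a [swarm_config()] (its seed, if set, seeds the run).
#' @param pred a [predator_config()].
#' @return an object of class `"catch_log"`: list with `catch_times`
#'   (ordered iteration indices), `catch_ids`, `survivors`, `mean_degree`
#'   (neighbors excluding self, averaged over alive agents and all
#'   iterations) and `intro_step`.
#' @export
run_predator <- function(config, pred) {
  state <- init_swarm(config)
  res <- cpp_run_predator(state$pos, state$theta, state$alive,
                          config$box_length, config$speed, config$dt,
                          config$eta, config$mode == "topological",
                          if (is.na(config$k)) 0L else config$k,
                          if (is.na(config$radius)) 0 else config$radius,
                          pred$speed_factor, pred$r_detect, pred$r_catch,
                          pred$intro_step, pred$n_steps)
  structure(list(catch_times = res$catch_times, catch_ids = res$catch_ids,
                 survivors = res$survivors, mean_degree = res$mean_degree,
                 intro_step = pred$intro_step, n_agents = config$n_agents),
            class = "catch_log")
}

#' @export
print.catch_log <- function(x, ...) {
  cat(sprintf("catch_log: %d catches, %d survivors (of %d)\n",
              length(x$catch_times), x$survivors, x$n_agents))
  invisible(x)
}

#' Mean avoidance time from catch logs
#'
#' Pools the intervals between consecutive catches within each run across
#' all runs and returns their mean and full distribution. The interval from
#' predator introduction to the first catch is excluded; simultaneous
#' catches contribute zero-length intervals.
#'
#' @param logs a `catch_log` or list of them.
#' @return list with `mean`, `intervals` (integer vector) and `n_intervals`.
#' @export
avoidance_time <- function(logs) {
  if (inherits(logs, "catch_log")) logs <- list(logs)
  intervals <- unlist(lapply(logs, function(lg) diff(lg$catch_times)))
  if (length(intervals) == 0)
    stop("no run has two or more catches; extend n_steps or n_runs")
  list(mean = mean(intervals), intervals = intervals,
       n_intervals = length(intervals))
}

#' Avoidance time versus connectivity
#'
#' For each interaction level (topological outdegree or metric radius) runs
#' `pred$n_runs` independent predator simulations with fresh initial
#' conditions and derived seeds, and tabulates the mean avoidance time. In
#' metric mode the realized mean degree (averaged over alive agents and all
#' iterations) is reported alongside the radius.
#'
#' @param base_config a `swarm_config` supplying everything but the
#'   interaction level; its seed is the master seed for the per-run seed
#'   derivation (see [derive_seeds()]).
#' @param pred a [predator_config()].
#' @param k_grid integer outdegrees, or `NULL`.
#' @param radius_grid metric radii, or `NULL`; exactly one grid must be
#'   given.
#' @return data.frame with columns `k` (imposed or realized mean degree),
#'   `radius` (metric mode only), `mean_avoidance_time`, `se`,
#'   `n_intervals`, `n_catches`.
#' @export
predator_experiment <- function(base_config, pred, k_grid = NULL,
                                radius_grid = NULL) {
  stopifnot(xor(is.null(k_grid), is.null(radius_grid)))
  grid <- if (is.null(k_grid)) radius_grid else k_grid
  master <- if (is.null(base_config$seed)) 1L else base_config$seed
  out <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    cfg <- base_config
    if (is.null(k_grid)) {
      cfg$mode <- "metric"
      cfg$radius <- grid[i]
    } else {
      cfg$mode <- "topological"
      cfg$k <- as.integer(grid[i])
    }
    seeds <- derive_seeds(master, pred$n_runs, stream = i)
    logs <- vector("list", pred$n_runs)
    for (r in seq_len(pred$n_runs)) {
      cfg$seed <- seeds[r]
      logs[[r]] <- run_predator(cfg, pred)
    }
    at <- avoidance_time(logs)
    mean_deg <- mean(vapply(logs, function(lg) lg$mean_degree, 0))
    out[[i]] <- data.frame(
      k = if (is.null(k_grid)) mean_deg else grid[i],
      radius = if (is.null(k_grid)) grid[i] else NA_real_,
      mean_avoidance_time = at$mean,
      se = stats::sd(at$intervals) / sqrt(at$n_intervals),
      n_intervals = at$n_intervals,
      n_catches = sum(vapply(logs, function(lg) length(lg$catch_times), 0L)))
  }
  do.call(rbind, out)
}
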