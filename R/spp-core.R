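#' Configuration of a Vicsek swarm
#'
#' Bundles the parameters of the discrete-time Vicsek model: `N` agents move
#' at constant speed `v0` in a periodic square box of side `L` and align
#' their heading to the mean orientation of their neighbors (self included),
#' with angular noise uniform in `[-pi*eta, pi*eta]` radians. Neighbors are
#' either all agents within a radius (`mode = "metric"`) or the `k` nearest
#' agents (`mode = "topological"`).
#'
#' If `box_length` is omitted it is chosen so that the number density
#' `N / L^2` equals 2, the package's reference density.
#'
#' @param n_agents number of agents (N >= 1).
#' @param mode `"topological"` (k nearest neighbors) or `"metric"` (radius).
#' @param k outdegree for topological interactions (k >= 0).
#' @param radius interaction radius for metric interactions (> 0).
#' @param box_length side of the periodic box; default `sqrt(n_agents / 2)`.
#' @param speed agent speed v0 in length units per step; default 0.05. At
#'   the reference density this is a few percent of the interaction range
#'   per step (the classic Vicsek speed regime), so neighbor graphs evolve
#'   smoothly and heading information propagates much faster than the
#'   agents themselves move.
#' @param dt timestep; default 1 (iteration units).
#' @param eta noise amplitude in `[0, 1]`; the heading perturbation is
#'   `2*pi*u` with `u ~ Uniform(-eta/2, eta/2)`. Default 0.05, deep in the
#'   ordered phase.
#' @param seed optional integer seed recorded in the config; [init_swarm()]
#'   and the runners call `set.seed(seed)` when it is non-`NULL`.
#' @return an object of class `"swarm_config"`.
#' @examples
#' cfg <- swarm_config(64, mode = "topological", k = 6, seed = 1)
#' st <- init_swarm(cfg)
#' order_parameter(st)
#' @export
swarm_config <- function(n_agents, mode = c("topological", "metric"),
                         k = NULL, radius = NULL, box_length = NULL,
                         speed = 0.05, dt = 1, eta = 0.05, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_agents >= 1, speed >= 0, dt > 0, eta >= 0, eta <= 1)
  if (is.null(box_length)) box_length <- sqrt(n_agents / 2)
  stopifnot(box_length > 0)
  if (mode == "topological") {
    if (is.null(k)) stop("topological mode requires `k`")
    stopifnot(k >= 0)
  } else {
    if (is.null(radius)) stop("metric mode requires `radius`")
    stopifnot(radius > 0)
  }
  structure(
    list(n_agents = as.integer(n_agents), box_length = box_length,
         speed = speed, dt = dt, eta = eta, mode = mode,
         k = if (is.null(k)) NA_integer_ else as.integer(k),
         radius = if (is.null(radius)) NA_real_ else radius,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "swarm_config")
}

#' @export
print.swarm_config <- function(x, ...) {
  cat("Vicsek swarm configuration\n")
  cat(sprintf("  N = %d, L = %.4g (density %.3g), v0 = %g, dt = %g, eta = %g\n",
              x$n_agents, x$box_length, x$n_agents / x$box_length^2,
              x$speed, x$dt, x$eta))
  if (x$mode == "topological")
    cat(sprintf("  interaction: topological, k = %d\n", x$k))
  else
    cat(sprintf("  interaction: metric, radius = %g\n", x$radius))
  invisible(x)
}

new_swarm_state <- function(t, pos, theta, alive) {
  structure(list(t = as.integer(t), pos = pos, theta = theta, alive = alive),
            class = "swarm_state")
}

#' Random initial swarm state
#'
#' Positions uniform in the box, headings uniform in `(-pi, pi]`, all agents
#' alive. Uses `config$seed` (if set) through `set.seed()`.
#'
#' @param config a [swarm_config()].
#' @return an object of class `"swarm_state"` with fields `t`, `pos`
#'   (N x 2 matrix in `[0, L)^2`), `theta` (headings in `(-pi, pi]`) and
#'   `alive` (logical).
#' @export
init_swarm <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_agents
  L <- config$box_length
  pos <- cbind(runif(n, 0, L), runif(n, 0, L))
  theta <- pi - runif(n, 0, 2 * pi)     # uniform on (-pi, pi]
  new_swarm_state(0L, pos, theta, rep(TRUE, n))
}

#' @export
print.swarm_state <- function(x, ...) {
  cat(sprintf("swarm_state: t = %d, %d/%d alive, order parameter %.4f\n",
              x$t, sum(x$alive), length(x$alive),
              order_parameter(x)))
  invisible(x)
}

#' Minimum-image displacement in a periodic box
#'
#' Displacement `b - a` with each component mapped into `[-L/2, L/2)`; its
#' Euclidean norm is the distance used by every neighbor and
#' predator-detection rule in the package.
#'
#' @param a,b points in `[0, L)^2` (length-2 vectors or n x 2 matrices).
#' @param L box side length.
#' @return displacement with the same shape as the inputs.
#' @examples
#' periodic_displacement(c(0.5, 0), c(9.5, 0), 10)  # c(-1, 0)
#' @export
periodic_displacement <- function(a, b, L) {
  d <- (b - a) %% L
  d - L * (d >= L / 2)
}

#' Periodic (minimum-image) distance
#' @inheritParams periodic_displacement
#' @return Euclidean norm(s) of the minimum-image displacement.
#' @export
periodic_distance <- function(a, b, L) {
  d <- periodic_displacement(a, b, L)
  if (is.matrix(d)) sqrt(rowSums(d^2)) else sqrt(sum(d^2))
}

#' Neighbor lists of a swarm state
#'
#' For every alive agent, the indices of its interaction partners, self
#' always included. Metric mode: all alive agents within `config$radius`
#' (periodic distance, inclusive). Topological mode: the `k` nearest alive
#' agents, ties at the cutoff distance broken toward the lower index; if
#' fewer than `k` other agents are alive, all of them. Dead agents get an
#' empty list and never appear in anyone's list.
#'
#' @param state a `swarm_state`.
#' @param config a `swarm_config`.
#' @return list of integer vectors (sorted ascending), one per agent.
#' @export
find_neighbors <- function(state, config) {
  cpp_neighbor_lists(state$pos, state$theta, state$alive,
                     config$box_length,
                     config$mode == "topological",
                     if (is.na(config$k)) 0L else config$k,
                     if (is.na(config$radius)) 0 else config$radius)
}

#' One synchronous Vicsek update
#'
#' Headings update to the orientation of the summed neighbor velocities
#' (self included) plus angular noise `2*pi*u`, `u ~ Uniform(-eta/2,
#' eta/2)`; positions advance one step with the pre-update velocities; both
#' updates read the same time-t snapshot. If an agent's neighbor velocity
#' sum vanishes its heading is kept. Noise is drawn from R's RNG stream
#' (one draw per alive agent, in index order) so `set.seed()` makes steps
#' reproducible.
#'
#' @inheritParams find_neighbors
#' @return the updated `swarm_state` (t advanced by one).
#' @export
vicsek_step <- function(state, config) {
  res <- cpp_vicsek_step(state$pos, state$theta, state$alive,
                         config$box_length, config$speed, config$dt,
                         config$eta, config$mode == "topological",
                         if (is.na(config$k)) 0L else config$k,
                         if (is.na(config$radius)) 0 else config$radius)
  new_swarm_state(state$t + 1L, res$pos, res$theta, state$alive)
}

#' Polar order parameter
#'
#' `||mean velocity|| / v0` over alive agents: 1 for perfect alignment, near
#' 0 for isotropic headings. Speed cancels, so the value depends only on the
#' headings.
#'
#' @param state a `swarm_state`.
#' @return a number in `[0, 1]`.
#' @export
order_parameter <- function(state) {
  th <- state$theta[state$alive]
  sqrt(mean(cos(th))^2 + mean(sin(th))^2)
}

#' Run the Vicsek dynamics
#'
#' Advances `n_steps` synchronous updates, optionally recording snapshots.
#'
#' @inheritParams find_neighbors
#' @param n_steps number of iterations.
#' @param sample_every if non-`NULL`, record the state every this many steps
#'   after `burn_in`.
#' @param burn_in steps discarded before sampling starts (default 0).
#' @param state optional starting state; default [init_swarm()] on `config`
#'   (which applies `config$seed`).
#' @return list with `state` (final `swarm_state`), `samples` (list of
#'   `swarm_state` snapshots, possibly empty) and `sample_steps`.
#' @export
run_swarm <- function(config, n_steps, sample_every = NULL, burn_in = 0,
                      state = NULL) {
  if (is.null(state)) state <- init_swarm(config)
  sample_steps <- integer(0)
  if (!is.null(sample_every) && sample_every >= 1) {
    sample_steps <- seq.int(burn_in + sample_every, n_steps,
                            by = sample_every)
    sample_steps <- sample_steps[sample_steps >= state$t + 1]
  }
  res <- cpp_run_swarm(state$pos, state$theta, state$alive,
                       config$box_length, config$speed, config$dt,
                       config$eta, config$mode == "topological",
                       if (is.na(config$k)) 0L else config$k,
                       if (is.na(config$radius)) 0 else config$radius,
                       as.integer(n_steps - state$t),
                       as.integer(sample_steps - state$t))
  samples <- Map(function(p, th, tt) new_swarm_state(tt, p, th, state$alive),
                 res$sample_pos, res$sample_theta, as.list(sample_steps))
  list(state = new_swarm_state(n_steps, res$pos, res$theta, state$alive),
       samples = samples, sample_steps = sample_steps)
}

#' Write sampled frames as a trajectory CSV
#'
#' One row per agent per frame, columns `t, id, x, y, theta, alive`.
#'
#' @param samples list of `swarm_state` objects.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trajectory <- function(samples, path) {
  rows <- lapply(samples, function(s) {
    data.frame(t = s$t, id = seq_along(s$theta), x = s$pos[, 1],
               y = s$pos[, 2], theta = s$theta, alive = s$alive)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
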