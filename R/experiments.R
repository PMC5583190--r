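#' Counter-based seed derivation
#'
#' Derives per-run seeds from a master seed so that adding runs or grid
#' points never reshuffles earlier ones: seed of run `r` in stream `s` is
#' `(master + 1000003 * s + 7919 * r) mod (2^31 - 1)`, kept strictly
#' positive. Every source of randomness in the package's experiment runners
#' is seeded through this function.
#'
#' @param master master seed (integer).
#' @param n number of seeds to derive.
#' @param stream stream index (e.g. the grid-point counter; default 0).
#' @return integer vector of `n` seeds.
#' @export
derive_seeds <- function(master, n, stream = 0) {
  m <- 2147483647
  base <- (as.numeric(master) %% m + 1000003 * as.numeric(stream)) %% m
  as.integer((base + 7919 * seq_len(n)) %% m + 1)
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values are parsed
#' as numbers where possible. Recognized keys for simulation runs:
#' `n_agents, box_length, speed, dt, eta, mode, k, radius, seed, n_steps,
#' sample_every, burn_in`.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 0L) != 2
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  vals <- lapply(kv, function(p) {
    v <- p[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  setNames(vals, vapply(kv, `[`, "", 1))
}

#' Swarm config from a key-value list
#'
#' @param conf named list as returned by [read_config()].
#' @return a [swarm_config()].
#' @export
config_from_list <- function(conf) {
  swarm_config(
    n_agents = conf$n_agents,
    mode = if (is.null(conf$mode)) "topological" else conf$mode,
    k = conf$k, radius = conf$radius, box_length = conf$box_length,
    speed = if (is.null(conf$speed)) 0.05 else conf$speed,
    dt = if (is.null(conf$dt)) 1 else conf$dt,
    eta = if (is.null(conf$eta)) 0.05 else conf$eta,
    seed = conf$seed)
}

#' Experiment presets
#'
#' Named parameter bundles for the package's standard experiments, at full
#' scale and at desk scale (suffix `-small`). Each preset fully determines
#' an experiment given a master seed.
#'
#' @return named list of preset descriptions.
#' @export
experiment_presets <- function() {
  list(
    `chi-sweep` = list(
      kind = "chi_sweep", n_agents = 2048, k_grid = seq(2, 40, 2),
      n_steps = 2e6, sample_every = 5e3, burn_in = 5e4,
      note = "full-scale susceptibility vs outdegree (hours)"),
    `chi-sweep-small` = list(
      kind = "chi_sweep", n_agents = 512, k_grid = c(2, 8, 16, 28, 40),
      n_steps = 1e5, sample_every = 1e3, burn_in = 2e4,
      note = "desk-scale susceptibility vs outdegree"),
    `predator-sweep` = list(
      kind = "predator_sweep", n_agents = 2048, k_grid = seq(0, 40, 4),
      n_runs = 500, n_steps = 5000, intro_step = 2000,
      note = "full-scale avoidance time vs outdegree (hours)"),
    `predator-sweep-small` = list(
      kind = "predator_sweep", n_agents = 512, k_grid = seq(0, 40, 4),
      n_runs = 100, n_steps = 1000, intro_step = 300,
      note = "desk-scale avoidance time vs outdegree"),
    `threshold-sweep` = list(
      kind = "threshold_sweep", n = 2048, k_grid = seq(2, 40, 2),
      theta = 0.5, informed_fraction = 0.36, n_realizations = 50,
      note = "polarization speed vs outdegree, both wirings"),
    `threshold-sweep-small` = list(
      kind = "threshold_sweep", n = 256, k_grid = seq(2, 20, 2),
      theta = 0.5, informed_fraction = 0.36, n_realizations = 20,
      note = "desk-scale polarization speed sweep"),
    `gain-sweep` = list(
      kind = "gain_sweep", n = 2048, k_grid = seq(2, 64, 2),
      omegas = 10^seq(-2, 2, length.out = 17),
      note = "leader-follower gain over k and omega"),
    `gain-sweep-small` = list(
      kind = "gain_sweep", n = 128, k_grid = seq(2, 32, 2),
      omegas = 10^seq(-2, 2, length.out = 9),
      note = "desk-scale gain sweep"))
}

#' Run a preset experiment
#'
#' Dispatches a named preset to the module runners, writes the result table
#' as CSV plus a JSON manifest (preset, parameters, master seed, package
#' version, timestamp) alongside, and returns the result invisibly. A
#' manifest plus this package version fully determines the outputs.
#'
#' @param preset preset name (see [experiment_presets()]).
#' @param seed master seed.
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing.
#' @param overwrite allow overwriting existing outputs (default FALSE).
#' @return the result data.frame, invisibly.
#' @export
run_experiment <- function(preset, seed = 1, out_dir = NULL,
                           overwrite = FALSE) {
  presets <- experiment_presets()
  if (!preset %in% names(presets))
    stop("unknown experiment: ", preset, "; see experiment_presets()")
  p <- presets[[preset]]
  if (grepl("full-scale", p$note))
    message("note: ", preset, " is a full-scale preset (", p$note, ")")
  res <- switch(
    p$kind,
    chi_sweep = {
      cfg <- swarm_config(p$n_agents, mode = "topological", k = 2,
                          seed = seed)
      susceptibility_sweep(cfg, k_grid = p$k_grid, n_steps = p$n_steps,
                           sample_every = p$sample_every,
                           burn_in = p$burn_in)
    },
    predator_sweep = {
      cfg <- swarm_config(p$n_agents, mode = "topological", k = 2,
                          seed = seed)
      pc <- predator_config(cfg, intro_step = p$intro_step,
                            n_steps = p$n_steps, n_runs = p$n_runs)
      predator_experiment(cfg, pc, k_grid = p$k_grid)
    },
    threshold_sweep = threshold_k_sweep(
      n = p$n, k_grid = p$k_grid, theta = p$theta,
      informed_fraction = p$informed_fraction,
      n_realizations = p$n_realizations, seed = seed),
    gain_sweep = gain_sweep(p$n, p$k_grid, p$omegas))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    csv <- file.path(out_dir, paste0(preset, ".csv"))
    man <- file.path(out_dir, paste0(preset, "-manifest.json"))
    if (!overwrite && (file.exists(csv) || file.exists(man)))
      stop("output exists; pass overwrite = TRUE to replace it")
    write.csv(res, csv, row.names = FALSE)
    manifest <- list(
      experiment = preset, parameters = p[setdiff(names(p), "note")],
      master_seed = seed,
      package_version = as.character(utils::packageVersion("swarmresp")),
      timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, man, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(res)
}
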