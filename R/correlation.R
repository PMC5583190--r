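#' Dimensionless velocity fluctuations
#'
#' For each alive agent, `dphi_i = (v_i - <v>) / sqrt(sum_k ||v_k - <v>||^2
#' / N)`, with `<v>` the arithmetic mean velocity over the `N` alive agents.
#' By construction the fluctuations sum to the zero vector and their squared
#' norms sum to `N`.
#'
#' @param state a `swarm_state`.
#' @param v0 agent speed used to form velocities from headings.
#' @return an object of class `"fluctuation_field"`: an N x 2 matrix
#'   `delta_phi` (rows of dead agents are `NA`) plus the normalization.
#' @export
velocity_fluctuations <- function(state, v0) {
  al <- state$alive
  if (sum(al) < 2) stop("need at least 2 alive agents")
  v <- v0 * cbind(cos(state$theta), sin(state$theta))
  vb <- colMeans(v[al, , drop = FALSE])
  dv <- sweep(v, 2, vb)
  norm2 <- sum(dv[al, ]^2) / sum(al)
  if (norm2 <= 0 || !is.finite(1 / norm2))
    stop("degenerate snapshot: all velocities identical, no fluctuation signal")
  dphi <- dv / sqrt(norm2)
  dphi[!al, ] <- NA_real_
  structure(list(delta_phi = dphi, alive = al, norm = sqrt(norm2)),
            class = "fluctuation_field")
}

#' Connected correlation of velocity fluctuations
#'
#' Binned estimate of C(r): the average of `dphi_i . dphi_j` over ordered
#' pairs `i != j` whose periodic minimum-image distance falls in each bin
#' `[edge_b, edge_{b+1})`. Empty bins are `NA`, not zero. The curve also
#' carries the cumulative pair-sum `sum_{i != j, r_ij < r0} dphi_i .
#' dphi_j / N` evaluated at the bin edges, and (by default) the raw pair
#' distances and products for the exact, un-binned cumulative used by
#' [susceptibility()].
#'
#' @param fluct a [velocity_fluctuations()] result.
#' @param state the `swarm_state` the fluctuations came from.
#' @param L box side length.
#' @param bin_width histogram bin width; default `L / 200`.
#' @param keep_pairs keep the raw pair list (exact chi); disable for large N
#'   to save memory.
#' @return an object of class `"correlation_curve"` with `bin_edges`,
#'   `c_of_r`, `pair_counts`, `cumulative` (at the right edges) and
#'   optionally `pair_dist`, `pair_prod`.
#' @export
connected_correlation <- function(fluct, state, L, bin_width = L / 200,
                                  keep_pairs = TRUE) {
  stopifnot(bin_width > 0)
  n_alive <- sum(state$alive)
  if (n_alive < 2) stop("need at least 2 alive agents")
  rmax <- L / sqrt(2)                    # largest minimum-image distance
  edges <- seq(0, rmax + bin_width, by = bin_width)
  dphi <- fluct$delta_phi
  dphi[!state$alive, ] <- 0
  h <- cpp_pair_hist(state$pos, state$alive, dphi, L, edges)
  c_of_r <- ifelse(h$count > 0, h$sum / h$count, NA_real_)
  curve <- list(bin_edges = edges, c_of_r = c_of_r, pair_counts = h$count,
                cumulative = cumsum(h$sum) / n_alive, n_alive = n_alive)
  if (keep_pairs) {
    pl <- cpp_pair_list(state$pos, state$alive, dphi, L)
    o <- order(pl$dist)
    curve$pair_dist <- pl$dist[o]
    curve$pair_prod <- pl$prod[o]
  }
  structure(curve, class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  occ <- sum(x$pair_counts > 0)
  cat(sprintf(
    "correlation_curve: %d agents, %d/%d occupied bins, bin width %.4g\n",
    x$n_alive, occ, length(x$c_of_r), diff(x$bin_edges[1:2])))
  cat(sprintf("  final cumulative = %.6f (identity: -1)\n",
              x$cumulative[length(x$cumulative)]))
  invisible(x)
}

#' Integrated correlation (susceptibility)
#'
#' `chi = max over r0 of sum_{i != j, r_ij < r0} dphi_i . dphi_j / N`. When
#' the curve retains its raw pair list the cumulative is evaluated exactly
#' at every pair distance (no binning error); otherwise the maximum is taken
#' over the binned cumulative at the bin edges. The trivial prefix `r0 = 0`
#' (cumulative 0) is not a candidate, so an all-negative cumulative yields
#' its least-negative value.
#'
#' @param curve a [connected_correlation()] result.
#' @return an object of class `"susceptibility"`: list with `chi` and
#'   `argmax_r0`.
#' @export
susceptibility <- function(curve) {
  if (!is.null(curve$pair_dist)) {
    # ordered-pair cumulative: each unordered pair counts twice
    cum <- cumsum(2 * curve$pair_prod) / curve$n_alive
    i <- which.max(cum)
    res <- list(chi = cum[i], argmax_r0 = curve$pair_dist[i])
  } else {
    cum <- curve$cumulative
    i <- which.max(cum)
    res <- list(chi = cum[i], argmax_r0 = curve$bin_edges[i + 1])
  }
  structure(res, class = "susceptibility")
}

#' @export
print.susceptibility <- function(x, ...) {
  cat(sprintf("susceptibility: chi = %.5g at r0 = %.5g\n",
              x$chi, x$argmax_r0))
  invisible(x)
}

#' Correlation sampling protocol over a swarm run
#'
#' Runs the Vicsek dynamics, computes the pair-correlation histogram every
#' `sample_every` iterations after a `burn_in` transient, averages the
#' histograms, and evaluates chi from the averaged cumulative (histograms
#' are averaged first, then the maximum is taken). Reference (full-scale)
#' values are `sample_every = 5e3`, `n_steps = 2e6`, `burn_in = 5e4`; all
#' three scale down. Degenerate snapshots with zero velocity fluctuation
#' are skipped with a warning.
#'
#' @inheritParams run_swarm
#' @param bin_width histogram bin width; default `L / 200`.
#' @return list with `curve` (averaged `correlation_curve`), `chi` (a
#'   `susceptibility` computed from the averaged cumulative), `n_samples`
#'   and `n_skipped`.
#' @export
correlation_protocol <- function(config, n_steps = 2e6, sample_every = 5e3,
                                 burn_in = 5e4,
                                 bin_width = config$box_length / 200) {
  stopifnot(n_steps > burn_in)
  run <- run_swarm(config, n_steps, sample_every = sample_every,
                   burn_in = burn_in)
  L <- config$box_length
  rmax <- L / sqrt(2)
  edges <- seq(0, rmax + bin_width, by = bin_width)
  acc_sum <- numeric(length(edges) - 1)
  acc_cnt <- numeric(length(edges) - 1)
  n_used <- 0L
  n_skip <- 0L
  for (s in run$samples) {
    fl <- tryCatch(velocity_fluctuations(s, config$speed),
                   error = function(e) NULL)
    if (is.null(fl)) {
      n_skip <- n_skip + 1L
      next
    }
    dphi <- fl$delta_phi
    dphi[!s$alive, ] <- 0
    h <- cpp_pair_hist(s$pos, s$alive, dphi, L, edges)
    acc_sum <- acc_sum + h$sum
    acc_cnt <- acc_cnt + h$count
    n_used <- n_used + 1L
  }
  if (n_skip > 0)
    warning(sprintf("%d degenerate (zero-fluctuation) snapshots skipped",
                    n_skip))
  if (n_used == 0) stop("no usable snapshots; extend n_steps or add noise")
  n_alive <- sum(run$state$alive)
  curve <- structure(
    list(bin_edges = edges,
         c_of_r = ifelse(acc_cnt > 0, acc_sum / acc_cnt, NA_real_),
         pair_counts = acc_cnt / n_used,
         cumulative = cumsum(acc_sum / n_used) / n_alive,
         n_alive = n_alive),
    class = "correlation_curve")
  list(curve = curve, chi = susceptibility(curve), n_samples = n_used,
       n_skipped = n_skip)
}

#' Susceptibility as a function of the outdegree
#'
#' Repeats [correlation_protocol()] over a grid of interaction levels
#' (topological `k` or metric `radius`) and tabulates chi.
#'
#' @param base_config a `swarm_config` supplying everything but the
#'   interaction level; its seed (if any) seeds each grid point as
#'   `seed + index`.
#' @param k_grid integer outdegrees (topological mode), or `NULL`.
#' @param radius_grid metric radii, or `NULL`; exactly one grid must be
#'   given.
#' @inheritParams correlation_protocol
#' @return data.frame with columns `k` (or `radius`), `chi`, `argmax_r0`,
#'   `n_samples`.
#' @export
susceptibility_sweep <- function(base_config, k_grid = NULL,
                                 radius_grid = NULL, n_steps = 2e6,
                                 sample_every = 5e3, burn_in = 5e4) {
  stopifnot(xor(is.null(k_grid), is.null(radius_grid)))
  grid <- if (is.null(k_grid)) radius_grid else k_grid
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
    if (!is.null(base_config$seed)) cfg$seed <- base_config$seed + i
    res <- correlation_protocol(cfg, n_steps, sample_every, burn_in)
    out[[i]] <- data.frame(level = grid[i], chi = res$chi$chi,
                           argmax_r0 = res$chi$argmax_r0,
                           n_samples = res$n_samples)
  }
  tab <- do.call(rbind, out)
  names(tab)[1] <- if (is.null(k_grid)) "radius" else "k"
  tab
}
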