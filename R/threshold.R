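#' Random directed network with fixed outdegree
#'
#' Each node observes exactly `k` out-neighbors drawn uniformly without
#' replacement from the other `N - 1` nodes; no self-loops, no duplicate
#' edges. Out-neighbors are the nodes a node OBSERVES, so a fixed outdegree
#' means a fixed information intake.
#'
#' @param n number of nodes.
#' @param k outdegree, `1 <= k <= n - 1`.
#' @return an object of class `"threshold_network"`: list with `n`, `adj`
#'   (n x n sparse 0/1 matrix, `adj[i, j] = 1` iff i observes j),
#'   `out_degree`, `kind`, `directed`.
#' @export
build_random_fixed_outdegree <- function(n, k) {
  stopifnot(n >= 2, k >= 1)
  if (k >= n) stop("k must be at most n - 1")
  targets <- vapply(seq_len(n), function(i) {
    others <- seq_len(n)[-i]
    others[sample.int(n - 1L, k)]
  }, integer(k))
  # targets is k x n: column i holds i's out-neighbors
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                              j = as.integer(targets),
                              x = 1, dims = c(n, n))
  structure(list(n = as.integer(n), adj = adj,
                 out_degree = rep(as.integer(k), n),
                 kind = "random-fixed-outdegree", directed = TRUE,
                 k = as.integer(k)),
            class = "threshold_network")
}

#' Undirected ring lattice with k-nearest-neighbor connectivity
#'
#' Node `i` is adjacent to `i - k/2, ..., i - 1, i + 1, ..., i + k/2`
#' (mod n): `k/2` neighbors on each side, so `k` must be even. Observation
#' lists are symmetric.
#'
#' @param n number of nodes.
#' @param k even connectivity, `k < n`.
#' @return a `"threshold_network"` (see [build_random_fixed_outdegree()]).
#' @export
build_ring_lattice <- function(n, k) {
  stopifnot(n >= 3, k >= 2)
  if (k %% 2 != 0) stop("ring lattice needs even k (k/2 neighbors per side)")
  if (k >= n) stop("k must be less than n")
  offs <- c(seq_len(k / 2), -seq_len(k / 2))
  i <- rep(seq_len(n), times = length(offs))
  j <- ((rep(seq_len(n), times = length(offs)) - 1 +
           rep(offs, each = n)) %% n) + 1
  adj <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  structure(list(n = as.integer(n), adj = adj,
                 out_degree = rep(as.integer(k), n),
                 kind = "ring-lattice", directed = FALSE,
                 k = as.integer(k)),
            class = "threshold_network")
}

#' @export
print.threshold_network <- function(x, ...) {
  cat(sprintf("threshold_network: %s, n = %d, k = %d (%s)\n",
              x$kind, x$n, x$k,
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' One synchronous linear-threshold update
#'
#' For every non-informed node `i`, the next state is 1 if the mean of its
#' out-neighbors' current states strictly exceeds `theta`, else 0 (self
#' excluded from the average). Informed nodes stay pinned at 1.
#'
#' @param network a `threshold_network`; every node must have at least one
#'   out-neighbor (guaranteed by the builders).
#' @param s binary state vector (0/1).
#' @param informed integer indices of pinned informed nodes.
#' @param theta threshold in (0, 1).
#' @return the updated 0/1 state vector.
#' @examples
#' net <- build_ring_lattice(6, 2)
#' s <- c(1, 0, 0, 1, 0, 0)
#' lt_step(net, s, informed = c(1, 4), theta = 0.4)
#' @export
lt_step <- function(network, s, informed, theta) {
  stopifnot(length(s) == network$n, theta > 0, theta < 1)
  frac <- as.numeric(network$adj %*% s) / network$out_degree
  s_new <- as.numeric(frac > theta)
  s_new[informed] <- 1
  s_new
}

#' Polarization trajectory and speed of the linear threshold model
#'
#' Starts from the all-zero ground state, pins a uniformly random informed
#' set of size `round(informed_fraction * n)` at state 1, and iterates
#' [lt_step()] synchronously. The polarization `P(t)` is the mean state.
#' The polarization speed is the mean rate `c = (1 - P(0)) / T`, with `T`
#' the first step at which `P = 1`. If full polarization is not reached the
#' dynamics is run until a state recurs (fixed point or cycle, detected by
#' hashing visited states) or `max_steps` is hit; then `c = 0` and
#' `absorbed = FALSE`. A `max_slope` estimator (largest single-step increase
#' of `P`) is reported alongside.
#'
#' @param network a `threshold_network`.
#' @param informed_fraction fraction of nodes pinned at 1 (default 0.36).
#' @param theta threshold (default 1/2).
#' @param max_steps iteration cap (default 10 * n).
#' @param informed optional explicit informed index set (overrides the
#'   fraction).
#' @return an object of class `"polarization_trace"`: list with `P`
#'   (polarization at t = 0, 1, ...), `T_absorb`, `c`, `c_max_slope`,
#'   `absorbed`, `cycle` (TRUE if a non-fixed-point recurrence was hit),
#'   `informed`.
#' @export
polarization_speed <- function(network, informed_fraction = 0.36,
                               theta = 0.5, max_steps = 10 * network$n,
                               informed = NULL) {
  n <- network$n
  if (is.null(informed)) {
    n_inf <- round(informed_fraction * n)
    informed <- sample.int(n, n_inf)
  }
  s <- numeric(n)
  s[informed] <- 1
  P <- mean(s)
  p0 <- P
  seen <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(s) paste(which(s > 0), collapse = ",")
  assign(key(s), TRUE, envir = seen)
  absorbed <- FALSE
  cycle <- FALSE
  T_absorb <- NA_integer_
  for (t in seq_len(max_steps)) {
    s <- lt_step(network, s, informed, theta)
    P <- c(P, mean(s))
    if (P[t + 1] == 1) {
      absorbed <- TRUE
      T_absorb <- t
      break
    }
    k <- key(s)
    if (!is.null(seen[[k]])) {  # revisited state: fixed point or cycle
      cycle <- sum(abs(s - lt_step(network, s, informed, theta))) > 0
      break
    }
    assign(k, TRUE, envir = seen)
  }
  if (p0 == 1) {  # degenerate: everything informed at t = 0
    absorbed <- TRUE
    T_absorb <- 0L
  }
  c_mean <- if (absorbed && !is.na(T_absorb) && T_absorb > 0)
    (1 - p0) / T_absorb else 0
  structure(list(P = P, T_absorb = T_absorb, c = c_mean,
                 c_max_slope = if (length(P) > 1) max(diff(P)) else 0,
                 absorbed = absorbed, cycle = cycle, informed = informed,
                 degenerate = p0 == 1),
            class = "polarization_trace")
}

#' @export
print.polarization_trace <- function(x, ...) {
  cat(sprintf(
    "polarization_trace: P0 = %.3f, %s, c = %.4f\n",
    x$P[1],
    if (x$absorbed) sprintf("absorbed at T = %d", x$T_absorb)
    else if (x$cycle) "cycle detected" else "stalled (fixed point)",
    x$c))
  invisible(x)
}

#' Polarization speed versus outdegree
#'
#' For each outdegree `k` and each network kind, averages the polarization
#' speed over `n_realizations` independent realizations (fresh network and
#' fresh informed set each) and locates the optimal outdegree `k*`.
#'
#' @param n number of nodes (default 2048).
#' @param k_grid outdegrees to scan (even values; default `seq(2, 40, 2)`).
#' @param theta threshold (default 1/2).
#' @param informed_fraction fraction pinned at 1 (default 0.36).
#' @param n_realizations realizations per (kind, k) (default 50).
#' @param kinds network kinds to include.
#' @param seed optional master seed; realization r of grid point i runs
#'   under [derive_seeds()] stream i.
#' @param estimator `"mean"` for `(1 - P(0)) / T` or `"max_slope"`.
#' @return data.frame with columns `kind`, `k`, `mean_c`, `se_c`, `n`,
#'   `n_absorbed`; attribute `k_star` is a named vector of per-kind argmax.
#' @export
threshold_k_sweep <- function(n = 2048, k_grid = seq(2, 40, by = 2),
                              theta = 0.5, informed_fraction = 0.36,
                              n_realizations = 50,
                              kinds = c("random-fixed-outdegree",
                                        "ring-lattice"),
                              seed = NULL,
                              estimator = c("mean", "max_slope")) {
  estimator <- match.arg(estimator)
  master <- if (is.null(seed)) 1L else as.integer(seed)
  out <- list()
  for (kind in kinds) {
    for (i in seq_along(k_grid)) {
      k <- k_grid[i]
      stream <- i + length(k_grid) * (match(kind, kinds) - 1)
      seeds <- derive_seeds(master, n_realizations, stream = stream)
      cs <- numeric(n_realizations)
      absorbed <- logical(n_realizations)
      for (r in seq_len(n_realizations)) {
        set.seed(seeds[r])
        net <- if (kind == "random-fixed-outdegree")
          build_random_fixed_outdegree(n, k)
        else build_ring_lattice(n, k)
        tr <- polarization_speed(net, informed_fraction, theta)
        cs[r] <- if (estimator == "mean") tr$c else tr$c_max_slope
        absorbed[r] <- tr$absorbed
      }
      out[[length(out) + 1]] <- data.frame(
        kind = kind, k = k, mean_c = mean(cs),
        se_c = stats::sd(cs) / sqrt(n_realizations),
        n = n_realizations, n_absorbed = sum(absorbed))
    }
  }
  tab <- do.call(rbind, out)
  k_star <- vapply(kinds, function(kd) {
    sub <- tab[tab$kind == kd, ]
    sub$k[which.max(sub$mean_c)]
  }, 0)
  attr(tab, "k_star") <- k_star
  tab
}
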