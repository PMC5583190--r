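#' Ring-lattice adjacency over N + 1 nodes
#'
#' Convenience builder for the leader-follower analyses: an undirected ring
#' of `n_nodes` sites, each adjacent to its `k` nearest sites (`k/2` per
#' side, `k` even).
#'
#' @param n_nodes total nodes (leader included).
#' @param k even connectivity.
#' @return a symmetric 0/1 adjacency matrix.
#' @export
ring_lattice_adjacency <- function(n_nodes, k) {
  stopifnot(k %% 2 == 0, k >= 2, k < n_nodes)
  offs <- c(seq_len(k / 2), -seq_len(k / 2))
  adj <- matrix(0, n_nodes, n_nodes)
  for (o in offs) {
    idx <- cbind(seq_len(n_nodes),
                 ((seq_len(n_nodes) - 1 + o) %% n_nodes) + 1)
    adj[idx] <- 1
  }
  adj
}

#' Leader-follower linear consensus system
#'
#' From an adjacency matrix over `N + 1` nodes and a designated leader,
#' builds the follower-block consensus matrix `W` with entries
#' `w_ij = omega0 * (a_ij / k_i - delta_ij)` and the leader-coupling vector
#' `W_l = {w_i0}`. The degree `k_i` counts ALL neighbors of follower `i`,
#' the leader included, so each row of `[W | W_l]` sums exactly to zero and
#' the diagonal of `W` is `-omega0`.
#'
#' @param adjacency square 0/1 matrix over all nodes (undirected graphs are
#'   symmetric; directed graphs are accepted, rows = observers).
#' @param leader index of the leader node (default 1).
#' @param omega0 natural response frequency of the agents (default 1; pure
#'   time scale).
#' @return an object of class `"consensus_system"`: list with `W` (N x N),
#'   `W_l` (length N), `omega0`, `n_followers`, `leader`, `undirected`.
#' @export
build_consensus_system <- function(adjacency, leader = 1, omega0 = 1) {
  adjacency <- as.matrix(adjacency)
  n_all <- nrow(adjacency)
  stopifnot(n_all == ncol(adjacency), n_all >= 2, omega0 > 0,
            leader >= 1, leader <= n_all)
  if (any(diag(adjacency) != 0)) stop("self-loops are not allowed")
  g <- igraph::graph_from_adjacency_matrix(
    adjacency, mode = if (isSymmetric(adjacency)) "undirected" else "directed")
  if (!igraph::is_connected(g, mode = "weak"))
    stop("graph is disconnected: consensus assumptions violated")
  if (sum(adjacency[, leader] > 0) == 0 && sum(adjacency[leader, ] > 0) == 0)
    stop("leader has no neighbors")
  fol <- setdiff(seq_len(n_all), leader)
  deg <- rowSums(adjacency)           # k_i counts all neighbors, leader incl.
  if (any(deg[fol] == 0))
    stop("isolated follower: consensus assumptions violated")
  W <- adjacency[fol, fol, drop = FALSE] / deg[fol]
  diag(W) <- diag(W) - 1
  W <- omega0 * W
  W_l <- omega0 * adjacency[fol, leader] / deg[fol]
  structure(list(W = W, W_l = W_l, omega0 = omega0,
                 n_followers = length(fol), leader = leader,
                 undirected = isSymmetric(adjacency)),
            class = "consensus_system")
}

#' @export
print.consensus_system <- function(x, ...) {
  cat(sprintf(
    "consensus_system: %d followers + 1 leader, omega0 = %g (%s graph)\n",
    x$n_followers, x$omega0,
    if (x$undirected) "undirected" else "directed"))
  invisible(x)
}

#' Exact frequency-domain gain of the leader-follower system
#'
#' Solves `H(omega) = (i omega I - W)^{-1} W_l` and returns the per-follower
#' complex response together with the squared gain
#' `H^2 = sum_i |h_i(omega)|^2`. At `omega = 0`, `H` is the all-ones vector
#' on any connected graph and `H^2` equals the follower count.
#'
#' @param system a [build_consensus_system()].
#' @param omega input (leader) angular frequency, real, >= 0.
#' @return list with `H` (complex vector) and `gain2`.
#' @export
transfer_gain <- function(system, omega) {
  stopifnot(length(omega) == 1, omega >= 0)
  A <- diag(complex(real = 0, imaginary = omega), system$n_followers) -
    system$W
  H <- tryCatch(solve(A, system$W_l), error = function(e)
    stop("singular frequency-response system: the graph must be connected ",
         "with every follower reachable from the leader"))
  list(H = H, gain2 = sum(Mod(H)^2))
}

#' Gain spectrum over a frequency grid
#'
#' @param system a `consensus_system`.
#' @param omegas frequencies; default log-spaced over
#'   `[1e-2, 1e2] * omega0` (four orders of magnitude).
#' @return data.frame with columns `omega`, `gain2`, `gain` (= sqrt).
#' @export
gain_spectrum <- function(system,
                          omegas = 10^seq(-2, 2, length.out = 41) *
                            system$omega0) {
  gain2 <- vapply(omegas, function(w) transfer_gain(system, w)$gain2, 0)
  data.frame(omega = omegas, gain2 = gain2, gain = sqrt(gain2))
}

#' Low-frequency expansion of the squared gain
#'
#' For undirected interaction networks the squared gain expands as
#' `H^2 = N - omega^2 * sum_ij (W^{-2})_ij + O(omega^4)`; the quadratic
#' coefficient is evaluated exactly through two linear solves.
#'
#' @param system a `consensus_system` built on an undirected graph.
#' @param omega frequency (may be a vector).
#' @return the approximation `N - omega^2 * sum_ij (W^{-2})_ij`.
#' @export
low_freq_expansion <- function(system, omega) {
  if (!system$undirected)
    stop("low-frequency expansion requires an undirected interaction network")
  ones <- rep(1, system$n_followers)
  a <- solve(system$W, ones)            # W^{-1} 1
  b <- solve(t(system$W), ones)         # W^{-T} 1
  s <- sum(a * b)                       # 1' W^{-2} 1
  system$n_followers - omega^2 * s
}

#' High-frequency gain coefficient
#'
#' At high frequency `H^2 = ||W_l||^2 / omega^2 + O(omega^{-4})`; returns
#' `||W_l||^2`. On a ring where the leader has `k` neighbors of degree `k`
#' this equals `omega0^2 / k`, so the high-frequency response decreases
#' with connectivity.
#'
#' @param system a `consensus_system`.
#' @return `||W_l||^2`.
#' @export
high_freq_norm <- function(system) {
  sum(system$W_l^2)
}

#' Squared gain over outdegree and frequency grids
#'
#' Builds, for each even `k` in `k_grid`, the `(N + 1)`-node ring-lattice
#' leader-follower system and evaluates the exact squared gain at every
#' frequency; reports the per-frequency optimal outdegree.
#'
#' @param n number of followers (the ring has `n + 1` sites).
#' @param k_grid even outdegrees.
#' @param omegas frequencies; default log-spaced over
#'   `[1e-2, 1e2] * omega0`.
#' @param omega0 natural frequency (default 1).
#' @return data.frame with columns `k`, `omega`, `gain2`; attribute
#'   `argmax_k` is a data.frame (`omega`, `k_star`).
#' @export
gain_sweep <- function(n, k_grid, omegas = 10^seq(-2, 2, length.out = 17),
                       omega0 = 1) {
  out <- list()
  for (k in k_grid) {
    sys <- build_consensus_system(ring_lattice_adjacency(n + 1, k),
                                  leader = 1, omega0 = omega0)
    g2 <- vapply(omegas, function(w) transfer_gain(sys, w)$gain2, 0)
    out[[length(out) + 1]] <- data.frame(k = k, omega = omegas, gain2 = g2)
  }
  tab <- do.call(rbind, out)
  argmax <- do.call(rbind, lapply(split(tab, tab$omega), function(d)
    data.frame(omega = d$omega[1], k_star = d$k[which.max(d$gain2)])))
  rownames(argmax) <- NULL
  attr(tab, "argmax_k") <- argmax
  tab
}

#' Time-domain oracle for the frequency response
#'
#' Integrates the leader-follower dynamics `dx/dt = W x + W_l u(t)` with a
#' sinusoidal leader `u(t) = u0 sin(omega t)` from rest and extracts each
#' follower's steady-state amplitude ratio by least-squares projection of
#' the last `n_periods` onto `sin(omega t)` and `cos(omega t)`. The ratios
#' must match `|h_i(omega)|` from [transfer_gain()] up to integration
#' tolerance. Intended as an independent verification route on small
#' systems (N <= 64). With `omega = 0` the leader input is the constant
#' `u0` and the long-time state of every follower is `u0`.
#'
#' @param system a `consensus_system` (small N).
#' @param omega input frequency.
#' @param u0 input amplitude (default 1).
#' @param t_max integration horizon; default covers the consensus transient
#'   plus 8 periods.
#' @param n_periods periods used for the amplitude fit (default 4).
#' @return list with `amplitude` (per-follower ratio to `u0`), `x` (final
#'   state), `t_max`.
#' @export
time_domain_gain <- function(system, omega, u0 = 1, t_max = NULL,
                             n_periods = 4) {
  n <- system$n_followers
  if (n > 64) stop("time-domain oracle is intended for N <= 64")
  if (omega == 0) {
    times <- seq(0, 60 / system$omega0, length.out = 400)
    sol <- deSolve::ode(
      y = numeric(n), times = times,
      func = function(t, x, p) list(as.numeric(system$W %*% x +
                                                 system$W_l * u0)),
      parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
    xf <- sol[nrow(sol), -1]
    return(list(amplitude = as.numeric(xf) / u0, x = xf, t_max = max(times)))
  }
  period <- 2 * pi / omega
  transient <- 40 / system$omega0
  if (is.null(t_max)) t_max <- transient + 8 * period
  if (t_max <= transient + n_periods * period)
    stop("t_max too short for the requested fit window; increase t_max")
  dt <- period / 64
  times <- seq(0, t_max, by = dt)
  sol <- deSolve::ode(
    y = numeric(n), times = times,
    func = function(t, x, p) list(as.numeric(system$W %*% x +
                                               system$W_l * u0 *
                                                 sin(omega * t))),
    parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
  keep <- sol[, 1] >= t_max - n_periods * period
  tt <- sol[keep, 1]
  X <- sol[keep, -1, drop = FALSE]
  basis <- cbind(sin(omega * tt), cos(omega * tt))
  coef <- qr.solve(basis, X)                  # 2 x n
  amp <- sqrt(coef[1, ]^2 + coef[2, ]^2) / u0
  list(amplitude = as.numeric(amp), x = sol[nrow(sol), -1], t_max = t_max)
}
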