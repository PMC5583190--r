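# Brute-force oracles, independent of the package's grid/heap machinery.

# minimum-image distance by explicit minimization over the 9 periodic images
oracle_pdist <- function(a, b, L) {
  shifts <- as.matrix(expand.grid(sx = c(-L, 0, L), sy = c(-L, 0, L)))
  min(sqrt((b[1] + shifts[, 1] - a[1])^2 + (b[2] + shifts[, 2] - a[2])^2))
}

oracle_pdist_all <- function(pos, L) {
  n <- nrow(pos)
  d <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j) d[i, j] <- oracle_pdist(pos[i, ], pos[j, ], L)
  d
}

# k nearest others by full sort (ties toward the lower index), self included
oracle_knn <- function(pos, L, k, alive = rep(TRUE, nrow(pos))) {
  n <- nrow(pos)
  d <- oracle_pdist_all(pos, L)
  lapply(seq_len(n), function(i) {
    if (!alive[i]) return(integer(0))
    others <- setdiff(which(alive), i)
    ord <- others[order(d[i, others], others)]
    sort(c(i, utils::head(ord, k)))
  })
}

# exact chi by sorted-pair cumulative over all pairs (ordered convention)
oracle_chi <- function(pos, theta, v0, L) {
  n <- nrow(pos)
  v <- v0 * cbind(cos(theta), sin(theta))
  dv <- sweep(v, 2, colMeans(v))
  dphi <- dv / sqrt(sum(dv^2) / n)
  pr <- c()
  dd <- c()
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      dd <- c(dd, oracle_pdist(pos[i, ], pos[j, ], L))
      pr <- c(pr, sum(dphi[i, ] * dphi[j, ]))
    }
  o <- order(dd)
  cum <- cumsum(2 * pr[o]) / n
  list(chi = max(cum), argmax_r0 = dd[o][which.max(cum)])
}

make_state <- function(pos, theta, alive = rep(TRUE, nrow(pos)), t = 0L) {
  structure(list(t = as.integer(t), pos = pos, theta = theta, alive = alive),
            class = "swarm_state")
}

random_connected_adjacency <- function(n, p = 0.3) {
  repeat {
    adj <- matrix(0, n, n)
    adj[upper.tri(adj)] <- as.numeric(runif(n * (n - 1) / 2) < p)
    adj <- adj + t(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (igraph::is_connected(g) && all(rowSums(adj) > 0)) return(adj)
  }
}
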