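test_that("the random fixed-outdegree builder has the promised structure", {
  set.seed(1)
  net <- build_random_fixed_outdegree(30, 5)
  expect_equal(Matrix::rowSums(net$adj), rep(5, 30), ignore_attr = TRUE)
  expect_true(all(Matrix::diag(net$adj) == 0))
  expect_true(all(net$adj@x == 1))          # no duplicate edges
  # k = N - 1 gives the complete directed graph
  net <- build_random_fixed_outdegree(7, 6)
  expect_equal(as.matrix(net$adj), 1 - diag(7), ignore_attr = TRUE)
  expect_error(build_random_fixed_outdegree(7, 7), "at most")

  # indegree approximately Binomial(N-1, k/(N-1)) across seeds
  set.seed(2)
  ins <- unlist(replicate(60, Matrix::colSums(
    build_random_fixed_outdegree(40, 6)$adj), simplify = FALSE))
  expect_equal(mean(ins), 6, tolerance = 0.02)
  expect_equal(stats::var(ins), 39 * (6 / 39) * (1 - 6 / 39),
               tolerance = 0.15)
})

test_that("the ring lattice wires k/2 neighbors per side", {
  net <- build_ring_lattice(6, 2)
  want <- as.matrix(Matrix::sparseMatrix(
    i = rep(1:6, each = 2),
    j = c(2, 6, 1, 3, 2, 4, 3, 5, 4, 6, 5, 1), x = 1))
  expect_equal(as.matrix(net$adj), want, ignore_attr = TRUE)
  # N = 6, k = 4: each node misses only its antipode
  net <- build_ring_lattice(6, 4)
  a <- as.matrix(net$adj)
  for (i in 1:6) expect_equal(which(a[i, ] == 0), sort(c(i, (i + 2) %% 6 + 1)),
                              ignore_attr = TRUE)
  # k = N - 1 with odd N is complete
  net <- build_ring_lattice(7, 6)
  expect_equal(as.matrix(net$adj), 1 - diag(7), ignore_attr = TRUE)
  expect_error(build_ring_lattice(8, 3), "even")
  # symmetry
  net <- build_ring_lattice(12, 4)
  expect_true(Matrix::isSymmetric(net$adj))
})

test_that("the threshold update is strict and pins informed nodes", {
  # node observing {1,1,0,0} at theta = 1/2 stays 0; {1,1,1,0} switches
  net <- structure(list(
    n = 5,
    adj = Matrix::sparseMatrix(i = c(1, 1, 1, 1, 2, 2, 2, 2, 3, 4, 5),
                               j = c(2, 3, 4, 5, 1, 3, 4, 5, 1, 1, 1),
                               x = 1, dims = c(5, 5)),
    out_degree = c(4, 4, 1, 1, 1), kind = "custom", directed = TRUE),
    class = "threshold_network")
  s <- c(0, 0, 1, 1, 0)    # node 1 sees {0,1,1,0} = mean 1/2
  s2 <- lt_step(net, s, informed = integer(0), theta = 0.5)
  expect_equal(s2[1], 0)
  s <- c(0, 0, 1, 1, 1)    # node 1 sees {0,1,1,1} = 3/4
  s2 <- lt_step(net, s, informed = integer(0), theta = 0.5)
  expect_equal(s2[1], 1)
  # informed nodes stay 1 whatever their neighbors say
  s2 <- lt_step(net, c(1, 0, 0, 0, 0), informed = 1L, theta = 0.5)
  expect_equal(s2[1], 1)
})

test_that("polarization traces match hand iterations", {
  # ring N=6, k=2, theta=0.4, informed {1,4}: everyone flips at t=1
  net <- build_ring_lattice(6, 2)
  tr <- polarization_speed(net, theta = 0.4, informed = c(1L, 4L))
  expect_true(tr$absorbed)
  expect_equal(tr$T_absorb, 1L)
  expect_equal(tr$c, (1 - 2 / 6) / 1)
  expect_equal(tr$P, c(1 / 3, 1))

  # complete graph, theta = 1/2, 36% informed: mean 0.36 < 1/2, frozen
  net <- build_random_fixed_outdegree(50, 49)
  set.seed(3)
  tr <- polarization_speed(net, informed_fraction = 0.36, theta = 0.5)
  expect_false(tr$absorbed)
  expect_equal(tr$c, 0)
  expect_equal(utils::tail(tr$P, 1), 18 / 50)

  # everyone informed: degenerate, T = 0
  net <- build_ring_lattice(8, 2)
  tr <- polarization_speed(net, informed = 1:8)
  expect_true(tr$degenerate)
  expect_equal(tr$T_absorb, 0L)
  expect_equal(tr$c, 0)
})

test_that("trajectories are deterministic and monotone in the informed set", {
  set.seed(14)
  for (rep in 1:10) {
    net <- build_random_fixed_outdegree(60, 6)
    small <- sample.int(60, 15)
    big <- c(small, sample(setdiff(1:60, small), 10))
    tr_a <- polarization_speed(net, theta = 0.45, informed = small)
    tr_a2 <- polarization_speed(net, theta = 0.45, informed = small)
    expect_identical(tr_a$P, tr_a2$P)
    tr_b <- polarization_speed(net, theta = 0.45, informed = big)
    len <- min(length(tr_a$P), length(tr_b$P))
    expect_true(all(tr_b$P[seq_len(len)] >= tr_a$P[seq_len(len)] - 1e-12))
    # a superset of sources never delays absorption (c itself is not
    # monotone: its numerator 1 - P(0) shrinks with the informed set)
    if (tr_a$absorbed) {
      expect_true(tr_b$absorbed)
      expect_lte(tr_b$T_absorb, tr_a$T_absorb)
    }
    # ground-state starts with pinned sources are monotone in time
    expect_true(all(diff(tr_a$P) >= -1e-12))
  }
})

test_that("the k sweep averages realizations and locates the optimum", {
  tab <- threshold_k_sweep(n = 192, k_grid = c(2, 6, 10),
                           n_realizations = 6, seed = 21,
                           kinds = "random-fixed-outdegree")
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$se_c >= 0))
  expect_true(all(tab$n_absorbed <= 6))
  ks <- attr(tab, "k_star")
  expect_true(ks[["random-fixed-outdegree"]] %in% c(2, 6, 10))
  # determinism of the whole sweep
  tab2 <- threshold_k_sweep(n = 192, k_grid = c(2, 6, 10),
                            n_realizations = 6, seed = 21,
                            kinds = "random-fixed-outdegree")
  expect_identical(tab$mean_c, tab2$mean_c)
})
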