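test_that("velocity fluctuations satisfy their defining identities", {
  # two agents with opposite headings: <v> = 0, fluctuations (+/-1, 0)
  st <- make_state(cbind(c(1, 3), c(1, 1)), c(0, pi))
  fl <- velocity_fluctuations(st, v0 = 0.5)
  expect_equal(fl$delta_phi[1, ], c(1, 0), tolerance = 1e-12)
  expect_equal(fl$delta_phi[2, ], c(-1, 0), tolerance = 1e-12)

  set.seed(8)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    st <- make_state(cbind(runif(n), runif(n)), runif(n, -pi, pi))
    fl <- velocity_fluctuations(st, v0 = 0.05)
    expect_equal(colSums(fl$delta_phi), c(0, 0), tolerance = 1e-10)
    expect_equal(sum(fl$delta_phi^2), n, tolerance = 1e-10)
  }

  # perfectly ordered snapshot has no fluctuation signal
  st <- make_state(cbind(runif(6), runif(6)), rep(1, 6))
  expect_error(velocity_fluctuations(st, 0.05), "degenerate")
})

test_that("connected correlation bins pair products correctly", {
  # two agents at a known distance: one occupied bin with C = -1
  st <- make_state(cbind(c(1, 4), c(1, 1)), c(0, pi))
  fl <- velocity_fluctuations(st, 0.5)
  cc <- connected_correlation(fl, st, L = 20, bin_width = 0.5)
  occ <- which(cc$pair_counts > 0)
  expect_length(occ, 1)
  expect_true(cc$bin_edges[occ] <= 3 && 3 < cc$bin_edges[occ + 1])
  expect_equal(cc$c_of_r[occ], -1, tolerance = 1e-12)
  expect_true(all(is.na(cc$c_of_r[-occ])))
  expect_equal(sum(cc$pair_counts), 2 * 1)  # ordered pairs
  expect_equal(cc$cumulative[length(cc$cumulative)], -1, tolerance = 1e-12)

  # two tight aligned pairs, mutually anti-aligned, far apart
  st <- make_state(rbind(c(1, 1), c(1.1, 1), c(6, 6), c(6.1, 6)),
                   c(0, 0, pi, pi))
  fl <- velocity_fluctuations(st, 0.5)
  cc <- connected_correlation(fl, st, L = 20, bin_width = 0.5)
  near <- which(cc$bin_edges[-length(cc$bin_edges)] <= 0.1 &
                  cc$bin_edges[-1] > 0.1)
  expect_equal(cc$c_of_r[near], 1, tolerance = 1e-12)
  far <- which(cc$pair_counts > 0 & seq_along(cc$pair_counts) != near)
  expect_true(all(cc$c_of_r[far] < 0))
  expect_equal(sum(cc$pair_counts), 4 * 3)
})

test_that("rebinning conserves the total pair sum", {
  set.seed(11)
  n <- 30
  L <- 6
  st <- make_state(cbind(runif(n, 0, L), runif(n, 0, L)),
                   runif(n, -pi, pi))
  fl <- velocity_fluctuations(st, 0.05)
  c1 <- connected_correlation(fl, st, L, bin_width = L / 100)
  c2 <- connected_correlation(fl, st, L, bin_width = L / 50)
  expect_equal(sum(c1$c_of_r * c1$pair_counts, na.rm = TRUE),
               sum(c2$c_of_r * c2$pair_counts, na.rm = TRUE),
               tolerance = 1e-10)
  expect_equal(sum(c1$pair_counts), n * (n - 1))
})

test_that("susceptibility takes the maximum of the cumulative", {
  # binned-curve arithmetic on a hand-made cumulative sequence
  fake <- structure(
    list(bin_edges = c(0, 1, 2, 3, 4), c_of_r = rep(0.1, 4),
         pair_counts = rep(2, 4), cumulative = c(0.5, 0.9, 0.4, -1),
         n_alive = 4),
    class = "correlation_curve")
  s <- susceptibility(fake)
  expect_equal(s$chi, 0.9)
  expect_equal(s$argmax_r0, 2)

  fake$cumulative <- c(-0.2, -0.05, -0.6, -1)
  expect_equal(susceptibility(fake)$chi, -0.05)

  # four-agent construction: chi peaks just before the far pairs enter
  st <- make_state(rbind(c(1, 1), c(1.1, 1), c(6, 6), c(6.1, 6)),
                   c(0, 0, pi, pi))
  fl <- velocity_fluctuations(st, 0.5)
  cc <- connected_correlation(fl, st, L = 20)
  s <- susceptibility(cc)
  expect_equal(s$chi, 1, tolerance = 1e-12)  # 2 ordered intra pairs / N
  expect_equal(s$argmax_r0, 0.1, tolerance = 1e-9)
})

test_that("chi equals the sorted-pair oracle and is invariant to rigid motions", {
  set.seed(21)
  for (n in c(24, 80)) {
    L <- 9
    pos <- cbind(runif(n, 0, L), runif(n, 0, L))
    theta <- runif(n, -pi, pi)
    st <- make_state(pos, theta)
    fl <- velocity_fluctuations(st, 0.05)
    s <- susceptibility(connected_correlation(fl, st, L))
    orc <- oracle_chi(pos, theta, 0.05, L)
    expect_equal(s$chi, orc$chi, tolerance = 1e-10)
    expect_equal(s$argmax_r0, orc$argmax_r0, tolerance = 1e-10)

    # global rotation of headings and translation of positions
    st2 <- make_state((pos + 2.345) %% L, theta + 1.234)
    fl2 <- velocity_fluctuations(st2, 0.05)
    s2 <- susceptibility(connected_correlation(fl2, st2, L))
    expect_equal(s2$chi, s$chi, tolerance = 1e-8)
  }
})

test_that("the sampling protocol is deterministic and reduces cleanly", {
  cfg <- swarm_config(48, k = 4, seed = 31)
  p1 <- correlation_protocol(cfg, n_steps = 600, sample_every = 200,
                             burn_in = 0)
  p2 <- correlation_protocol(cfg, n_steps = 600, sample_every = 200,
                             burn_in = 0)
  expect_identical(p1$curve$c_of_r, p2$curve$c_of_r)
  expect_identical(p1$chi$chi, p2$chi$chi)
  expect_equal(p1$n_samples, 3)

  # single-snapshot reduction: one histogram only
  p3 <- correlation_protocol(cfg, n_steps = 600, sample_every = 600,
                             burn_in = 0)
  expect_equal(p3$n_samples, 1)
  # averaged cumulative still ends at the exact zero-sum identity
  expect_equal(p3$curve$cumulative[length(p3$curve$cumulative)], -1,
               tolerance = 1e-10)
})

test_that("per-snapshot identities hold along a run", {
  cfg <- swarm_config(64, k = 6, seed = 17)
  r <- run_swarm(cfg, 400, sample_every = 100)
  for (s in r$samples) {
    fl <- velocity_fluctuations(s, cfg$speed)
    expect_equal(colSums(fl$delta_phi), c(0, 0), tolerance = 1e-9)
    expect_equal(sum(fl$delta_phi^2), 64, tolerance = 1e-9)
    cc <- connected_correlation(fl, s, cfg$box_length, keep_pairs = FALSE)
    expect_equal(cc$cumulative[length(cc$cumulative)], -1,
                 tolerance = 1e-9)
  }
})
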