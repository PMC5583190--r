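test_that("the predator pursues the nearest agent at 1.4x speed", {
  # single agent due east at distance 5
  st <- make_state(cbind(c(15), c(10)), 0)
  p2 <- predator_step(c(10, 10), st, v0 = 0.5, speed_factor = 1.4, L = 100)
  expect_equal(p2, c(10 + 1.4 * 0.5, 10), tolerance = 1e-12)

  # predator exactly on an agent holds position
  p3 <- predator_step(c(15, 10), st, 0.5, 1.4, 100)
  expect_equal(p3, c(15, 10))

  # nearest-agent choice matches a full distance scan (with wrapping)
  set.seed(4)
  n <- 40
  L <- 8
  st <- make_state(cbind(runif(n, 0, L), runif(n, 0, L)),
                   runif(n, -pi, pi))
  pred <- runif(2, 0, L)
  d <- vapply(seq_len(n), function(i) oracle_pdist(pred, st$pos[i, ], L), 0)
  i_star <- which.min(d)
  p4 <- predator_step(pred, st, 0.5, 1.4, L)
  step_dir <- periodic_displacement(pred, p4, L)
  want_dir <- periodic_displacement(pred, st$pos[i_star, ], L) / d[i_star]
  expect_equal(step_dir / sqrt(sum(step_dir^2)), want_dir,
               tolerance = 1e-9)
})

test_that("the flee override points agents straight away from the threat", {
  # agent at R_D/2 with the predator due south flees due north
  st <- make_state(cbind(c(10), c(11)), 0.5)
  ov <- flee_override(st, pred_pos = c(10, 10), r_detect = 2, L = 100)
  expect_true(ov$fleeing[1])
  expect_equal(ov$theta[1], pi / 2, tolerance = 1e-12)

  # at exactly R_D the agent does NOT flee (strict inequality)
  st <- make_state(cbind(c(12), c(10)), 0.5)
  ov <- flee_override(st, c(10, 10), r_detect = 2, L = 100)
  expect_false(ov$fleeing[1])
  expect_equal(ov$theta[1], 0.5)

  # far agents keep the pure alignment update
  cfg <- swarm_config(3, k = 2, box_length = 100, eta = 0)
  st <- make_state(cbind(c(50, 50.3, 50.6), c(50, 50, 50)),
                   c(0, pi / 2, pi / 2))
  ov <- flee_override(st, c(10, 10), r_detect = 2, L = 100)
  expect_false(any(ov$fleeing))
  st2 <- vicsek_step(st, cfg)
  expect_equal(st2$theta, rep(atan2(2, 1), 3), tolerance = 1e-12)
})

test_that("catches remove agents and log simultaneous events together", {
  st <- make_state(cbind(c(1, 1.05, 5), c(1, 1, 5)), rep(0, 3), t = 7L)
  # no agent within range: unchanged
  res <- catch_and_remove(st, c(3, 3), r_catch = 0.5, L = 10)
  expect_equal(res$state$alive, rep(TRUE, 3))
  expect_equal(nrow(res$catches), 0)
  # two agents inside the catch disc in the same step
  res <- catch_and_remove(st, c(1.02, 1), r_catch = 0.5, L = 10)
  expect_equal(res$state$alive, c(FALSE, FALSE, TRUE))
  expect_equal(res$catches$t, c(7L, 7L))
  expect_equal(sort(res$catches$id), c(1L, 2L))
})

test_that("avoidance time pools within-run intervals and drops the first catch", {
  lg1 <- structure(list(catch_times = c(2100, 2400, 2900)),
                   class = "catch_log")
  at <- avoidance_time(lg1)
  expect_equal(at$intervals, c(300, 500))
  expect_equal(at$mean, 400)

  lg2 <- structure(list(catch_times = c(100, 200)), class = "catch_log")
  lg3 <- structure(list(catch_times = c(150, 450)), class = "catch_log")
  at <- avoidance_time(list(lg2, lg3))
  expect_equal(sort(at$intervals), c(100, 300))
  expect_equal(at$mean, 200)

  lg4 <- structure(list(catch_times = c(9)), class = "catch_log")
  expect_error(avoidance_time(lg4), "two or more")
})

test_that("a slow predator never catches a fleeing loner", {
  # geometric sanity: with speed_factor <= 1 the distance cannot shrink
  L <- 100
  v0 <- 0.5
  st <- make_state(cbind(50, 51), pi / 2)
  pred <- c(50, 50)
  d0 <- periodic_distance(pred, st$pos[1, ], L)
  for (step in 1:200) {
    ov <- flee_override(st, pred, r_detect = 50, L = L)
    st$theta <- ov$theta
    st$pos <- (st$pos + v0 * cbind(cos(st$theta), sin(st$theta))) %% L
    pred <- predator_step(pred, st, v0, speed_factor = 0.9, L = L)
    res <- catch_and_remove(st, pred, r_catch = 0.3, L = L)
    st <- res$state
    expect_equal(nrow(res$catches), 0)
  }
  expect_gte(periodic_distance(pred, st$pos[1, ], L), d0)
})

test_that("full runs conserve agents and respect the intro step", {
  cfg <- swarm_config(48, k = 4, seed = 77)
  pc <- predator_config(cfg, intro_step = 30, n_steps = 400, n_runs = 1)
  lg <- run_predator(cfg, pc)
  expect_s3_class(lg, "catch_log")
  expect_equal(lg$survivors + length(lg$catch_times), 48)
  if (length(lg$catch_times) > 0) {
    expect_gt(min(lg$catch_times), 30)
    expect_true(all(diff(lg$catch_times) >= 0))
  }
  # no predator phase at all: empty log
  pc0 <- predator_config(cfg, intro_step = 39, n_steps = 40, n_runs = 1)
  lg0 <- run_predator(cfg, pc0)
  expect_equal(length(lg0$catch_times), 0)
  expect_equal(lg0$survivors, 48)
  # determinism
  lg2 <- run_predator(cfg, pc)
  expect_identical(lg$catch_times, lg2$catch_times)
})

test_that("the experiment table reports realized degrees and uncertainty", {
  base <- swarm_config(64, k = 2, seed = 11)
  pc <- predator_config(base, intro_step = 40, n_steps = 400, n_runs = 3)
  tab <- predator_experiment(base, pc, k_grid = c(0, 6))
  expect_equal(tab$k, c(0, 6))
  expect_true(all(tab$n_intervals > 0))
  expect_true(all(tab$mean_avoidance_time > 0))
  expect_true(all(is.finite(tab$se)))

  # metric sweep reports the realized mean degree
  tabm <- predator_experiment(base, pc, radius_grid = c(1.2))
  expect_true(is.finite(tabm$k) && tabm$k > 0)
  expect_equal(tabm$radius, 1.2)
})

test_that("metric and topological hunts agree at matched mean degree", {
  # the ordered phase is spatially clumped, so the realized metric degree
  # exceeds the uniform-density estimate; match the topological run to the
  # degree the metric run actually realized
  base <- swarm_config(256, k = 8, seed = 400)
  pc <- predator_config(base, intro_step = 150, n_steps = 650, n_runs = 8)
  tm <- predator_experiment(base, pc, radius_grid = 0.9)
  expect_gt(tm$k, 0)
  tt <- predator_experiment(base, pc, k_grid = round(tm$k))
  ratio <- tt$mean_avoidance_time / tm$mean_avoidance_time
  expect_gt(ratio, 0.6)
  expect_lt(ratio, 1.6)
})
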