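game134 <- game_params(1.34)

test_that("pairwise payoffs implement the weak prisoner's dilemma", {
  expect_equal(pairwise_payoff("C", "C", game134), 1)
  expect_equal(pairwise_payoff("D", "C", game134), 1.34)
  expect_equal(pairwise_payoff("C", "D", game134), 0)
  expect_equal(pairwise_payoff("D", "D", game134), 0)
  # integer coding and vectorization over the neighbor argument
  expect_equal(pairwise_payoff(1L, c(1L, 0L, 1L), game134), c(1, 0, 1))
  expect_equal(pairwise_payoff(0L, c(1L, 0L), game_params(1.5)), c(1.5, 0))
  expect_error(pairwise_payoff("X", "C", game134), "'C' or 'D'")
})

test_that("utility accumulates weighted payoffs over the 8 neighbors", {
  allC <- sim_state(lattice_spec(4), matrix(1L, 4, 4))
  for (x in c(1L, 6L, 16L)) {
    rec <- utility(allC, x, game134)
    expect_equal(rec$U, 8)
    expect_equal(rec$avg_U, 1)
    expect_equal(rec$avg_payoff, 1)
  }
  # lone defector among cooperators, uniform weights
  s <- matrix(1L, 4, 4)
  s[2, 2] <- 0L
  st <- sim_state(lattice_spec(4), s)
  expect_equal(utility(st, 6L, game134)$U, 8 * 1.34)
})

test_that("utility matches a brute-force 8-term oracle on random fixtures", {
  set.seed(99)
  for (k in 1:100) {
    st <- random_state(L = 5, delta = 0.4)
    site <- sample.int(25L, 1L)
    expect_equal(utility(st, site, game134)$U,
                 brute_force_utility(st, site, game134),
                 tolerance = 1e-12)
  }
})

test_that("weight adjustment rewards above-average and punishes below-average links", {
  wp <- weight_params(0.4, 0.1)
  # focal cooperator at site 1 with one defecting neighbor at (2,2)
  s <- matrix(1L, 4, 4)
  s[2, 2] <- 0L
  st <- sim_state(lattice_spec(4), s)
  site <- 1L
  rec <- utility(st, site, game134)
  expect_true(any(rec$payoffs > rec$avg_payoff) &&
                any(rec$payoffs < rec$avg_payoff))
  st2 <- adjust_weights(st, site, rec, wp)
  ed <- st$edge[site, ]
  up <- rec$payoffs > rec$avg_payoff
  dn <- rec$payoffs < rec$avg_payoff
  expect_equal(st2$weights[ed[up]], rep(1.1, sum(up)))
  expect_equal(st2$weights[ed[dn]], rep(0.9, sum(dn)))
  # untouched edges stay put
  expect_equal(st2$weights[-ed], st$weights[-ed])
})

test_that("weight adjustment clamps at the bounds and is inert for Delta = 0", {
  wp <- weight_params(0.4, 0.2)
  s <- matrix(1L, 4, 4)
  s[2, 2] <- 0L  # gives site 1 a mixed neighborhood
  st <- sim_state(lattice_spec(4), s)
  st$weights[] <- 1.4  # already at the upper bound
  rec <- utility(st, 1L, game134)
  st2 <- adjust_weights(st, 1L, rec, wp)
  expect_true(all(st2$weights <= 1.4 & st2$weights >= 0.6))
  expect_equal(st2$weights[st$edge[1L, rec$payoffs > rec$avg_payoff]],
               rep(1.4, sum(rec$payoffs > rec$avg_payoff)))

  st3 <- adjust_weights(st, 1L, rec, weight_params(0.4, 0))
  expect_identical(st3$weights, st$weights)
})

test_that("a strategy-uniform neighborhood leaves weights unchanged", {
  # all payoffs equal the mean payoff exactly: nothing to discriminate
  allC <- sim_state(lattice_spec(4), matrix(1L, 4, 4))
  rec <- utility(allC, 6L, game134)
  expect_true(all(rec$payoffs == rec$avg_payoff))
  st2 <- adjust_weights(allC, 6L, rec, weight_params(0.4, 0.2))
  expect_identical(st2$weights, allC$weights)
  allD <- sim_state(lattice_spec(4), matrix(0L, 4, 4))
  st3 <- adjust_weights(allD, 6L, utility(allD, 6L, game134),
                        weight_params(0.4, 0.2))
  expect_identical(st3$weights, allD$weights)
})

test_that("adoption probability is the clipped normalized utility difference", {
  expect_equal(adoption_probability(5, 5, game134), 0)
  expect_equal(adoption_probability(6, 5, game134), 0)
  expect_equal(adoption_probability(0, 8 * 1.34, game134), 1)
  expect_equal(adoption_probability(2, 4, game134), 2 / (8 * 1.34))
  # weighted utilities can exceed the normalizer: clipped at 1
  b <- 1.34
  expect_equal(adoption_probability(0, 8 * 1.8 * b, game_params(b)), 1)
  # fuzzing over the reachable utility range [0, 8 (1+delta) b]
  set.seed(42)
  U <- matrix(runif(2000, 0, 8 * 1.8 * 1.34), ncol = 2)
  W <- adoption_probability(U[, 1], U[, 2], game134)
  expect_true(all(W >= 0 & W <= 1))
  expect_true(all(W[U[, 2] <= U[, 1]] == 0))
})

test_that("the pure-R stepper is trace-identical to the compiled kernel", {
  cfg <- run_config(L = 5, b = 1.34, delta = 0.4, Delta = 0.2,
                    total_mcs = 10, measure_window = 5, replicates = 1)
  set.seed(123)
  st <- init_state(cfg)
  n_steps <- 200L
  set.seed(456)
  ref <- st
  for (k in seq_len(n_steps)) ref <- elementary_step(ref, cfg)
  set.seed(456)
  out <- coevoPD:::cpp_elementary_steps(as.integer(st$strategies),
                                        st$weights, 5L, 1.34, 0.4, 0.2,
                                        n_steps)
  expect_identical(as.integer(ref$strategies), out$strategies)
  expect_identical(ref$weights, out$weights)
})

test_that("with Delta = 0 the kernel is trace-identical to an independent classical implementation", {
  L <- 8
  set.seed(2024)
  strat <- matrix(sample(c(0L, 1L), L * L, replace = TRUE), L, L)
  n_steps <- 3L * L * L
  set.seed(77)
  ref <- classical_spd_steps(strat, b = 1.3, n_steps)
  set.seed(77)
  out <- coevoPD:::cpp_elementary_steps(as.integer(strat),
                                        rep(1, 4 * L * L), L, 1.3, 0.4, 0,
                                        n_steps)
  expect_identical(as.integer(ref), out$strategies)
  expect_true(all(out$weights == 1))
})

test_that("elementary and Monte Carlo steps are deterministic under a fixed seed", {
  cfg <- run_config(L = 4, b = 1.5, delta = 0.4, Delta = 0.2,
                    total_mcs = 5, measure_window = 3, replicates = 1,
                    init_mode = "half_plane")
  run_once <- function() {
    set.seed(7)
    st <- init_state(cfg)
    st <- monte_carlo_step(st, cfg)
    st
  }
  a <- run_once()
  b2 <- run_once()
  expect_identical(a$strategies, b2$strategies)
  expect_identical(a$weights, b2$weights)
  expect_identical(a$mcs, 1L)
})

test_that("uniform strategy fields are absorbing for strategies", {
  for (init in c(0L, 1L)) {
    L <- 10
    r <- NULL
    cfg <- run_config(L = L, b = 1.9, delta = 0.8, Delta = 0.4,
                      total_mcs = 1000, measure_window = 100,
                      replicates = 1)
    set.seed(5)
    out <- coevoPD:::cpp_run_kernel(rep(init, L * L), rep(1, 4 * L * L), L,
                                    1.9, 0.8, 0.4, 1000L, integer(0),
                                    FALSE, FALSE, TRUE)
    expect_true(all(out$strategies == init))
    expect_true(all(out$rho == init))
    expect_true(out$bounds_ok)
  }
})

test_that("run_simulation honors total_mcs = 0 and the Delta = 0 classical limit", {
  cfg0 <- run_config(L = 10, b = 1.2, delta = 0.4, Delta = 0.2,
                     total_mcs = 0, measure_window = 1, replicates = 1)
  r0 <- run_simulation(cfg0, seed = 1)
  expect_identical(nrow(r0$trajectory), 1L)
  expect_identical(r0$trajectory$mcs, 0L)

  cfgc <- run_config(L = 20, b = 1.3, delta = 0.4, Delta = 0,
                     total_mcs = 50, measure_window = 10, replicates = 1)
  rc <- run_simulation(cfgc, seed = 1)
  expect_true(all(rc$state$weights == 1))
})

test_that("weak temptation sustains cooperation in the classical limit", {
  cfg <- run_config(L = 50, b = 1.01, delta = 0.4, Delta = 0,
                    total_mcs = 2000, measure_window = 200, replicates = 1)
  r <- run_simulation(cfg, seed = 4, stop_when_uniform = TRUE)
  expect_gt(r$stationary, 0)
})

test_that("weight bounds hold over full runs at several parameter settings", {
  for (p in list(c(0.4, 0.2), c(0.8, 0.4), c(0.2, 0.3))) {
    cfg <- run_config(L = 20, b = 1.5, delta = p[1], Delta = p[2],
                      total_mcs = 300, measure_window = 50, replicates = 1)
    r <- run_simulation(cfg, seed = 9, check_bounds = TRUE)
    expect_true(all(r$state$weights >= 1 - p[1] &
                      r$state$weights <= 1 + p[1]))
  }
})

test_that("seeded runs reproduce bit-exactly and echo their seed", {
  cfg <- run_config(L = 10, b = 1.34, delta = 0.4, Delta = 0.2,
                    total_mcs = 30, measure_window = 10, replicates = 1)
  a <- run_simulation(cfg, seed = 31)
  b2 <- run_simulation(cfg, seed = 31)
  expect_identical(a$trajectory, b2$trajectory)
  expect_identical(a$state$weights, b2$state$weights)
  expect_identical(a$seed, 31L)
  c2 <- run_simulation(cfg, seed = 32)
  expect_false(identical(a$state$strategies, c2$state$strategies) &&
                 identical(a$state$weights, c2$state$weights))
})
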