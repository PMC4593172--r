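small_cfg <- run_config(L = 10, b = 1.34, delta = 0.4, Delta = 0.2,
                        total_mcs = 60, measure_window = 20, replicates = 2)

test_that("extinction threshold interpolates the synthetic closed-form curve", {
  curve <- data.frame(b = seq(1.10, 1.40, by = 0.01))
  curve$mean <- pmax(0, 1 - 5 * (curve$b - 1.1))
  expect_equal(find_extinction_threshold(curve, tol = 1e-9), 1.30,
               tolerance = 1e-6)
  # identically-zero and identically-one curves are out of range
  z <- data.frame(b = seq(1.1, 1.3, 0.05), mean = 0)
  expect_true(is.na(find_extinction_threshold(z, tol = 1e-6)))
  expect_identical(attr(find_extinction_threshold(z, tol = 1e-6), "status"),
                   "below_range")
  o <- data.frame(b = seq(1.1, 1.3, 0.05), mean = 1)
  expect_identical(attr(find_extinction_threshold(o, tol = 1e-6), "status"),
                   "above_range")
})

test_that("defector extinction uses the dominance level 1 - tol", {
  curve <- data.frame(b = seq(1.0 + 0.02, 1.5, by = 0.02))
  curve$mean <- pmin(1, pmax(0, 1 - 4 * (curve$b - 1.2)))
  # crosses 1 - tol just above b = 1.2
  thr <- find_extinction_threshold(curve, "defectors", tol = 1e-6)
  expect_equal(thr, 1.2, tolerance = 1e-3)
})

test_that("raising the extinction tolerance never raises the threshold", {
  set.seed(8)
  curve <- data.frame(b = seq(1.1, 1.5, by = 0.02))
  curve$mean <- pmax(0, 1 - 3 * (curve$b - 1.1) + rnorm(nrow(curve), 0, 0.02))
  tols <- c(1e-6, 1e-3, 0.01, 0.05, 0.2)
  thr <- vapply(tols, function(tl)
    as.numeric(find_extinction_threshold(curve, tol = tl)), numeric(1))
  expect_true(all(diff(thr) <= 1e-12))
})

test_that("a single-point amplitude sweep reproduces direct runs", {
  sw <- sweep_amplitude(1.34, 0.4, 0.5, config = small_cfg, seed = 10)
  expect_identical(nrow(sw), 2L)
  direct <- vapply(split_seed(10, 1:2), function(s) {
    cfg <- run_config(L = 10, b = 1.34, delta = 0.4, Delta = 0.2,
                      total_mcs = 60, measure_window = 20, replicates = 2)
    run_simulation(cfg, seed = s, stop_when_uniform = TRUE)$stationary
  }, numeric(1))
  expect_equal(sw$rho_c, direct)
  agg <- aggregate_sweep(sw)
  expect_equal(agg$mean, mean(direct))
})

test_that("sweeps validate their parameter domains", {
  expect_error(sweep_amplitude(1.34, 0, 0.5, config = small_cfg),
               "delta != 0")
  expect_error(sweep_amplitude(1.34, 0.4, c(-0.1, 0.5), config = small_cfg),
               ">= 0")
  expect_error(sweep_temptation(0.4, 0.2, c(1.2, 2.3), config = small_cfg),
               "1 < b < 2")
  expect_error(phase_diagram(numeric(0), 1.2, 0.4, config = small_cfg),
               "non-empty")
  expect_error(phase_diagram(0.5, 1.2, 0, config = small_cfg),
               "delta != 0")
})

test_that("replicate aggregation stays within the replicate range", {
  sw <- sweep_temptation(0.4, 0.2, c(1.15, 1.3), config = small_cfg,
                         seed = 5)
  agg <- aggregate_sweep(sw)
  expect_identical(agg$n, rep(2L, 2))
  for (i in seq_len(nrow(agg))) {
    reps <- sw$rho_c[sw$b == agg$b[i]]
    expect_gte(agg$mean[i], min(reps))
    expect_lte(agg$mean[i], max(reps))
  }
  # single replicate: no standard error
  cfg1 <- run_config(L = 10, b = 1.34, delta = 0.4, Delta = 0.2,
                     total_mcs = 40, measure_window = 10, replicates = 1)
  agg1 <- aggregate_sweep(sweep_amplitude(1.34, 0.4, 0.5, config = cfg1,
                                          seed = 2))
  expect_true(is.na(agg1$se))
})

test_that("time courses record per-MCS rho and honor thinning and snapshots", {
  cfg <- run_config(L = 10, b = 1.34, delta = 0.4, Delta = 0.2,
                    init_mode = "half_plane", total_mcs = 40,
                    measure_window = 10, replicates = 1)
  tc <- time_course(cfg, snapshot_steps = c(0, 20, 40), seed = 6)
  expect_identical(nrow(tc$trajectory), 41L)
  expect_identical(names(tc$snapshots), c("0", "20", "40"))
  tc2 <- time_course(cfg, record_every = 10, seed = 6)
  expect_identical(tc2$trajectory$mcs, c(0L, 10L, 20L, 30L, 40L))
})

test_that("phase diagrams report single-valued boundaries per ratio", {
  cfg <- run_config(L = 10, b = 1.34, delta = 0.4, Delta = 0.2,
                    total_mcs = 80, measure_window = 20, replicates = 2)
  pd <- phase_diagram(c(0.25, 0.5), c(1.05, 1.2, 1.35), 0.4, config = cfg,
                      seed = 3)
  expect_identical(nrow(pd$boundaries), 2L)
  expect_identical(pd$boundaries$ratio, c(0.25, 0.5))
  expect_identical(nrow(pd$surface), 6L)
  expect_true(all(pd$surface$mean >= 0 & pd$surface$mean <= 1))
  expect_identical(nrow(pd$grid), 12L)
})

test_that("stationary cooperation is non-increasing in b in the classical case", {
  bs <- c(1.05, 1.15, 1.25, 1.35)
  cfg <- run_config(L = 50, b = 1.2, delta = 0.4, Delta = 0,
                    total_mcs = 2000, measure_window = 300, replicates = 5)
  sw <- sweep_temptation(0.4, 0, bs, config = cfg, seed = 14)
  agg <- aggregate_sweep(sw, by = "b")
  se <- ifelse(is.na(agg$se), 0, agg$se)
  for (i in seq_len(nrow(agg) - 1)) {
    expect_lte(agg$mean[i + 1],
               agg$mean[i] + se[i] + se[i + 1])
  }
})

test_that("stationary levels agree between L = 50 and L = 100 at spot checks", {
  pts <- list(c(Delta = 0, expect = NA), c(Delta = 0.2, expect = NA),
              c(Delta = 0.4, expect = NA))
  for (p in pts) {
    res <- lapply(c(50, 100), function(L) {
      cfg <- run_config(L = L, b = 1.34, delta = 0.4, Delta = p[["Delta"]],
                        total_mcs = 3000, measure_window = 300,
                        replicates = 3)
      vapply(split_seed(21, 1:3), function(s)
        run_simulation(cfg, seed = s, stop_when_uniform = TRUE)$stationary,
        numeric(1))
    })
    m <- vapply(res, mean, numeric(1))
    se <- vapply(res, function(x) stats::sd(x) / sqrt(length(x)), numeric(1))
    expect_lte(abs(m[1] - m[2]), 2 * sqrt(se[1]^2 + se[2]^2) + 0.02)
  }
})
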