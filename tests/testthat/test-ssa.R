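test_that("propensities follow the discrete state", {
  pars <- ref_params()
  # empty promoter, no repressor: only synthesis, at a * Phi
  p0 <- propensities(0, 0, pars)
  expect_equal(p0$propensity[p0$reaction == "synthesis"], 45.1660557,
               tolerance = 1e-7)
  expect_equal(sum(p0$propensity), 45.1660557, tolerance = 1e-7)
  # full promoter: no binding possible, unbinding at N * q
  pN <- propensities(3, 50, pars)
  expect_equal(sum(pN$propensity[grepl("^bind", pN$reaction)]), 0)
  expect_equal(pN$propensity[pN$reaction == "unbind3"], 3 * 0.75)
  # intermediate state: binding scales linearly in n
  p1 <- propensities(1, 100, pars)
  expect_equal(p1$propensity[p1$reaction == "bind2"],
               rate_ladder(pars)$kon[2] * 100)
  expect_error(propensities(4, 10, pars), "occupancy")
})

test_that("same seed reproduces the trajectory exactly", {
  pars <- ref_params(eps = 9)
  t1 <- simulate_circuit(pars, t_end = 260, seed = 99, burn_in = 200)
  t2 <- simulate_circuit(pars, t_end = 260, seed = 99, burn_in = 200)
  expect_identical(t1$time, t2$time)
  expect_identical(t1$n, t2$n)
  t3 <- simulate_circuit(pars, t_end = 260, seed = 100, burn_in = 200)
  expect_false(identical(t1$time, t3$time))
})

test_that("states stay in range and events balance species changes", {
  pars <- ref_params(eps = 9)
  traj <- simulate_circuit(pars, t_end = 150, seed = 5, burn_in = 0,
                           init = list(occupancy = 0, n = 52))
  expect_true(all(traj$n >= 0))
  expect_true(all(traj$occupancy %in% 0:3))
  # consecutive records differ by exactly one reaction's stoichiometry
  expect_true(all(abs(diff(traj$n)) <= 1))
  expect_true(all(abs(diff(traj$occupancy)) <= 1))
  n_by <- table(factor(traj$reaction, levels = 1:8))
  binds <- sum(n_by[c(1, 3, 5)]); unbinds <- sum(n_by[c(2, 4, 6)])
  expect_equal(binds - unbinds, tail(traj$occupancy, 1) - 0)
  expect_equal(as.integer(n_by[7] - n_by[8] - binds + unbinds),
               tail(traj$n, 1) - 52L)
})

test_that("pure death process decays exponentially in the mean", {
  pars <- ref_params(a0 = 0, eps = 1)   # synthesis off; g = 0.3
  set.seed(31)
  n0 <- 100; t_obs <- 3
  finals <- vapply(1:400, function(i) {
    tr <- simulate_circuit(pars, t_end = t_obs + 1e-9, burn_in = 0,
                           init = list(occupancy = 0, n = n0))
    keep <- tr$time <= t_obs
    if (!any(keep)) n0 else tr$n[max(which(keep))]
  }, numeric(1))
  expected <- n0 * exp(-deg_rate(pars) * t_obs)
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - expected), 3 * se + 1e-9)
})

test_that("long-run mean approaches the fixed point in the fast-promoter limit", {
  # When the promoter ladder is much faster than synthesis/degradation
  # (p, q scaled up together, which leaves the regulatory function and the
  # fixed point untouched), promoter noise averages out and the stochastic
  # time-average converges to the deterministic fixed point.
  pars_fast <- circuit_params(N = 3, p = 1.7e-3 * 100, q = 75, eps = 9,
                              a0 = 0.075, g0 = 0.3)
  fp <- find_fixed_point(pars_fast)
  expect_equal(fp$c_star, find_fixed_point(ref_params(eps = 9))$c_star,
               tolerance = 1e-10)   # same fixed point as the slow ladder
  mat <- simulate_batch(pars_fast, n_real = 4, dt = 0.5, n_samples = 4000,
                        burn_in = 100, seed = 8)
  expect_equal(mean(mat), fp$c_star, tolerance = 0.02)
})

test_that("resampling holds the last value and preserves time averages", {
  # constant trajectory stays constant
  tr <- tibble::tibble(time = c(0, 10), occupancy = c(1L, 1L), n = c(5L, 5L))
  rs <- resample(tr, dt = 2)
  expect_equal(rs$n, rep(5L, 5))
  # single event: value switches at the first grid point at/after the event
  tr1 <- tibble::tibble(time = c(0, 5, 6), occupancy = c(0L, 0L, 0L),
                        n = c(0L, 1L, 1L))
  rs1 <- resample(tr1, dt = 2)
  expect_equal(rs1$time, c(2, 4, 6))
  expect_equal(rs1$n, c(0L, 0L, 1L))
  expect_error(resample(tr1, dt = 10), "duration")
  # time-average of the resampled series matches the event-weighted average
  pars <- ref_params(eps = 9)
  traj <- simulate_circuit(pars, t_end = 600, seed = 12, burn_in = 100)
  dt <- 0.05
  rs2 <- resample(traj, dt = dt)
  holds <- diff(c(traj$time, max(traj$time)))
  exact <- sum(traj$n * holds) / sum(holds)
  expect_equal(mean(rs2$n), exact, tolerance = 0.02)
})

test_that("stochastic trajectories at the reference point are oscillatory", {
  pars <- ref_params(eps = 9)
  traj <- simulate_circuit(pars, t_end = 1000, seed = 4, burn_in = 200)
  # excursions alternate between near-empty and high-copy episodes
  expect_lt(min(traj$n), 15)
  expect_gt(max(traj$n), 100)
  # the resampled series crosses its mean many times over 800 min
  rs <- resample(traj, dt = 0.5)
  dev <- rs$n - mean(rs$n)
  crossings <- sum(diff(sign(dev[dev != 0])) != 0)
  expect_gt(crossings, 40)
})
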