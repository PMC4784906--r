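test_that("empty promoter with no repressor only synthesizes", {
  pars <- ref_params()
  d <- circuit_rhs(c(1, 0, 0, 0, 0), pars)
  expect_equal(d, c(0, 0, 0, 0, syn_rate_counts(pars)))
})

test_that("fixed point solves the rate equations to high precision", {
  for (eps in c(1, 2, 9)) {
    for (lam in c(0.5, 1, 4)) {
      fp <- find_fixed_point(ref_params(eps = eps, lambda = lam))
      resid <- circuit_rhs(c(fp$phi_star, fp$c_star), fp$params)
      expect_lt(max(abs(resid)), 1e-10)
      expect_equal(sum(fp$phi_star), 1, tolerance = 1e-12)
      expect_true(all(fp$phi_star >= 0))
      expect_gte(fp$c_star, 0)
    }
  }
})

test_that("fixed point limits: no synthesis, and unbinding-dominated", {
  fp0 <- find_fixed_point(ref_params(a0 = 0))
  expect_equal(fp0$c_star, 0)
  expect_equal(unname(fp0$phi_star[1]), 1)

  fast_q <- circuit_params(N = 3, p = 1.7e-3, q = 1e7, eps = 9,
                           a0 = 0.075, g0 = 0.3)
  fp <- find_fixed_point(fast_q)
  expect_equal(unname(fp$phi_star[1]), 1, tolerance = 1e-5)
  expect_equal(fp$c_star, syn_rate_counts(fast_q) / deg_rate(fast_q),
               tolerance = 1e-5)
})

test_that("scalar ladder reduction agrees with a full-system Newton solve", {
  pars <- ref_params(eps = 9)
  N <- pars$N
  # Newton on the full system with the conservation constraint replacing the
  # first promoter equation; Jacobian by central differences (independent of
  # the package's analytic one).
  fun <- function(x) {
    r <- circuit_rhs(x, pars)
    c(sum(x[1:(N + 1)]) - 1, r[-1])
  }
  x <- c(rep(1 / (N + 1), N + 1), syn_rate_counts(pars) / deg_rate(pars) / 2)
  for (it in 1:50) {
    Jn <- matrix(0, N + 2, N + 2)
    h <- 1e-7
    for (j in seq_len(N + 2)) {
      e <- numeric(N + 2); e[j] <- h
      Jn[, j] <- (fun(x + e) - fun(x - e)) / (2 * h)
    }
    step <- solve(Jn, fun(x))
    x <- x - step
    if (max(abs(step)) < 1e-12) break
  }
  fp <- find_fixed_point(pars)
  expect_equal(x[N + 2], fp$c_star, tolerance = 1e-8)
  expect_equal(x[1:(N + 1)], unname(fp$phi_star), tolerance = 1e-8)
})

test_that("analytic Jacobian matches central differences on random states", {
  set.seed(21)
  for (N in c(1, 3)) {
    pars <- ref_params(N = N, eps = 5)
    st <- random_state(N)
    J <- circuit_jacobian(st, pars)
    h <- 1e-6
    Jn <- matrix(0, N + 2, N + 2)
    for (j in seq_len(N + 2)) {
      e <- numeric(N + 2); e[j] <- h
      Jn[, j] <- (circuit_rhs(st + e, pars) - circuit_rhs(st - e, pars)) / (2 * h)
    }
    expect_equal(J, Jn, tolerance = 1e-6)
  }
})

test_that("reference point is a stable focus whose damped frequency is 0.373", {
  fp <- find_fixed_point(ref_params(eps = 9))
  expect_identical(fp$stability_class, "stable_focus")
  ev <- fp$eigenvalues
  expect_true(all(Re(ev[abs(ev) > 1e-9 * max(abs(ev))]) < 0))
  expect_equal(max(Im(ev)), 0.3727175, tolerance = 1e-6)
  # all swept parameter ranges keep the fixed point attracting
  for (eps in c(1, 2, 9)) for (lam in c(0.5, 2, 16)) for (N in c(3, 5)) {
    fpx <- find_fixed_point(ref_params(eps = eps, lambda = lam, N = N))
    evx <- fpx$eigenvalues
    expect_true(all(Re(evx[abs(evx) > 1e-9 * max(abs(evx))]) < 0))
  }
})

test_that("stability classification handles crafted spectra", {
  expect_identical(classify_stability(c(-1, -1, -1)), "stable_node")
  expect_identical(classify_stability(c(1i, -1i)), "degenerate")
  expect_identical(classify_stability(c(0.1 + 1i, 0.1 - 1i, -2)), "unstable")
  expect_identical(classify_stability(c(-0.2 + 1i, -0.2 - 1i, -3)),
                   "stable_focus")
})

test_that("integration conserves probability and stays non-negative", {
  traj <- integrate_circuit(ref_params(eps = 9), t_end = 300, dt = 0.5)
  phisum <- rowSums(traj[, paste0("phi", 0:3)])
  expect_lt(max(abs(phisum - 1)), 1e-8)
  expect_gt(min(as.matrix(traj[, -1])), -1e-8)
})

test_that("strong cooperativity gives a damped oscillation into the focus", {
  pars <- ref_params(eps = 9)
  fp <- find_fixed_point(pars)
  traj <- integrate_circuit(pars, t_end = 400, dt = 0.2)
  dev <- traj$n - fp$c_star
  crossings <- sum(diff(sign(dev[dev != 0])) != 0)
  expect_gt(crossings, 4)                   # several over/undershoots
  # and converges to the located fixed point
  expect_equal(tail(traj$n, 1), fp$c_star, tolerance = 1e-6)
  expect_equal(unlist(tail(traj[, 2:5], 1)), unname(fp$phi_star),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("weak cooperativity relaxes with far fewer repressor overshoots", {
  pars <- ref_params(eps = 2)
  fp <- find_fixed_point(pars)
  traj <- integrate_circuit(pars, t_end = 400, dt = 0.2)
  dev9 <- integrate_circuit(ref_params(eps = 9), t_end = 400, dt = 0.2)$n -
    find_fixed_point(ref_params(eps = 9))$c_star
  dev2 <- traj$n - fp$c_star
  n_cross <- function(d) sum(diff(sign(d[abs(d) > 1e-9])) != 0)
  expect_lt(n_cross(dev2), n_cross(dev9))
  expect_equal(tail(traj$n, 1), fp$c_star, tolerance = 1e-6)
})

test_that("a trajectory started at the fixed point stays there", {
  pars <- ref_params(eps = 9)
  fp <- find_fixed_point(pars)
  traj <- integrate_circuit(pars, t_end = 50, dt = 1,
                            init = c(fp$phi_star, fp$c_star))
  expect_lt(max(abs(traj$n - fp$c_star)), 1e-6)
})
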