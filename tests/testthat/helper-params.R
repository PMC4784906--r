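# Reference parameter sets used throughout the suite.

# The main working point (three sites, strong cooperativity, 1 fL volume).
ref_params <- function(eps = 9, lambda = 1, N = 3, a0 = 0.075, g0 = 0.3) {
  circuit_params(N = N, p = 1.7e-3, q = 0.75, eps = eps,
                 a0 = a0, g0 = g0, lambda = lambda, omega = 1e-15)
}

# Hand-coded three-site rate equations, written term by term, independent of
# the matrix assembly in the package (oracle for circuit_rhs).
rhs_three_site_by_hand <- function(state, params) {
  stopifnot(params$N == 3)
  k01 <- params$p * 3
  k12 <- params$eps * params$p * 2
  k23 <- params$eps^2 * params$p
  k10 <- params$q; k21 <- 2 * params$q; k32 <- 3 * params$q
  a <- syn_rate_counts(params); g <- deg_rate(params)
  f0 <- state[1]; f1 <- state[2]; f2 <- state[3]; f3 <- state[4]; cc <- state[5]
  c(
    -k01 * f0 * cc + k10 * f1,
    -k12 * f1 * cc - k10 * f1 + k01 * f0 * cc + k21 * f2,
    -k23 * f2 * cc - k21 * f2 + k12 * f1 * cc + k32 * f3,
    -k32 * f3 + k23 * f2 * cc,
    a * f0 - g * cc + k10 * f1 + k21 * f2 + k32 * f3 -
      cc * (k01 * f0 + k12 * f1 + k23 * f2)
  )
}

random_state <- function(N) {
  phi <- runif(N + 1)
  c(phi / sum(phi), runif(1, 0, 200))
}
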