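#' Reaction propensities for a discrete circuit state
#'
#' Propensities (events per minute) of the `2N + 2` reactions for a promoter
#' occupancy `i` and free-repressor copy number `n`: binding from state `i`
#' proceeds at `kon[i + 1] * n` (zero unless the promoter is in state `i`),
#' unbinding from `i` at `koff[i]`, synthesis at `a * Phi` only from the empty
#' promoter, degradation at `g * n`.
#'
#' @param occupancy Promoter state, integer in `0:N`.
#' @param n Free repressor copy number, integer >= 0.
#' @param params A [circuit_params()] object.
#' @return A tibble with columns `reaction` and `propensity`.
#' @examples
#' propensities(0, 0, circuit_params())  # only synthesis is active
#' @export
propensities <- function(occupancy, n, params) {
  stopifnot(inherits(params, "circuit_params"),
            "occupancy must be in 0:N" =
              length(occupancy) == 1 && occupancy %in% 0:params$N,
            "n must be a non-negative integer" =
              length(n) == 1 && n >= 0 && n == round(n))
  N <- params$N
  kon <- kon_vec(params)
  koff <- koff_vec(params)
  a <- numeric(2 * N + 2)
  s <- seq_len(N)
  a[2 * s - 1] <- ifelse(occupancy == s - 1, kon[s] * n, 0)
  a[2 * s] <- ifelse(occupancy == s, koff[s], 0)
  a[2 * N + 1] <- if (occupancy == 0) syn_rate_counts(params) else 0
  a[2 * N + 2] <- deg_rate(params) * n
  net_names <- c(rbind(paste0("bind", s), paste0("unbind", s)),
                 "synthesis", "degradation")
  tibble::tibble(reaction = net_names, propensity = a)
}

default_initial_counts <- function(params) {
  fp <- find_fixed_point(params)
  list(occupancy = 0L, n = as.integer(round(fp$c_star)))
}

#' Exact stochastic simulation of the circuit (Gillespie direct method)
#'
#' Event-driven simulation of the `2N + 2` reactions in molecule counts with a
#' single promoter copy. Binding consumes one free repressor and unbinding
#' releases one, exactly as in the stoichiometric matrix. The default initial
#' state (promoter empty, repressor at the deterministic fixed point) together
#' with the burn-in removes the relaxation transient.
#'
#' @param params A [circuit_params()] object.
#' @param t_end Total simulated time, min.
#' @param seed Optional RNG seed for reproducibility.
#' @param burn_in Time discarded before recording, min.
#' @param init Optional list with `occupancy` and `n`.
#' @param max_events Safety cap on simulated events.
#' @return A tibble of class `circuit_ssa` with one row per recorded event:
#'   `time`, `occupancy`, `n`, `reaction` (index into the network's reaction
#'   ordering).
#' @examples
#' traj <- simulate_circuit(circuit_params(N = 3, eps = 9),
#'                          t_end = 250, seed = 1, burn_in = 200)
#' @export
simulate_circuit <- function(params, t_end, seed = NULL, burn_in = 200,
                             init = NULL, max_events = 5e7) {
  stopifnot(inherits(params, "circuit_params"),
            "need t_end > burn_in >= 0" = t_end > burn_in && burn_in >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- default_initial_counts(params)
  res <- ssa_events_cpp(kon_vec(params), koff_vec(params),
                        syn_rate_counts(params), deg_rate(params),
                        as.integer(init$occupancy), as.integer(init$n),
                        t_end, burn_in, as.integer(max_events))
  out <- tibble::tibble(time = res$time,
                        occupancy = res$occupancy,
                        n = res$n,
                        reaction = res$reaction)
  class(out) <- c("circuit_ssa", class(out))
  attr(out, "params") <- params
  attr(out, "burn_in") <- burn_in
  attr(out, "seed") <- seed
  out
}

#' Resample an event-resolved trajectory onto a uniform grid
#'
#' Zero-order hold (right-continuous step interpolation): the value on each
#' grid point is the state after the most recent event at or before it.
#'
#' @param trajectory A [simulate_circuit()] result (or any tibble with `time`
#'   plus value columns).
#' @param dt Sampling interval, min (must not exceed the record duration).
#' @param from Start of the grid; defaults to the first recorded time.
#' @return A tibble with `time` and the held `occupancy` and `n` columns.
#' @export
resample <- function(trajectory, dt, from = NULL) {
  stopifnot("dt must be positive" = dt > 0,
            "trajectory must be non-empty" = nrow(trajectory) > 0)
  t0 <- if (is.null(from)) trajectory$time[1] else from
  duration <- max(trajectory$time) - t0
  if (dt > duration) stop("dt exceeds the trajectory duration")
  grid <- t0 + dt * seq_len(floor(duration / dt))
  idx <- findInterval(grid, trajectory$time)
  idx[idx == 0L] <- 1L
  tibble::tibble(time = grid,
                 occupancy = trajectory$occupancy[idx],
                 n = trajectory$n[idx])
}

#' Batch of grid-sampled stochastic realizations
#'
#' Runs `n_real` independent realizations and records the repressor copy
#' number on a uniform grid by zero-order hold (no event log is kept), the
#' form needed for averaged-periodogram spectral estimation.
#'
#' @inheritParams simulate_circuit
#' @param n_real Number of realizations.
#' @param dt Sampling interval, min.
#' @param n_samples Samples per realization (default 4096 at `dt = 0.2`,
#'   i.e. 819.2 min of recording per realization).
#' @return A numeric matrix with `n_samples` rows and `n_real` columns.
#' @export
simulate_batch <- function(params, n_real, dt = 0.2, n_samples = 4096,
                           burn_in = 200, seed = NULL, init = NULL) {
  stopifnot(inherits(params, "circuit_params"),
            n_real >= 1, dt > 0, n_samples >= 16)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- default_initial_counts(params)
  ssa_grid_cpp(kon_vec(params), koff_vec(params),
               syn_rate_counts(params), deg_rate(params),
               as.integer(init$occupancy), as.integer(init$n),
               dt, as.integer(n_samples), burn_in, as.integer(n_real))
}

#' Promoter occupancy with the repressor pool frozen
#'
#' Simulates only the binding/unbinding ladder at a fixed free-repressor copy
#' number (synthesis and degradation disabled, binding does not deplete the
#' pool), sampling the occupancy on a uniform grid. Used to validate the
#' analytic stationary ladder distribution.
#'
#' @inheritParams simulate_circuit
#' @param n_frozen Fixed repressor copy number.
#' @param dt Sampling interval, min.
#' @param n_samples Number of samples.
#' @return Integer vector of sampled occupancies.
#' @export
simulate_frozen_ladder <- function(params, n_frozen, dt = 5, n_samples = 2000,
                                   burn_in = 50, seed = NULL) {
  stopifnot(inherits(params, "circuit_params"), n_frozen >= 0)
  if (!is.null(seed)) set.seed(seed)
  as.integer(ssa_frozen_cpp(kon_vec(params), koff_vec(params),
                            as.integer(n_frozen), 0L, dt,
                            as.integer(n_samples), burn_in))
}
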