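#' Deterministic right-hand side of the rate equations
#'
#' Evaluates `S %*% f(state)` for the full `N + 2` dimensional system: the
#' promoter-state fractions exchange probability along the binding/unbinding
#' ladder (binding flux `kon[s] * phi[s-1] * c`), and the repressor gains
#' `a * phi_0` from synthesis, loses `g * c` to degradation, and exchanges one
#' molecule with the promoter per (un)binding event. The repressor coordinate
#' is in molecule counts; promoter coordinates are occupancy fractions.
#'
#' @param state Numeric vector `(phi_0, ..., phi_N, c)`.
#' @param params A [circuit_params()] object.
#' @return The time derivative, same length as `state`.
#' @export
circuit_rhs <- function(state, params) {
  net <- build_network(params)
  stopifnot("state must have N + 2 entries" = length(state) == params$N + 2)
  as.numeric(net$stoich %*% net$rate_fn(state))
}

default_initial_state <- function(params) {
  c(1, rep(0, params$N), 0)
}

#' Integrate the deterministic rate equations
#'
#' Stiff-capable integration (deSolve, lsoda) of the full promoter-ladder
#' system on a uniform reporting grid. The default initial condition is the
#' empty promoter with no repressor.
#'
#' @param params A [circuit_params()] object.
#' @param t_end Final time, min.
#' @param dt Reporting interval, min.
#' @param init Initial state `(phi_0, ..., phi_N, c)`; default empty promoter.
#' @param rtol,atol Integrator tolerances.
#' @return A tibble of class `circuit_ode` with columns `time`,
#'   `phi0 ... phiN` and `n` (repressor copy number).
#' @examples
#' traj <- integrate_circuit(circuit_params(N = 3, eps = 9), t_end = 200)
#' @export
integrate_circuit <- function(params, t_end, dt = 0.5,
                              init = default_initial_state(params),
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "circuit_params"),
            "t_end must be positive" = t_end > 0,
            "init must have N + 2 entries" = length(init) == params$N + 2)
  net <- build_network(params)
  S <- net$stoich
  deriv <- function(t, y, p) list(as.numeric(S %*% net$rate_fn(y)))
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::lsoda(y = init, times = times, func = deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE integration failed: ", paste(attr(sol, "istate"), collapse = " "))
  }
  out <- tibble::as_tibble(as.data.frame(unclass(sol)))
  names(out) <- c("time", paste0("phi", 0:params$N), "n")
  class(out) <- c("circuit_ode", class(out))
  attr(out, "params") <- params
  out
}

#' Deterministic fixed point of the circuit
#'
#' At steady state each binding/unbinding flux on the ladder balances in
#' detail, so the promoter distribution conditional on the repressor level `c`
#' is `phi_i(c) = phi_0 * prod_{j<=i} kon[j] * c / koff[j]`, and the net
#' binding fluxes cancel in the repressor balance. The fixed point therefore
#' solves the scalar equation `a * phi_0(c) - g * c = 0`, bracketed on
#' `(0, a/g]`, after which the Jacobian spectrum classifies stability.
#'
#' @param params A [circuit_params()] object.
#' @param tol Root-finder tolerance on `c`.
#' @return An object of class `circuit_fixed_point`: a list with `phi_star`,
#'   `c_star` (molecule counts), `eigenvalues`, `stability_class` and `params`.
#' @examples
#' fp <- find_fixed_point(circuit_params(N = 3, eps = 9))
#' fp$stability_class
#' @export
find_fixed_point <- function(params, tol = 1e-14) {
  stopifnot(inherits(params, "circuit_params"))
  a_n <- syn_rate_counts(params)
  g <- deg_rate(params)
  kon <- kon_vec(params)
  koff <- koff_vec(params)

  phi_of_c <- function(cc) {
    w <- cumprod(kon * cc / koff)
    phi0 <- 1 / (1 + sum(w))
    c(phi0, phi0 * w)
  }
  resid <- function(cc) a_n * phi_of_c(cc)[1] - g * cc

  c_star <- if (a_n == 0) 0 else {
    upper <- a_n / g
    if (resid(upper) >= 0) upper else {
      uniroot(resid, lower = 0, upper = upper, tol = tol)$root
    }
  }
  phi_star <- phi_of_c(c_star)
  state <- c(phi_star, c_star)
  J <- circuit_jacobian(state, params)
  ev <- eigen(J, only.values = TRUE)$values

  structure(
    list(phi_star = setNames(phi_star, paste0("phi", 0:params$N)),
         c_star = c_star,
         eigenvalues = ev,
         stability_class = classify_stability(ev),
         params = params),
    class = "circuit_fixed_point"
  )
}

#' Analytic Jacobian of the rate equations
#'
#' `J = S %*% dF/dx` where the only nonlinear entries come from the bilinear
#' binding rates `kon[s] * phi[s-1] * c`.
#'
#' @param state State vector `(phi_0, ..., phi_N, c)` in count units.
#' @param params A [circuit_params()] object.
#' @return The `(N+2) x (N+2)` Jacobian matrix.
#' @export
circuit_jacobian <- function(state, params) {
  stopifnot(inherits(params, "circuit_params"),
            "state must have N + 2 entries" = length(state) == params$N + 2)
  N <- params$N
  kon <- kon_vec(params)
  koff <- koff_vec(params)
  phi <- state[seq_len(N + 1)]
  cc <- state[N + 2]
  G <- matrix(0, nrow = 2 * N + 2, ncol = N + 2)
  for (s in seq_len(N)) {
    G[2 * s - 1, s] <- kon[s] * cc
    G[2 * s - 1, N + 2] <- kon[s] * phi[s]
    G[2 * s, s + 1] <- koff[s]
  }
  G[2 * N + 1, 1] <- syn_rate_counts(params)
  G[2 * N + 2, N + 2] <- deg_rate(params)
  net <- build_network(params)
  unname(net$stoich %*% G)
}

#' Classify the stability of a fixed point from its eigenvalues
#'
#' A stable focus has all real parts negative with a genuinely complex pair
#' (damped oscillation); a stable node has all real parts negative and a
#' purely real spectrum; any positive real part is unstable; real parts on the
#' imaginary axis (within tolerance) are degenerate. One zero eigenvalue along
#' the promoter-probability conservation direction is always present and is
#' discounted before classification.
#'
#' @param eigenvalues Complex eigenvalue vector of the Jacobian.
#' @param tol_rel Scale-free tolerance relative to the spectral radius.
#' @return One of `"stable_focus"`, `"stable_node"`, `"unstable"`,
#'   `"degenerate"`.
#' @export
classify_stability <- function(eigenvalues, tol_rel = 1e-9) {
  scale <- max(abs(eigenvalues), 1e-300)
  tol <- tol_rel * scale
  # drop the structural zero mode (promoter conservation)
  keep <- abs(eigenvalues) > tol
  ev <- eigenvalues[keep]
  if (length(ev) == 0) return("degenerate")
  re <- Re(ev); im <- Im(ev)
  if (any(re > tol)) return("unstable")
  if (any(abs(re) <= tol)) return("degenerate")
  if (any(abs(im) > tol)) "stable_focus" else "stable_node"
}

#' @export
print.circuit_fixed_point <- function(x, ...) {
  cat("<circuit_fixed_point>\n")
  cat(sprintf("  c* = %.4f molecules (%.5f uM), class: %s\n",
              x$c_star, x$c_star / counts_per_micromolar(x$params$omega),
              x$stability_class))
  cat("  phi* =", paste(sprintf("%.4f", x$phi_star), collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.circuit_fixed_point <- function(x, ...) {
  tibble::tibble(
    species = c(names(x$phi_star), "c"),
    value = c(unname(x$phi_star), x$c_star)
  )
}

#' @export
glance.circuit_fixed_point <- function(x, ...) {
  ev <- x$eigenvalues
  keep <- abs(ev) > 1e-9 * max(abs(ev))
  lead <- ev[keep][which.max(Re(ev[keep]))]
  tibble::tibble(
    c_star = x$c_star,
    phi0_star = unname(x$phi_star[1]),
    stability_class = x$stability_class,
    re_leading = Re(lead),
    im_leading = abs(Im(lead)),
    eigenfrequency = max(Im(ev)),
    damped_period = if (max(Im(ev)) > 0) 2 * pi / max(Im(ev)) else NA_real_
  )
}
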