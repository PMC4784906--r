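#' Diffusion matrix of the linear noise approximation
#'
#' `D = S %*% diag(f) %*% t(S)` evaluated at the fixed point, with the
#' per-reaction rates `f` in events per minute (count units). `D` is symmetric
#' positive semidefinite by construction; the promoter rows share a left null
#' vector with the Jacobian (probability conservation carries no noise).
#'
#' @param fixed_point A [find_fixed_point()] result.
#' @return The `(N+2) x (N+2)` diffusion matrix.
#' @export
diffusion_matrix <- function(fixed_point) {
  stopifnot(inherits(fixed_point, "circuit_fixed_point"))
  params <- fixed_point$params
  net <- build_network(params)
  f <- net$rate_fn(c(fixed_point$phi_star, fixed_point$c_star))
  S <- net$stoich
  unname(S %*% (f * t(S)))
}

default_omega_grid <- function() seq(0.001, 5, by = 0.001)

#' Fluctuation power spectrum in the linear noise approximation
#'
#' Evaluates the closed-form stationary spectrum of fluctuations about a
#' stable fixed point,
#' `S_i(w) = (Phi/pi) * [(-J + i w I)^-1 D (-J' - i w I)^-1]_(ii)`,
#' where `Phi` is the molecules-per-uM volume factor and `D` the diffusion
#' matrix. Two noise conventions are available:
#'
#' * `"expression"` (default): only the repressor synthesis and degradation
#'   reactions contribute shot noise (`D` restricted to the repressor
#'   coordinate). For a single-copy promoter the Gaussian treatment of the
#'   binary promoter state badly misrepresents its noise; suppressing those
#'   channels is the convention under which the spectra and phase diagrams of
#'   this mechanism study reproduce (see the methods vignette).
#' * `"full"`: the complete `D = S diag(f) S'`, i.e. the textbook linear
#'   noise approximation with every reaction contributing.
#'
#' Both conventions coincide for a plain birth-death process (no binding
#' sites), where the spectrum is the Lorentzian `(Phi/pi) * 2a/(g^2 + w^2)`.
#'
#' @param fixed_point A [find_fixed_point()] result; must be stable.
#' @param omega_grid Angular frequency grid, rad min^-1 (default 0.001-5 by
#'   0.001, covering all reported peaks).
#' @param species Species index for the diagonal entry (default `N + 2`,
#'   the repressor).
#' @param noise `"expression"` or `"full"` (see above).
#' @param normalize Divide by the trapezoid integral over the grid so the
#'   spectrum integrates to 1.
#' @return A tibble of class `circuit_spectrum` with columns `omega` and
#'   `power`, and attributes `species`, `source = "lna"`, `normalized`.
#' @examples
#' fp <- find_fixed_point(circuit_params(N = 3, eps = 9))
#' spec <- lna_spectrum(fp)
#' find_peak(spec)
#' @export
lna_spectrum <- function(fixed_point, omega_grid = default_omega_grid(),
                         species = NULL,
                         noise = c("expression", "full"),
                         normalize = FALSE) {
  stopifnot(inherits(fixed_point, "circuit_fixed_point"))
  noise <- match.arg(noise)
  params <- fixed_point$params
  n <- params$N + 2
  if (is.null(species)) species <- n
  stopifnot("species index out of range" = species >= 1 && species <= n)

  J <- circuit_jacobian(c(fixed_point$phi_star, fixed_point$c_star), params)
  ev <- fixed_point$eigenvalues
  keep <- abs(ev) > 1e-9 * max(abs(ev))
  if (any(Re(ev[keep]) >= 0)) {
    stop("fixed point is not stable (", fixed_point$stability_class,
         "); the stationary LNA spectrum is undefined")
  }
  D <- diffusion_matrix(fixed_point)
  if (noise == "expression") {
    Dn <- matrix(0, n, n)
    Dn[n, n] <- D[n, n]
    D <- Dn
  }
  power <- lna_psd(J, D, omega_grid, species = species,
                   prefactor = counts_per_micromolar(params$omega) / pi)
  new_spectrum(omega_grid, power, species = species, source = "lna",
               normalized = normalize)
}

#' Stationary power spectral density of a linear SDE
#'
#' Low-level evaluator of
#' `S_i(w) = prefactor * [(-J + i w I)^-1 D (-J' - i w I)^-1]_(ii)`
#' for a stationary Ornstein-Uhlenbeck process with drift `J` and diffusion
#' `D`. The bracketed matrix is Hermitian positive semidefinite, so the
#' diagonal entry is real and non-negative. For the scalar birth-death
#' process (`J = -g`, `D = 2a`) this is the Lorentzian
#' `prefactor * 2a / (g^2 + w^2)`.
#'
#' @param J Square drift (Jacobian) matrix.
#' @param D Diffusion matrix, same dimension.
#' @param omega_grid Angular frequencies, rad min^-1.
#' @param species Diagonal index to report.
#' @param prefactor Overall scale (default `1/pi`).
#' @return Numeric vector of spectral densities on `omega_grid`.
#' @export
lna_psd <- function(J, D, omega_grid, species = nrow(J), prefactor = 1 / pi) {
  J <- as.matrix(J); D <- as.matrix(D)
  stopifnot(nrow(J) == ncol(J), all(dim(D) == dim(J)),
            species >= 1, species <= nrow(J))
  I_n <- diag(nrow(J))
  vapply(omega_grid, function(w) {
    Mi <- solve(-J + 1i * w * I_n)
    Re((Mi %*% D %*% Conj(t(Mi)))[species, species])
  }, numeric(1)) * prefactor
}

new_spectrum <- function(omega, power, species, source, normalized) {
  if (normalized) {
    total <- trapezoid(omega, power)
    power <- power / total
  }
  out <- tibble::tibble(omega = omega, power = power)
  class(out) <- c("circuit_spectrum", class(out))
  attr(out, "species") <- species
  attr(out, "source") <- source
  attr(out, "normalized") <- normalized
  out
}

trapezoid <- function(x, y) {
  sum(diff(x) * (y[-1] + y[-length(y)])) / 2
}
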