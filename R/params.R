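#' Circuit parameter set
#'
#' Bundles the kinetic parameters of the N-site autorepressive circuit.
#' Binding and unbinding constants act per repressor molecule; the synthesis
#' rate is specified as a concentration flux and converted to molecules per
#' minute through the cell volume (see [counts_per_micromolar()]). The
#' synthesis/degradation time-scale can be swept jointly through `lambda`
#' without moving the fixed point: the effective rates are
#' `a = lambda * a0` and `g = lambda * g0`.
#'
#' @param N Number of repressor binding sites (integer, >= 1).
#' @param p Binding rate constant for an empty site, molecule^-1 min^-1
#'   (numerically equal to the published (uM min)^-1 value; see the methods
#'   vignette for the unit convention).
#' @param q Unbinding rate constant per bound repressor, min^-1.
#' @param eps Cooperativity intensity: each already-bound repressor multiplies
#'   subsequent binding rates by `eps`. `eps = 1` means independent sites.
#' @param a0 Base synthesis rate, uM min^-1 (active only while the promoter is
#'   completely free of repressor).
#' @param g0 Base degradation rate, min^-1.
#' @param lambda Joint scaling of synthesis and degradation, dimensionless.
#' @param omega Cell volume, litres.
#'
#' @return An object of class `circuit_params`.
#' @examples
#' pars <- circuit_params(N = 3, eps = 9)
#' syn_rate(pars)   # lambda * a0
#' deg_rate(pars)   # lambda * g0
#' @export
circuit_params <- function(N = 3, p = 1.7e-3, q = 0.75, eps = 9,
                           a0 = 0.075, g0 = 0.3, lambda = 1,
                           omega = 1e-15) {
  stopifnot(
    "N must be a single integer >= 1" =
      length(N) == 1 && is.finite(N) && N >= 1 && N == round(N),
    "p, q, g0, lambda, omega must be single positive numbers" =
      all(vapply(list(p, q, g0, lambda, omega),
                 function(x) length(x) == 1 && is.finite(x) && x > 0,
                 logical(1))),
    "a0 must be a single non-negative number (0 switches synthesis off)" =
      length(a0) == 1 && is.finite(a0) && a0 >= 0,
    "eps must be a single positive number" =
      length(eps) == 1 && is.finite(eps) && eps > 0
  )
  structure(
    list(N = as.integer(N), p = p, q = q, eps = eps,
         a0 = a0, g0 = g0, lambda = lambda, omega = omega),
    class = "circuit_params"
  )
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<circuit_params>\n")
  cat(sprintf("  N = %d binding sites, eps = %g%s\n", x$N, x$eps,
              if (x$eps == 1) " (no cooperativity)" else ""))
  cat(sprintf("  p = %g /molecule/min, q = %g /min\n", x$p, x$q))
  cat(sprintf("  a = %g uM/min, g = %g /min (lambda = %g)\n",
              syn_rate(x), deg_rate(x), x$lambda))
  cat(sprintf("  omega = %g L  (%.3f molecules per uM)\n",
              x$omega, counts_per_micromolar(x$omega)))
  invisible(x)
}

#' Effective synthesis and degradation rates
#'
#' `syn_rate()` returns `lambda * a0` (uM min^-1) and `deg_rate()` returns
#' `lambda * g0` (min^-1). `syn_rate_counts()` converts the synthesis flux to
#' molecules per minute for the configured volume.
#'
#' @param params A [circuit_params()] object.
#' @return A single number.
#' @export
syn_rate <- function(params) params$lambda * params$a0

#' @rdname syn_rate
#' @export
deg_rate <- function(params) params$lambda * params$g0

#' @rdname syn_rate
#' @export
syn_rate_counts <- function(params) {
  syn_rate(params) * counts_per_micromolar(params$omega)
}

#' Molecules per micromolar for a given volume
#'
#' Conversion factor between concentrations (uM) and molecule copy numbers:
#' `N_Avogadro * omega * 1e-6`. For the reference cell volume of 1 fL this is
#' about 602.2 molecules per uM.
#'
#' @param omega Volume in litres (> 0).
#' @return Molecules per uM.
#' @examples
#' counts_per_micromolar(1e-15)
#' @export
counts_per_micromolar <- function(omega) {
  stopifnot("omega must be a single positive number" =
              length(omega) == 1 && is.finite(omega) && omega > 0)
  6.02214076e23 * omega * 1e-6
}
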