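#' Phase-diagram sweep over cooperativity and synthesis/degradation time-scale
#'
#' For every `(eps, lambda)` grid cell the pipeline is
#' [find_fixed_point()] then [lna_spectrum()] then [q90()]. Because `a` and
#' `g` scale jointly with `lambda`, the fixed point (and the regulatory
#' function) is identical along the `lambda` axis; only the fluctuation
#' spectrum changes. Cells whose spectrum has no interior peak, or whose
#' spectral floor exceeds 90 percent of the peak, carry `NA` in the
#' `omega_hat` / `q90` columns — an explicit "no clear oscillation" outcome,
#' never encoded as 0.
#'
#' @param params Base [circuit_params()]; its `eps` and `lambda` are replaced
#'   cell by cell.
#' @param eps_grid Cooperativity values (default brackets 1 through 9).
#' @param lam_grid Time-scale values (default 0.5 through 16).
#' @param omega_grid Frequency grid passed to [lna_spectrum()].
#' @param noise Noise convention for [lna_spectrum()].
#' @return A tibble of class `circuit_sweep`, one row per cell: `eps`, `lam`,
#'   `stability_class`, `c_star`, `omega_hat`, `delta_omega`, `q90`, `period`.
#'   Cells where the pipeline fails are kept with `NA` results and the error
#'   message in `note`.
#' @examples
#' sw <- run_sweep(circuit_params(N = 3), eps_grid = c(2, 9), lam_grid = c(1, 2))
#' @export
run_sweep <- function(params,
                      eps_grid = c(1, 1.5, 2, 3, 5, 7, 9),
                      lam_grid = c(0.5, 0.75, 1, 1.25, 1.5, 2, 3, 4, 8, 16),
                      omega_grid = default_omega_grid(),
                      noise = c("expression", "full")) {
  stopifnot(inherits(params, "circuit_params"),
            length(eps_grid) >= 1, length(lam_grid) >= 1)
  noise <- match.arg(noise)
  grid <- tidyr::expand_grid(eps = eps_grid, lam = lam_grid)
  cells <- purrr::pmap(grid, function(eps, lam) {
    tryCatch({
      pars <- circuit_params(N = params$N, p = params$p, q = params$q,
                             eps = eps, a0 = params$a0, g0 = params$g0,
                             lambda = lam, omega = params$omega)
      fp <- find_fixed_point(pars)
      summ <- q90(lna_spectrum(fp, omega_grid = omega_grid, noise = noise))
      tibble::tibble(stability_class = fp$stability_class,
                     c_star = fp$c_star,
                     omega_hat = summ$omega_hat,
                     delta_omega = summ$delta_omega,
                     q90 = summ$q90,
                     period = summ$period,
                     note = NA_character_)
    }, error = function(e) {
      tibble::tibble(stability_class = NA_character_, c_star = NA_real_,
                     omega_hat = NA_real_, delta_omega = NA_real_,
                     q90 = NA_real_, period = NA_real_,
                     note = conditionMessage(e))
    })
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(cells))
  class(out) <- c("circuit_sweep", class(out))
  attr(out, "params") <- params
  attr(out, "noise") <- noise
  out
}

#' Extract fixed-lambda slices from a sweep
#'
#' Returns the one-dimensional curves of `omega_hat` and `q90` against `eps`
#' at the requested `lambda` values.
#'
#' @param sweep A [run_sweep()] result.
#' @param lam_values Lambda values to extract.
#' @param strict If `TRUE`, off-grid values raise an error; otherwise the
#'   nearest grid value is used with a warning.
#' @return The matching sweep rows (possibly empty), ordered by `lam`, `eps`.
#' @export
sweep_slice <- function(sweep, lam_values, strict = FALSE) {
  stopifnot(inherits(sweep, "circuit_sweep"))
  if (length(lam_values) == 0) return(sweep[0, ])
  grid_lam <- sort(unique(sweep$lam))
  matched <- vapply(lam_values, function(l) {
    if (any(abs(grid_lam - l) < 1e-12)) return(l)
    if (strict) stop("lambda = ", l, " is not on the sweep grid")
    nearest <- grid_lam[which.min(abs(grid_lam - l))]
    warning("lambda = ", l, " is off-grid; using nearest cell lambda = ",
            nearest)
    nearest
  }, numeric(1))
  sweep |>
    dplyr::filter(.data$lam %in% matched) |>
    dplyr::arrange(.data$lam, .data$eps)
}
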