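#' Cooperative binding/unbinding rate ladder
#'
#' For a promoter with `N` identical sites, the binding constant for the
#' transition from `s - 1` to `s` bound repressors is
#' `kon[s] = eps^(s-1) * (N + 1 - s) * p` (free-site counting times the
#' cooperative enhancement by the `s - 1` repressors already bound), and the
#' reverse unbinding constant is `koff[s] = s * q`. With `eps = 1` the ladder
#' reduces to pure combinatorial site counting.
#'
#' @param params A [circuit_params()] object.
#' @return A tibble with one row per ladder step: `site` (the destination
#'   occupancy `s`), `kon` (molecule^-1 min^-1) and `koff` (min^-1).
#' @examples
#' rate_ladder(circuit_params(N = 3, eps = 9))
#' @export
rate_ladder <- function(params) {
  stopifnot(inherits(params, "circuit_params"))
  s <- seq_len(params$N)
  tibble::tibble(
    site = s,
    kon  = params$eps^(s - 1) * (params$N + 1 - s) * params$p,
    koff = s * params$q
  )
}

kon_vec <- function(params) rate_ladder(params)$kon
koff_vec <- function(params) rate_ladder(params)$koff

#' Reaction network of the N-site autorepressive circuit
#'
#' Assembles the `N + 2` species (promoter states `phi_0 ... phi_N`, then the
#' repressor `c`) and `2N + 2` reactions: for each ladder step a binding
#' reaction (consuming one free repressor) and an unbinding reaction
#' (releasing one), plus synthesis (active only from the empty promoter state)
#' and first-order degradation. Reactions are ordered
#' bind_1, unbind_1, ..., bind_N, unbind_N, synthesis, degradation.
#'
#' @param params A [circuit_params()] object.
#' @return An object of class `circuit_network` with elements `species`,
#'   `reactions`, `stoich` (the (N+2) x (2N+2) stoichiometric matrix),
#'   `kon`, `koff`, `rate_fn` (maps a state vector in count units — promoter
#'   fractions followed by repressor copy number — to the per-reaction rate
#'   vector, min^-1) and the originating `params`.
#' @examples
#' net <- build_network(circuit_params(N = 3))
#' net$stoich
#' @export
build_network <- function(params) {
  stopifnot(inherits(params, "circuit_params"))
  N <- params$N
  kon <- kon_vec(params)
  koff <- koff_vec(params)
  a_n <- syn_rate_counts(params)
  g <- deg_rate(params)

  species <- c(paste0("phi", 0:N), "c")
  reactions <- c(rbind(paste0("bind", seq_len(N)), paste0("unbind", seq_len(N))),
                 "synthesis", "degradation")

  S <- matrix(0L, nrow = N + 2, ncol = 2 * N + 2,
              dimnames = list(species, reactions))
  for (s in seq_len(N)) {
    jb <- 2L * s - 1L; ju <- 2L * s
    S[s, jb] <- -1L; S[s + 1L, jb] <- 1L; S[N + 2L, jb] <- -1L
    S[s, ju] <- 1L;  S[s + 1L, ju] <- -1L; S[N + 2L, ju] <- 1L
  }
  S[N + 2L, 2L * N + 1L] <- 1L
  S[N + 2L, 2L * N + 2L] <- -1L

  rate_fn <- function(state) {
    stopifnot("state must have N + 2 entries" = length(state) == N + 2)
    phi <- state[seq_len(N + 1)]
    cc <- state[N + 2]
    f <- numeric(2 * N + 2)
    s <- seq_len(N)
    f[2 * s - 1] <- kon * phi[s] * cc
    f[2 * s] <- koff * phi[s + 1]
    f[2 * N + 1] <- a_n * phi[1]
    f[2 * N + 2] <- g * cc
    setNames(f, reactions)
  }

  structure(
    list(species = species, reactions = reactions, stoich = S,
         kon = kon, koff = koff, rate_fn = rate_fn, params = params),
    class = "circuit_network"
  )
}

#' @export
print.circuit_network <- function(x, ...) {
  cat(sprintf("<circuit_network> %d species, %d reactions (N = %d)\n",
              length(x$species), length(x$reactions), x$params$N))
  invisible(x)
}

#' @export
tidy.circuit_network <- function(x, ...) {
  S <- x$stoich
  tibble::tibble(
    reaction = rep(colnames(S), each = nrow(S)),
    species = rep(rownames(S), times = ncol(S)),
    change = as.integer(S)
  ) |> dplyr::filter(.data$change != 0L)
}

#' Export a network summary as JSON
#'
#' Writes species, stoichiometry and the rate-constant table for inspection or
#' as a plain-text fixture.
#'
#' @param network A [build_network()] result.
#' @param path File path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
network_json <- function(network, path = NULL) {
  stopifnot(inherits(network, "circuit_network"))
  obj <- list(
    species = network$species,
    reactions = network$reactions,
    stoich = unname(apply(network$stoich, 1, as.integer, simplify = FALSE)),
    rate_constants = list(
      kon = network$kon, koff = network$koff,
      synthesis_per_min = syn_rate_counts(network$params),
      degradation_per_min = deg_rate(network$params)
    )
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
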