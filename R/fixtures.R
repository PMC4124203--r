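#' Ideal-gas (uniformly random) reference ensemble
#'
#' Generates configurations of independent uniform points with no hard
#' core: the reference system whose g(r) is identically 1 and against
#' which the RDF normalization is calibrated.
#'
#' @param N Particles per configuration.
#' @param box An [sq_box].
#' @param n Number of configurations.
#' @param seed RNG seed; output is reproducible from `(N, box, n, seed)`.
#' @return An \code{sq_ensemble} whose configurations have columns `x`,
#'   `y` (no regions or energies).
#' @export
ideal_gas_ensemble <- function(N, box, n = 1, seed = 1) {
  stopifnot(N >= 1, n >= 1)
  set.seed(as.integer(seed))
  configs <- lapply(seq_len(n), function(k)
    data.frame(x = runif(N, 0, box$side), y = runif(N, 0, box$side)))
  structure(configs, box = box, seed = as.integer(seed),
            generator = "ideal_gas", class = "sq_ensemble")
}

#' Square-lattice reference configuration
#'
#' Points on a square lattice with the given spacing; its RDF has peaks at
#' analytically known distances (spacing, spacing * sqrt(2), ...), which
#' makes it a convenient structured test input.
#'
#' @param spacing Lattice constant, units of d; must be at least d and
#'   divide the box side.
#' @param box An [sq_box].
#' @return A data frame with columns `x`, `y`.
#' @export
lattice_configuration <- function(spacing, box) {
  stopifnot(spacing >= 1)
  m <- box$side / spacing
  if (abs(m - round(m)) > 1e-9)
    stop("box side must be an integer multiple of the lattice spacing")
  m <- as.integer(round(m))
  pts <- expand.grid(x = (seq_len(m) - 1) * spacing,
                     y = (seq_len(m) - 1) * spacing)
  data.frame(x = pts$x, y = pts$y)
}

#' Brute-force reference energy
#'
#' Independent scalar double-loop evaluation of the interaction energy of
#' one particle against a quenched set: explicit per-pair minimum-image
#' arithmetic and the triangular-well formula written out inline, sharing
#' no helpers with the production energy path. Used as the oracle in
#' equivalence tests.
#'
#' @inheritParams particle_energy
#' @return Energy in units of \eqn{\varepsilon}; `Inf` on overlap.
#' @export
brute_force_energy <- function(position, others, pattern, box,
                               params = sq_potential()) {
  others <- as_xy_matrix(others)
  L <- box$side
  d <- params$d
  lam <- params$lambda * d
  # region factor of the evaluated particle, by direct stripe scan
  xfrac <- position[1] / L
  U <- NA_real_
  lo <- 0
  for (s in seq_along(pattern$bounds)) {
    if (xfrac >= lo && xfrac < pattern$bounds[s]) { U <- pattern$factors[s]; break }
    lo <- pattern$bounds[s]
  }
  if (is.na(U)) U <- pattern$factors[length(pattern$factors)]
  e <- 0
  n <- nrow(others)
  if (n == 0) return(0)
  for (j in seq_len(n)) {
    dx <- position[1] - others[j, 1]
    dy <- position[2] - others[j, 2]
    while (dx > L / 2) dx <- dx - L
    while (dx < -L / 2) dx <- dx + L
    while (dy > L / 2) dy <- dy - L
    while (dy < -L / 2) dy <- dy + L
    r <- sqrt(dx^2 + dy^2)
    if (r < d) return(Inf)
    if (r <= lam) e <- e - (params$epsilon / U) * (lam - r) / (lam - d)
  }
  e
}

#' Boltzmann reference distribution on a discrete landscape
#'
#' Normalized \eqn{e^{-E/(T^* \varepsilon)}} over a finite set of energies:
#' the target distribution for Metropolis-kernel stationarity tests.
#'
#' @param energies Numeric vector (or matrix) of energies in units of
#'   \eqn{\varepsilon}; `Inf` entries (forbidden cells) get probability 0.
#' @param tstar Reduced temperature.
#' @param epsilon Energy scale.
#' @return Probabilities of the same shape as `energies`, summing to 1.
#' @export
boltzmann_reference <- function(energies, tstar = 1, epsilon = 1) {
  if (all(!is.finite(energies) | is.na(energies)))
    stop("all-infinite landscape: no accessible states")
  w <- exp(-energies / (tstar * epsilon))
  w[!is.finite(energies)] <- 0
  w / sum(w)
}
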