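#' Region-scaled triangular-well pair potential
#'
#' Parameters of the pair interaction: an impenetrable hard core of
#' diameter \eqn{d} plus a linear ("triangular") attractive well running
#' from \eqn{-\varepsilon/U} at contact to zero at \eqn{\lambda d}:
#' \deqn{u(r) = \infty \; (r < d); \quad
#'       -\frac{\varepsilon}{U}\,\frac{\lambda d - r}{\lambda d - d}
#'       \; (d \le r \le \lambda d); \quad 0 \; (r > \lambda d).}
#' The surface energy factor \eqn{U} divides the well depth, so regions
#' with small \eqn{U} bind particles strongly. \eqn{d} and \eqn{\varepsilon}
#' are the units of length and energy and are fixed at 1; the reduced
#' temperature \eqn{T^* = kT/\varepsilon} sets the Boltzmann factor
#' \eqn{e^{-u/(T^*\varepsilon)}}.
#'
#' @param lambda Well-range multiplier \eqn{\lambda > 1}; the well width is
#'   \eqn{(\lambda - 1) d}, 0.5 d at the default 1.5.
#' @param epsilon Well-depth scale \eqn{\varepsilon} (unit energy, 1).
#' @param tstar Reduced temperature \eqn{T^* = kT/\varepsilon} (default 1).
#' @param d Hard-core diameter (unit length, 1).
#'
#' @return An object of class \code{sq_potential}.
#' @examples
#' pot <- sq_potential()
#' pair_energy(c(0.9, 1, 1.25, 1.5, 2), 1, pot)  # Inf -1 -0.5 0 0
#' @export
sq_potential <- function(lambda = 1.5, epsilon = 1, tstar = 1.0, d = 1) {
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda > 1,
            is.numeric(epsilon), length(epsilon) == 1, epsilon > 0,
            is.numeric(tstar), length(tstar) == 1, tstar > 0,
            is.numeric(d), length(d) == 1, d > 0)
  structure(list(lambda = as.double(lambda), epsilon = as.double(epsilon),
                 tstar = as.double(tstar), d = as.double(d)),
            class = "sq_potential")
}

#' @export
print.sq_potential <- function(x, ...) {
  cat(sprintf(paste0("Triangular-well potential: d = %g, lambda = %g ",
                     "(well width %g d), epsilon = %g, T* = %g\n"),
              x$d, x$lambda, (x$lambda - 1) * x$d, x$epsilon, x$tstar))
  invisible(x)
}

#' Pair energy at given separation
#'
#' Evaluates the triangular-well pair potential at distance `r` with the
#' well depth scaled by the energy factor `factor_u` of the region the
#' evaluated particle stands in. Vectorized over `r`.
#'
#' @param r Distance(s), units of \eqn{d}; must be non-negative.
#' @param factor_u Region energy factor \eqn{U > 0}.
#' @param params An [sq_potential].
#' @return Energy in units of \eqn{\varepsilon}; `Inf` inside the hard core.
#' @export
pair_energy <- function(r, factor_u, params = sq_potential()) {
  if (!is.numeric(factor_u) || length(factor_u) != 1 ||
      !is.finite(factor_u) || factor_u <= 0)
    stop("factor_u must be a single strictly positive finite number")
  stopifnot(all(r >= 0))
  d <- params$d; lam <- params$lambda * d
  depth <- params$epsilon / factor_u
  e <- numeric(length(r))
  core <- r < d
  well <- !core & r <= lam
  e[core] <- Inf
  e[well] <- -depth * (lam - r[well]) / (lam - d)
  e
}

#' Total interaction energy of one particle
#'
#' Sum of pair energies between a (mobile) particle and a set of quenched
#' particles, using minimum-image distances. The energy factor is taken
#' from the region the mobile particle itself stands in, so the same
#' neighbour binds more strongly when the particle sits in a low-U stripe.
#' Returns `Inf` iff any minimum-image distance is below \eqn{d}.
#'
#' @param position Length-2 point, wrapped into the box.
#' @param others n x 2 matrix (or data frame with columns x, y) of quenched
#'   positions; may have zero rows.
#' @param pattern An [sq_pattern].
#' @param box An [sq_box].
#' @param params An [sq_potential].
#' @return Energy in units of \eqn{\varepsilon}.
#' @export
particle_energy <- function(position, others, pattern, box,
                            params = sq_potential()) {
  others <- as_xy_matrix(others)
  if (nrow(others) == 0) return(0)
  U <- region_of(position, pattern, box)$factor
  r <- min_image_dist(position[1], position[2], others[, 1], others[, 2],
                      box$side)
  if (any(r < params$d)) return(Inf)
  sum(pair_energy(r, U, params))
}

#' Metropolis acceptance probability for an energy change
#'
#' \eqn{\min(1, e^{-\Delta E /(T^* \varepsilon)})}; an infinite energy
#' increase (hard-core overlap at the proposal) gives probability 0.
#'
#' @param delta_e Energy change in units of \eqn{\varepsilon}.
#' @param params An [sq_potential].
#' @return Acceptance probability in \[0, 1\].
#' @export
metropolis_accept_prob <- function(delta_e, params = sq_potential()) {
  p <- exp(-delta_e / (params$tstar * params$epsilon))
  pmin(1, p)
}

# Coerce data frames / vectors to an n x 2 coordinate matrix.
as_xy_matrix <- function(p) {
  if (is.data.frame(p)) p <- cbind(p$x, p$y)
  if (is.null(dim(p))) p <- matrix(p, ncol = 2, byrow = TRUE)
  if (is.null(p) || length(p) == 0) return(matrix(numeric(0), ncol = 2))
  storage.mode(p) <- "double"
  p
}
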