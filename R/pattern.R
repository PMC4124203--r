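#' Striped surface-energy pattern
#'
#' Partitions the box into vertical stripes along x, each carrying a label
#' and a surface energy factor \eqn{U}. The factor scales the depth of the
#' attractive well felt by a particle standing in that stripe (depth
#' \eqn{\varepsilon/U}): small \eqn{U} means strong attraction, emulating a
#' high-energy (e.g. laser-ablated) region, while large \eqn{U} emulates a
#' passivated (e.g. PEO-coated) region.
#'
#' The default layout is three equal-width stripes R1 | R2 | R3 with the
#' outer stripes sharing the factor `u1` and the central stripe carrying
#' `u2`. Because both axes are periodic, R1 and R3 are adjacent across the
#' x-boundary; they carry the same factor, so the energy landscape remains
#' consistent there.
#'
#' @param widths Stripe widths as fractions of the box side; must be
#'   strictly positive and sum to 1.
#' @param labels Stripe names, one per width.
#' @param factors Energy factor \eqn{U > 0} per stripe.
#' @param u1,u2 Convenience shortcut for [stripe_pattern()].
#'
#' @return An object of class \code{sq_pattern} with elements `widths`,
#'   `labels`, `factors` and `bounds` (cumulative upper boundaries as
#'   fractions of the side).
#' @examples
#' pat <- stripe_pattern(u1 = 1e-4, u2 = 1)   # strongly selective surface
#' region_of(c(10, 3), pat, sq_box(20))       # centre -> R2
#' @export
sq_pattern <- function(widths = rep(1 / 3, 3),
                       labels = c("R1", "R2", "R3"),
                       factors = c(1, 1, 1)) {
  widths <- as.double(widths); factors <- as.double(factors)
  labels <- as.character(labels)
  if (length(widths) < 1 || length(labels) != length(widths) ||
      length(factors) != length(widths))
    stop("widths, labels and factors must have equal, positive length")
  if (any(!is.finite(widths)) || any(widths <= 0))
    stop("stripe widths must be positive and finite")
  if (abs(sum(widths) - 1) > 1e-8)
    stop("stripe widths must sum to 1 (fractions of the box side)")
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("energy factors must be strictly positive and finite")
  bounds <- cumsum(widths)
  bounds[length(bounds)] <- 1  # exact closure of [0, L)
  structure(list(widths = widths, labels = labels, factors = factors,
                 bounds = bounds),
            class = "sq_pattern")
}

#' @rdname sq_pattern
#' @export
stripe_pattern <- function(u1 = 1, u2 = 1) {
  sq_pattern(factors = c(u1, u2, u1))
}

#' @export
print.sq_pattern <- function(x, ...) {
  cat("Surface pattern (stripes along x):\n")
  lo <- c(0, x$bounds[-length(x$bounds)])
  for (i in seq_along(x$labels))
    cat(sprintf("  %-4s [%.4f, %.4f) x L   U = %g\n",
                x$labels[i], lo[i], x$bounds[i], x$factors[i]))
  invisible(x)
}

# Stripe index for x-coordinates (vectorized). x must be wrapped.
region_index <- function(x, pattern, box) {
  findInterval(x / box$side, c(0, pattern$bounds), rightmost.closed = FALSE,
               left.open = FALSE)
}

#' Region lookup for positions
#'
#' Maps wrapped positions to the stripe containing their x-coordinate and
#' its energy factor. Pure and total on the box.
#'
#' @param position A length-2 point or an n x 2 matrix, already wrapped into
#'   \eqn{[0, L)^2}.
#' @param pattern An [sq_pattern].
#' @param box An [sq_box].
#' @return For a single point, a list with `label` and `factor`; for a
#'   matrix, a data frame with columns `label` and `factor`.
#' @export
region_of <- function(position, pattern, box) {
  single <- is.null(dim(position))
  xs <- if (single) position[1] else position[, 1]
  if (any(xs < 0 | xs >= box$side))
    stop("position outside the box: wrap with wrap_position() first")
  idx <- region_index(xs, pattern, box)
  if (single)
    list(label = pattern$labels[idx], factor = pattern$factors[idx])
  else
    data.frame(label = pattern$labels[idx], factor = pattern$factors[idx])
}

#' Area fraction of each stripe
#'
#' @param pattern An [sq_pattern].
#' @return Named numeric vector of area fractions (equal to width
#'   fractions, since stripes span the full height of the box).
#' @export
area_fractions <- function(pattern) {
  setNames(pattern$widths, pattern$labels)
}

# Cumulative stripe boundaries in length units, for the C++ engine.
pattern_edges <- function(pattern, box) pattern$bounds * box$side
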