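#' Periodic simulation box
#'
#' Defines the square 2-D simulation cell. All lengths are in units of the
#' hard-core particle diameter \eqn{d}; coordinates live in the half-open
#' box \eqn{[0, L)^2} and distances are measured with the minimum-image
#' convention.
#'
#' @param side Box side length \eqn{L} in units of \eqn{d}. The default
#'   \code{20} gives the standard 400 \eqn{d^2} cell; \code{sqrt(1000)}
#'   gives the 1000 \eqn{d^2} cell used for finite-size checks.
#'
#' @return An object of class \code{sq_box}.
#' @examples
#' box <- sq_box(20)
#' min_image(c(1, 0), c(19, 0), box)$distance  # 2, across the boundary
#' @export
sq_box <- function(side = 20) {
  stopifnot(is.numeric(side), length(side) == 1, is.finite(side), side > 0)
  structure(list(side = as.double(side), periodic = c(x = TRUE, y = TRUE)),
            class = "sq_box")
}

#' @export
print.sq_box <- function(x, ...) {
  cat(sprintf("Periodic box: %.6g d x %.6g d (area %.6g d^2)\n",
              x$side, x$side, x$side^2))
  invisible(x)
}

#' Wrap positions into the periodic box
#'
#' @param p A length-2 point, or an n x 2 matrix of points.
#' @param box An [sq_box].
#' @return Positions wrapped into \eqn{[0, L)^2}, same shape as `p`.
#' @export
wrap_position <- function(p, box) {
  L <- box$side
  w <- p - L * floor(p / L)
  # guard against w == L from floating-point roundoff of tiny negatives
  w[w >= L] <- 0
  w
}

#' Minimum-image displacement and distance
#'
#' Returns the displacement from `p1` to `p2` measured to the nearest
#' periodic image, so each component has magnitude at most \eqn{L/2}.
#'
#' @param p1,p2 Length-2 points in \eqn{[0, L)^2}.
#' @param box An [sq_box].
#' @return A list with `disp` (length-2 displacement) and `distance`
#'   (Euclidean norm of the wrapped displacement).
#' @export
min_image <- function(p1, p2, box) {
  L <- box$side
  d <- p2 - p1
  d <- d - L * round(d / L)
  list(disp = d, distance = sqrt(sum(d^2)))
}

# Vectorized minimum-image distances from (px, py) to columns (x, y).
# Internal workhorse for energy and histogram code paths.
min_image_dist <- function(px, py, x, y, L) {
  dx <- px - x; dx <- dx - L * round(dx / L)
  dy <- py - y; dy <- dy - L * round(dy / L)
  sqrt(dx * dx + dy * dy)
}
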