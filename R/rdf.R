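#' Minimum-image pair-distance histogram
#'
#' Counts unordered particle pairs per distance bin, summed over the
#' configurations of an ensemble. Bins are half-open
#' \eqn{[r_i, r_i + \Delta r)} with uniform width starting at 0.
#'
#' @param configs A list of configurations (each with columns/components
#'   `x`, `y`), or a single configuration, or an \code{sq_ensemble}.
#' @param box An [sq_box] shared by all configurations.
#' @param dr Bin width \eqn{\Delta r} in units of d (default 0.05).
#' @param rmax Histogram range; must not exceed \eqn{L/2} (minimum-image
#'   validity). Default \eqn{L/2}.
#' @return Integer vector of pair counts with attributes `bin_edges`, `n`
#'   (number of configurations) and `N` (particles per configuration).
#' @export
accumulate_pair_histogram <- function(configs, box, dr = 0.05, rmax = NULL) {
  configs <- as_config_list(configs)
  if (is.null(rmax)) rmax <- box$side / 2
  if (dr <= 0) stop("dr must be positive")
  if (rmax > box$side / 2 + 1e-12)
    stop("rmax must not exceed half the box side (minimum image breaks)")
  nbins <- as.integer(floor(rmax / dr + 1e-9))
  Ns <- vapply(configs, function(c) length(c$x), integer(1))
  if (length(unique(Ns)) != 1)
    stop("all configurations must have the same particle count")
  counts <- integer(nbins)
  for (cf in configs)
    counts <- counts + cpp_pair_histogram(as.double(cf$x), as.double(cf$y),
                                          box$side, dr, nbins)
  structure(counts, bin_edges = seq(0, by = dr, length.out = nbins + 1),
            n = length(configs), N = Ns[1])
}

#' Normalize a pair histogram to g(r)
#'
#' Applies the standard ideal-gas normalization of the 2-D radial
#' distribution function,
#' \deqn{g(r_i + \Delta r/2) = \frac{N_i}{\pi r_i \Delta r \rho N n},}
#' where \eqn{N_i} is the unordered pair count in bin \eqn{i} summed over
#' \eqn{n} configurations of \eqn{N} particles, \eqn{\rho} is the global
#' number density, and \eqn{r_i} is the lower bin edge. The unordered-pair
#' convention pairs with the factor \eqn{\pi} (rather than \eqn{2\pi}); the
#' linear-shell denominator \eqn{\pi r_i \Delta r} is half the annulus
#' circumference times width. `mode = "shell"` instead divides by the exact
#' half-annulus area \eqn{\pi (r_{i+1}^2 - r_i^2)/2}, removing the small
#' \eqn{O(\Delta r / r)} bias of the linear form.
#'
#' @param pair_counts Output of [accumulate_pair_histogram()], or a plain
#'   count vector (then `bin_edges` is required).
#' @param N Particles per configuration (\eqn{\ge 2}).
#' @param n Number of configurations pooled.
#' @param rho Global number density \eqn{N/L^2}.
#' @param dr Bin width.
#' @param bin_edges Bin edges; taken from `pair_counts` attributes when
#'   present.
#' @param mode `"literal"` (lower-edge linear shell, default) or `"shell"`
#'   (exact annulus area).
#' @param stderr Optional per-bin standard error to attach.
#' @return An object of class \code{sq_rdf}: a data frame with columns
#'   `r` (bin centre), `g`, `count` and `se`, with bin geometry and run
#'   metadata as attributes.
#' @export
normalize_rdf <- function(pair_counts, N, n, rho, dr = NULL,
                          bin_edges = NULL, mode = c("literal", "shell"),
                          stderr = NULL) {
  mode <- match.arg(mode)
  if (is.null(bin_edges)) bin_edges <- attr(pair_counts, "bin_edges")
  if (is.null(bin_edges)) stop("bin_edges required")
  if (is.null(dr)) dr <- diff(bin_edges[1:2])
  if (dr <= 0 || any(diff(bin_edges) <= 0)) stop("bins must have positive width")
  stopifnot(N >= 2, n >= 1, rho > 0)
  counts <- as.integer(pair_counts)
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1]
  denom <- if (mode == "literal") pi * lo * dr * rho * N * n
           else pi * (hi^2 - lo^2) / 2 * rho * N * n
  g <- counts / denom
  g[counts == 0] <- 0   # covers the r = 0 bin where the literal denominator vanishes
  out <- data.frame(r = (lo + hi) / 2, g = g, count = counts,
                    se = if (is.null(stderr)) NA_real_ else stderr)
  structure(out, bin_edges = bin_edges, dr = dr, N = N, n = n, rho = rho,
            mode = mode, class = c("sq_rdf", "data.frame"))
}

#' Radial distribution function of an ensemble
#'
#' Computes g(r) from pooled pair counts over all realizations and attaches
#' an across-realization standard error (each realization's g computed with
#' n = 1, aggregated per bin).
#'
#' @inheritParams accumulate_pair_histogram
#' @inheritParams normalize_rdf
#' @param box Taken from the ensemble when omitted.
#' @return An \code{sq_rdf}.
#' @examples
#' ens <- ideal_gas_ensemble(N = 120, box = sq_box(20), n = 20, seed = 1)
#' rdf <- sq_rdf(ens, box = sq_box(20))
#' first_peak(rdf)
#' @export
sq_rdf <- function(configs, box = NULL, dr = 0.05, rmax = NULL,
                   mode = c("literal", "shell")) {
  mode <- match.arg(mode)
  if (is.null(box)) box <- attr(configs, "box")
  if (is.null(box)) stop("box required (not found on the input)")
  clist <- as_config_list(configs)
  counts <- accumulate_pair_histogram(clist, box, dr, rmax)
  N <- attr(counts, "N"); n <- attr(counts, "n")
  rho <- N / box$side^2
  per <- vapply(clist, function(cf) {
    ci <- accumulate_pair_histogram(list(cf), box, dr, rmax)
    normalize_rdf(ci, N = N, n = 1, rho = rho, mode = mode)$g
  }, numeric(length(counts)))
  se <- if (n > 1) apply(matrix(per, ncol = n), 1, sd) / sqrt(n)
        else rep(NA_real_, length(counts))
  normalize_rdf(counts, N = N, n = n, rho = rho, mode = mode, stderr = se)
}

#' First peak of g(r)
#'
#' Maximum of g over the bins whose centres lie in `[rmin, rmax]` (by
#' default the attractive well \eqn{[d, \lambda d]} at \eqn{\lambda = 1.5}),
#' ties broken toward smaller r.
#'
#' @param rdf An \code{sq_rdf}.
#' @param rmin,rmax Search range for the peak, units of d.
#' @return List with `r` (bin centre), `g` (height) and `se`.
#' @export
first_peak <- function(rdf, rmin = 1, rmax = 1.5) {
  sel <- which(rdf$r >= rmin & rdf$r <= rmax)
  if (length(sel) == 0) stop("no bins with centres in [rmin, rmax]")
  i <- sel[which.max(rdf$g[sel])]   # which.max takes the first maximum
  list(r = rdf$r[i], g = rdf$g[i], se = rdf$se[i])
}

#' Region occupancy of an ensemble
#'
#' Fraction of quenched particles in each stripe, per realization,
#' aggregated to mean and standard error, next to the stripe area
#' fractions. The contrast between occupancy and area fraction is the
#' quantitative signature of selective adsorption.
#'
#' @param configs An \code{sq_ensemble}, a single configuration, or a list
#'   of configurations with a `region` column.
#' @param pattern,box Taken from the ensemble when omitted. When a
#'   configuration lacks a `region` column it is assigned from positions.
#' @return An object of class \code{sq_occupancy}: data frame with columns
#'   `region`, `mean_fraction`, `se`, `area_fraction`.
#' @export
region_occupancy <- function(configs, pattern = NULL, box = NULL) {
  if (is.null(pattern)) pattern <- attr(configs, "pattern")
  if (is.null(box)) box <- attr(configs, "box")
  if (is.null(pattern) || is.null(box))
    stop("pattern and box required (not found on the input)")
  clist <- as_config_list(configs)
  fracs <- vapply(clist, function(cf) {
    reg <- cf$region
    if (is.null(reg))
      reg <- pattern$labels[region_index(wrap_position(cf$x, box), pattern,
                                         box)]
    tab <- table(factor(reg, levels = pattern$labels))
    as.double(tab) / sum(tab)
  }, numeric(length(pattern$labels)))
  fracs <- matrix(fracs, nrow = length(pattern$labels))
  out <- data.frame(region = pattern$labels,
                    mean_fraction = rowMeans(fracs),
                    se = apply(fracs, 1, std_err),
                    area_fraction = as.double(area_fractions(pattern)))
  structure(out, realizations = ncol(fracs),
            class = c("sq_occupancy", "data.frame"))
}

#' @export
print.sq_occupancy <- function(x, ...) {
  cat(sprintf("Region occupancy over %d realization(s):\n",
              attr(x, "realizations")))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-4s fraction %.4f +/- %.4f   (area fraction %.4f)\n",
                x$region[i], x$mean_fraction[i], x$se[i], x$area_fraction[i]))
  invisible(x)
}

#' @export
print.sq_rdf <- function(x, ...) {
  cat(sprintf(
    "g(r): %d bins of width %.4g d, %d configuration(s) x %d particles (%s mode)\n",
    nrow(x), attr(x, "dr"), attr(x, "n"), attr(x, "N"), attr(x, "mode")))
  pk <- first_peak(x)
  cat(sprintf("  first peak: g = %.4g at r = %.4g d\n", pk$g, pk$r))
  invisible(x)
}

#' Plot g(r)
#'
#' @param x An \code{sq_rdf}.
#' @param se Draw +/- 1 standard-error whiskers where available.
#' @param ... Passed to [plot()].
#' @export
plot.sq_rdf <- function(x, se = TRUE, ...) {
  plot(x$r, x$g, type = "l", xlab = "r / d", ylab = "g(r)", ...)
  if (se && any(is.finite(x$se)))
    segments(x$r, x$g - x$se, x$r, x$g + x$se, col = "grey50")
  abline(h = 1, lty = 3)
  invisible(x)
}

# Accept an ensemble, a bare list of configurations, or one configuration.
as_config_list <- function(configs) {
  if (inherits(configs, "sq_ensemble")) return(unclass(configs))
  if (inherits(configs, "sq_config") || is.data.frame(configs))
    return(list(configs))
  if (is.list(configs) && !is.null(configs$x) && !is.null(configs$y))
    return(list(configs))
  as.list(configs)
}
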