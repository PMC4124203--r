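#' Sequential-quenching simulation parameters
#'
#' @param rho Target reduced number density \eqn{\rho^* = \rho d^2}
#'   (default 0.3). The particle count is \eqn{N =
#'   \mathrm{round}(\rho^* L^2 / d^2)}: 120 on the default 20 d box.
#' @param moves Attempted Metropolis moves per particle before it is
#'   quenched (default 3000). Rejected moves count against the budget.
#' @param max_disp Per-axis maximum trial displacement (default 0.5 d).
#' @param retry_cap Maximum insertion attempts before a jamming error
#'   (default 1e6).
#' @param realizations Number of independent realizations in an ensemble
#'   (default 100).
#'
#' @return An object of class \code{sq_sim_params}.
#' @export
sq_sim_params <- function(rho = 0.3, moves = 3000, max_disp = 0.5,
                          retry_cap = 1e6, realizations = 100) {
  stopifnot(is.numeric(rho), length(rho) == 1, rho > 0,
            is.numeric(moves), length(moves) == 1, moves >= 0,
            is.numeric(max_disp), length(max_disp) == 1, max_disp > 0,
            is.numeric(retry_cap), length(retry_cap) == 1, retry_cap >= 1,
            is.numeric(realizations), length(realizations) == 1,
            realizations >= 1)
  structure(list(rho = as.double(rho), moves = as.integer(moves),
                 max_disp = as.double(max_disp),
                 retry_cap = as.double(retry_cap),
                 realizations = as.integer(realizations)),
            class = "sq_sim_params")
}

# Deterministic per-realization / per-condition seed stream, kept within
# 32-bit integer range for set.seed.
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(k) * 7919
  as.integer(s %% 2147483647)
}

# Shared validation for an engine run.
check_run_inputs <- function(box, pattern, potential, sim) {
  stopifnot(inherits(box, "sq_box"), inherits(pattern, "sq_pattern"),
            inherits(potential, "sq_potential"),
            inherits(sim, "sq_sim_params"))
  if (box$side <= 2 * potential$lambda * potential$d)
    stop("box side must exceed 2*lambda*d for the minimum image to cover ",
         "the interaction range")
  if (sim$max_disp > box$side / 2)
    stop("max_disp must not exceed half the box side")
  invisible(TRUE)
}

#' Insert a particle with hard-core rejection
#'
#' Draws uniform positions in the box until one has minimum-image distance
#' at least \eqn{d} to every quenched particle, as in random sequential
#' adsorption. Uses R's RNG.
#'
#' @param positions n x 2 matrix (possibly empty) of quenched positions.
#' @param box An [sq_box].
#' @param params An [sq_potential] (for the hard-core diameter).
#' @param retry_cap Attempts before a jamming error.
#' @return Accepted length-2 position.
#' @export
attempt_insertion <- function(positions, box, params = sq_potential(),
                              retry_cap = 1e6) {
  positions <- as_xy_matrix(positions)
  L <- box$side
  for (attempt in seq_len(retry_cap)) {
    p <- runif(2, 0, L)
    if (nrow(positions) == 0) return(p)
    r <- min_image_dist(p[1], p[2], positions[, 1], positions[, 2], L)
    if (all(r >= params$d)) return(p)
  }
  stop(sprintf("insertion jammed after %d attempts: density or pattern %s",
               as.integer(retry_cap), "infeasible"))
}

#' One Metropolis trial move of the mobile particle
#'
#' Proposes independent per-axis uniform offsets in
#' \eqn{[-\mathrm{max\_disp}, +\mathrm{max\_disp}]}, wraps into the box,
#' and accepts with probability
#' \eqn{\min(1, e^{-[E(r') - E(r)]/(T^*\varepsilon)})} where \eqn{E} is
#' [particle_energy()] against the quenched set. A proposal overlapping a
#' quenched particle is always rejected. On rejection the position is
#' unchanged.
#'
#' @param current Length-2 current position (finite energy).
#' @param others Quenched positions (n x 2 matrix, possibly empty).
#' @param pattern,box,params Pattern, box and potential.
#' @param max_disp Per-axis displacement cap.
#' @return The new position, with attributes `accepted` (logical) and
#'   `energy` (its interaction energy).
#' @export
metropolis_step <- function(current, others, pattern, box,
                            params = sq_potential(), max_disp = 0.5) {
  proposal <- wrap_position(current + runif(2, -max_disp, max_disp), box)
  e_old <- particle_energy(current, others, pattern, box, params)
  e_new <- particle_energy(proposal, others, pattern, box, params)
  de <- e_new - e_old
  accept <- is.finite(e_new) &&
    (de <= 0 || runif(1) < exp(-de / (params$tstar * params$epsilon)))
  out <- if (accept) proposal else current
  structure(out, accepted = accept, energy = if (accept) e_new else e_old)
}

#' Diffuse a particle and quench it
#'
#' Applies [metropolis_step()] exactly `moves` times from `start`; the
#' position after the final step is the quench position. Reference R
#' implementation of the per-particle diffusion stage (the ensemble driver
#' uses an equivalent compiled path).
#'
#' @inheritParams metropolis_step
#' @param start Starting position (accepted insertion).
#' @param moves Attempted-move budget.
#' @return Final position with attribute `energy`.
#' @export
diffuse_and_quench <- function(start, others, pattern, box,
                               params = sq_potential(), max_disp = 0.5,
                               moves = 3000) {
  pos <- start
  for (m in seq_len(moves))
    pos <- metropolis_step(pos, others, pattern, box, params, max_disp)
  e <- particle_energy(as.double(pos), others, pattern, box, params)
  structure(as.double(pos), energy = e)
}

#' Run one sequential-quenching realization
#'
#' Alternates insertion with hard-core rejection and Metropolis surface
#' diffusion of the newest particle among its frozen predecessors, quenching
#' each in place, until the particle count reaches
#' \eqn{\mathrm{round}(\rho^* L^2)}. Deterministic given `seed`.
#'
#' @param box An [sq_box].
#' @param pattern An [sq_pattern].
#' @param potential An [sq_potential].
#' @param sim An [sq_sim_params].
#' @param seed Integer RNG seed for this realization.
#' @return An object of class \code{sq_config}: a data frame with columns
#'   `x`, `y`, `region`, `energy` (interaction energy at quench) and
#'   `energy_init` (at insertion), rows in insertion order, with the run
#'   objects and seed attached as attributes. The `total_energy` attribute
#'   sums the at-quench energies, which counts each interacting pair once.
#' @examples
#' cfg <- run_realization(sim = sq_sim_params(moves = 50), seed = 1)
#' nrow(cfg)  # 120 particles at the default density
#' @export
run_realization <- function(box = sq_box(), pattern = stripe_pattern(),
                            potential = sq_potential(),
                            sim = sq_sim_params(), seed = 1) {
  check_run_inputs(box, pattern, potential, sim)
  n_target <- as.integer(round(sim$rho * box$side^2 / potential$d^2))
  set.seed(as.integer(seed))
  res <- cpp_run_realization(n_target, box$side, sim$moves, sim$max_disp,
                             potential$lambda, potential$epsilon,
                             potential$tstar, pattern_edges(pattern, box),
                             pattern$factors, sim$retry_cap)
  region <- pattern$labels[region_index(res$x, pattern, box)]
  out <- data.frame(x = res$x, y = res$y, region = region,
                    energy = res$energy, energy_init = res$energy_init)
  structure(out, box = box, pattern = pattern, potential = potential,
            sim = sim, seed = as.integer(seed),
            total_energy = sum(res$energy),
            class = c("sq_config", "data.frame"))
}

#' Run an ensemble of independent realizations
#'
#' Realization \eqn{k} uses an RNG stream derived deterministically from
#' `(seed, k)`, so ensembles are reproducible and realizations independent.
#'
#' @inheritParams run_realization
#' @param seed Master seed.
#' @return An object of class \code{sq_ensemble}: a list of
#'   \code{sq_config} objects with the run objects attached as attributes.
#' @export
run_ensemble <- function(box = sq_box(), pattern = stripe_pattern(),
                         potential = sq_potential(),
                         sim = sq_sim_params(), seed = 1) {
  check_run_inputs(box, pattern, potential, sim)
  configs <- vector("list", sim$realizations)
  for (k in seq_len(sim$realizations)) {
    configs[[k]] <- tryCatch(
      run_realization(box, pattern, potential, sim, derive_seed(seed, k)),
      error = function(e) stop(sprintf("realization %d: %s", k,
                                       conditionMessage(e)), call. = FALSE))
  }
  structure(configs, box = box, pattern = pattern, potential = potential,
            sim = sim, seed = as.integer(seed), class = "sq_ensemble")
}

#' High-level simulation front end
#'
#' Builds the box, pattern, potential and simulation parameters from flat
#' arguments and runs an ensemble. Defaults reproduce the standard study
#' conditions: 20 d box, \eqn{\rho^* = 0.3}, \eqn{T^* = 1},
#' \eqn{\lambda = 1.5}, 3000 moves, 0.5 d cap, 100 realizations,
#' equal-thirds R1|R2|R3 stripes.
#'
#' @param u1,u2 Energy factors of the outer (R1, R3) and central (R2)
#'   stripes.
#' @param side Box side in units of d.
#' @param rho,tstar,lambda,moves,max_disp,realizations See
#'   [sq_sim_params()] and [sq_potential()].
#' @param pattern Optional [sq_pattern] overriding `u1`/`u2`.
#' @param seed Master seed.
#' @return An \code{sq_ensemble}.
#' @export
sq_simulate <- function(u1 = 1, u2 = 1, side = 20, rho = 0.3, tstar = 1.0,
                        lambda = 1.5, moves = 3000, max_disp = 0.5,
                        realizations = 100, pattern = NULL, seed = 1) {
  if (is.null(pattern)) pattern <- stripe_pattern(u1, u2)
  run_ensemble(box = sq_box(side), pattern = pattern,
               potential = sq_potential(lambda = lambda, tstar = tstar),
               sim = sq_sim_params(rho = rho, moves = moves,
                                   max_disp = max_disp,
                                   realizations = realizations),
               seed = seed)
}

#' @export
print.sq_config <- function(x, ...) {
  box <- attr(x, "box")
  cat(sprintf("Quenched configuration: %d particles on a %.4g d box (seed %d)\n",
              nrow(x), box$side, attr(x, "seed")))
  cat(sprintf("  total interaction energy: %.4g epsilon\n",
              attr(x, "total_energy")))
  tab <- table(factor(x$region, levels = attr(x, "pattern")$labels))
  cat("  region counts:", paste(names(tab), as.integer(tab), sep = "=",
                                collapse = "  "), "\n")
  invisible(x)
}

#' @export
print.sq_ensemble <- function(x, ...) {
  box <- attr(x, "box")
  pat <- attr(x, "pattern")
  cat(sprintf(
    "SQ ensemble: %d realizations x %d particles, %.4g d box (seed %d)\n",
    length(x), nrow(x[[1]]), box$side, attr(x, "seed")))
  cat(sprintf("  stripe factors: %s\n",
              paste(pat$labels, pat$factors, sep = "=", collapse = "  ")))
  invisible(x)
}

#' @export
summary.sq_ensemble <- function(object, ...) {
  occ <- region_occupancy(object)
  en <- vapply(object, function(c) attr(c, "total_energy"), numeric(1))
  out <- list(realizations = length(object), particles = nrow(object[[1]]),
              occupancy = occ,
              mean_total_energy = mean(en), se_total_energy = std_err(en))
  class(out) <- "summary.sq_ensemble"
  out
}

#' @export
print.summary.sq_ensemble <- function(x, ...) {
  cat(sprintf("SQ ensemble summary: %d realizations x %d particles\n",
              x$realizations, x$particles))
  cat(sprintf("  mean total energy %.4g +/- %.2g epsilon\n",
              x$mean_total_energy, x$se_total_energy))
  print(x$occupancy)
  invisible(x)
}

#' Plot a quenched configuration
#'
#' Draws particles as circles of diameter \eqn{d} coloured by region, with
#' stripe boundaries marked.
#'
#' @param x An \code{sq_config}.
#' @param ... Passed to [plot()].
#' @export
plot.sq_config <- function(x, ...) {
  box <- attr(x, "box"); pat <- attr(x, "pattern")
  L <- box$side
  cols <- setNames(adjustcolor(seq_along(pat$labels) + 1, 0.7), pat$labels)
  plot(NA, xlim = c(0, L), ylim = c(0, L), asp = 1,
       xlab = "x / d", ylab = "y / d", ...)
  abline(v = pattern_edges(pat, box), lty = 3, col = "grey40")
  symbols(x$x, x$y, circles = rep(0.5, nrow(x)), inches = FALSE,
          add = TRUE, bg = cols[x$region], fg = "grey20")
  invisible(x)
}

std_err <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
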