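box20 <- sq_box(20)
pot_default <- sq_potential()

min_image_pairwise <- function(cfg, i, L) {
  dx <- cfg$x[i] - cfg$x[seq_len(i - 1)]; dx <- dx - L * round(dx / L)
  dy <- cfg$y[i] - cfg$y[seq_len(i - 1)]; dy <- dy - L * round(dy / L)
  sqrt(dx^2 + dy^2)
}

test_that("insertion draws uniform positions and rejects hard-core overlap", {
  set.seed(1)
  # empty configuration: first draw accepted
  p <- attempt_insertion(matrix(numeric(0), ncol = 2), box20)
  expect_true(all(p >= 0 & p < 20))
  # dense quenched set: every accepted insertion respects the hard core
  set.seed(2)
  quenched <- cbind(runif(60, 0, 20), runif(60, 0, 20))
  for (i in 1:50) {
    p <- attempt_insertion(quenched, box20)
    r <- vapply(seq_len(nrow(quenched)), function(j)
      min_image(p, quenched[j, ], box20)$distance, numeric(1))
    expect_gte(min(r), 1)
  }
  # a box fully covered by a fine lattice of spacing < 2d leaves no gap of
  # radius d anywhere: insertion must jam
  jam <- as.matrix(lattice_configuration(1, sq_box(8)))
  expect_error(attempt_insertion(jam, sq_box(8), retry_cap = 200),
               "jammed after 200")
})

test_that("metropolis_step accepts all proposals on a flat landscape", {
  pat <- stripe_pattern(1, 1)
  empty <- matrix(numeric(0), ncol = 2)
  set.seed(3)
  pos <- c(10, 10)
  steps <- matrix(NA_real_, 400, 2)
  for (i in 1:400) {
    new <- metropolis_step(pos, empty, pat, box20, pot_default)
    expect_true(attr(new, "accepted"))
    d <- min_image(pos, as.double(new), box20)$disp
    steps[i, ] <- d
    pos <- as.double(new)
  }
  # per-axis displacement uniform on [-0.5, 0.5]
  expect_true(all(abs(steps) <= 0.5))
  ks <- suppressWarnings(stats::ks.test(steps[, 1], "punif", -0.5, 0.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("proposals overlapping a quenched particle are always rejected", {
  pat <- stripe_pattern(1, 1)
  # ring of quenched particles so tight that any proposal from the centre
  # that moves more than a little lands inside a core; run many steps and
  # verify the mobile particle's energy stays finite (never enters a core)
  set.seed(4)
  centre <- c(10, 10)
  ring <- t(vapply(seq(0, 2 * pi, length.out = 13)[-13],
                   function(a) centre + 1.05 * c(cos(a), sin(a)),
                   numeric(2)))
  pos <- centre
  for (i in 1:300) {
    pos <- as.double(metropolis_step(pos, ring, pat, box20, pot_default))
    e <- particle_energy(pos, ring, pat, box20, pot_default)
    expect_true(is.finite(e))
  }
})

test_that("a realization reaches the target count with hard cores intact", {
  sim <- sq_sim_params(moves = 150, realizations = 1)
  cfg <- run_realization(box20, stripe_pattern(1, 1), pot_default, sim,
                         seed = 11)
  expect_equal(nrow(cfg), 120)          # round(0.3 * 400)
  expect_true(all(cfg$x >= 0 & cfg$x < 20 & cfg$y >= 0 & cfg$y < 20))
  dmin <- min(vapply(2:nrow(cfg), function(i)
    min(min_image_pairwise(cfg, i, 20)), numeric(1)))
  expect_gte(dmin, 1)
  # 1000 d^2 box holds 300 particles
  cfg2 <- run_realization(sq_box(sqrt(1000)), stripe_pattern(1, 1),
                          pot_default, sq_sim_params(moves = 30), seed = 12)
  expect_equal(nrow(cfg2), 300)
})

test_that("runs are deterministic in the seed and ensembles derive per-realization streams", {
  sim <- sq_sim_params(moves = 60, realizations = 3)
  a <- run_realization(box20, stripe_pattern(0.1, 1), pot_default, sim, 99)
  b <- run_realization(box20, stripe_pattern(0.1, 1), pot_default, sim, 99)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_identical(a$energy, b$energy)
  e1 <- run_ensemble(box20, stripe_pattern(0.1, 1), pot_default, sim, 7)
  e2 <- run_ensemble(box20, stripe_pattern(0.1, 1), pot_default, sim, 7)
  expect_identical(lapply(e1, `[[`, "x"), lapply(e2, `[[`, "x"))
  # realization k of the ensemble is a plain run at the derived seed
  direct <- run_realization(box20, stripe_pattern(0.1, 1), pot_default, sim,
                            derive_seed(7, 2))
  expect_identical(e1[[2]]$x, direct$x)
  # different realizations differ
  expect_false(identical(e1[[1]]$x, e1[[2]]$x))
})

test_that("single free particle ends uniformly distributed and diffuses linearly", {
  pat <- stripe_pattern(1, 1)
  edges <- c(20 / 3, 40 / 3, 20)
  set.seed(21)
  finals <- t(vapply(1:600, function(i) {
    start <- runif(2, 0, 20)
    w <- cpp_metropolis_walk(start[1], start[2], numeric(0), numeric(0),
                             20, 1.5, 1, 1, edges, c(1, 1, 1), 0.5, 400, 0)
    w[nrow(w), ]
  }, numeric(2)))
  ks <- suppressWarnings(stats::ks.test(finals[, 1], "punif", 0, 20))
  expect_gt(ks$p.value, 0.01)
  # mean squared displacement grows linearly: each axis accumulates
  # var = steps * (1/12) * (0.5)^2... i.e. step variance of U(-0.5, 0.5)
  set.seed(22)
  for (steps in c(100, 400)) {
    msd <- mean(vapply(1:400, function(i) {
      w <- cpp_metropolis_walk(50, 50, numeric(0), numeric(0),
                               100, 1.5, 1, 1, c(100 / 3, 200 / 3, 100),
                               c(1, 1, 1), 0.5, steps, 0)
      sum((w[nrow(w), ] - c(50, 50))^2)
    }, numeric(1)))
    expected <- 2 * steps * (1 / 12)    # two axes, U(-0.5,0.5) variance 1/12
    expect_equal(msd, expected, tolerance = 0.15)
  }
})

test_that("a deep well captures the diffusing particle within the well range", {
  # one quenched neighbour with eps/U = 1e4: after diffusion the particle
  # should sit inside [d, lambda d] of the neighbour almost always
  pat_deep <- stripe_pattern(1e-4, 1e-4)
  edges <- c(20 / 3, 40 / 3, 20)
  # start inside the well: with eps/U = 1e4 the escape probability per
  # uphill attempt is ~exp(-1e4 * dr) and the particle must still be bound
  # at quench time essentially always
  set.seed(31)
  captured <- vapply(1:300, function(i) {
    repeat {
      start <- c(10, 10) + runif(2, -1.45, 1.45)
      d0 <- min_image(start, c(10, 10), box20)$distance
      if (d0 >= 1 && d0 <= 1.45) break
    }
    w <- cpp_metropolis_walk(start[1], start[2], 10, 10, 20, 1.5, 1, 1,
                             edges, rep(1e-4, 3), 0.5, 2000, 0)
    d <- min_image(w[nrow(w), ], c(10, 10), box20)$distance
    d >= 1 && d <= 1.5
  }, logical(1))
  expect_gte(mean(captured), 0.99)
})

test_that("diffusion lowers the energy of almost every insertion in the deep-well regime", {
  sim <- sq_sim_params(moves = 500, realizations = 4)
  ens <- run_ensemble(box20, stripe_pattern(0.01, 0.01), pot_default, sim,
                      seed = 41)
  quench <- unlist(lapply(ens, `[[`, "energy"))
  init <- unlist(lapply(ens, `[[`, "energy_init"))
  expect_gte(mean(quench <= init + 1e-12), 0.95)
})

test_that("R diffusion path agrees statistically with the compiled engine", {
  # same landscape, same move budget: the mean quench distance to a single
  # attractive neighbour must match between metropolis_step/diffuse_and_quench
  # and cpp_metropolis_walk
  pat <- stripe_pattern(0.2, 0.2)
  others <- rbind(c(10, 10))
  edges <- c(20 / 3, 40 / 3, 20)
  set.seed(51)
  dr_r <- vapply(1:60, function(i) {
    p <- diffuse_and_quench(c(12, 10), others, pat, box20, pot_default,
                            moves = 150)
    min_image(as.double(p), c(10, 10), box20)$distance
  }, numeric(1))
  dr_c <- vapply(1:60, function(i) {
    w <- cpp_metropolis_walk(12, 10, 10, 10, 20, 1.5, 1, 1, edges,
                             rep(0.2, 3), 0.5, 150, 0)
    min_image(w[nrow(w), ], c(10, 10), box20)$distance
  }, numeric(1))
  expect_gt(stats::t.test(dr_r, dr_c)$p.value, 0.01)
})

test_that("zero move budget quenches at the insertion point", {
  sim <- sq_sim_params(moves = 0, realizations = 1)
  cfg <- run_realization(box20, stripe_pattern(1e-4, 1), pot_default, sim, 61)
  expect_equal(cfg$energy, cfg$energy_init)
  # with no diffusion the occupancy must follow the area fractions (RSA)
  sim2 <- sq_sim_params(moves = 0, realizations = 20)
  ens <- run_ensemble(box20, stripe_pattern(1e-4, 1), pot_default, sim2, 62)
  occ <- region_occupancy(ens)
  expect_lt(abs(occ$mean_fraction[2] - 1 / 3), 4 * occ$se[2] + 0.02)
})
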