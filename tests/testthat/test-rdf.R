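box20 <- sq_box(20)

# independent O(N^2) reference: explicit double loop, own min-image code
ref_histogram <- function(cfgs, L, dr, rmax) {
  nb <- floor(rmax / dr + 1e-9)
  counts <- integer(nb)
  for (cf in cfgs) {
    n <- length(cf$x)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dx <- cf$x[i] - cf$x[j]; dx <- dx - L * round(dx / L)
      dy <- cf$y[i] - cf$y[j]; dy <- dy - L * round(dy / L)
      r <- sqrt(dx^2 + dy^2)
      if (r < nb * dr) {
        b <- floor(r / dr) + 1
        counts[b] <- counts[b] + 1L
      }
    }
  }
  counts
}

test_that("pair histogram bins each unordered pair once, in the right bin", {
  cfg <- list(x = c(1, 1), y = c(2, 3.2))   # single pair at distance 1.2
  h <- accumulate_pair_histogram(list(cfg), box20, dr = 0.1)
  expect_equal(sum(h), 1)
  expect_equal(as.integer(h[13]), 1L)       # [1.2, 1.3) is bin 13
  # a pair wrapped across the boundary: (1,0)-(19,0) at distance 2
  cfg2 <- list(x = c(1, 19), y = c(0, 0))
  h2 <- accumulate_pair_histogram(list(cfg2), box20, dr = 0.5)
  expect_equal(as.integer(h2[5]), 1L)       # [2.0, 2.5)
  expect_error(accumulate_pair_histogram(list(cfg), box20, dr = 0.1,
                                         rmax = 12), "half the box")
})

test_that("histogram counts match the brute-force double loop exactly", {
  set.seed(71)
  for (trial in 1:20) {
    cfgs <- lapply(1:3, function(k)
      list(x = runif(10, 0, 20), y = runif(10, 0, 20)))
    h <- accumulate_pair_histogram(cfgs, box20, dr = 0.13, rmax = 9)
    expect_identical(as.integer(h), ref_histogram(cfgs, 20, 0.13, 9))
  }
})

test_that("normalization applies the lower-edge linear-shell formula", {
  # one pair in bin [1.15, 1.25), two particles, one configuration, 20d box
  counts <- integer(24)
  counts[12] <- 1L
  edges <- seq(0.05, 2.45, by = 0.1)   # bin 12 is [1.15, 1.25)
  rdf <- normalize_rdf(counts, N = 2, n = 1, rho = 2 / 400,
                       bin_edges = edges)
  expect_equal(rdf$g[12], 276.791205377, tolerance = 1e-9)
  expect_equal(rdf$r[12], 1.2)
  # empty bins give g = 0 exactly
  expect_true(all(rdf$g[-12] == 0))
  # exact-shell mode divides by the half-annulus area instead
  rdf2 <- normalize_rdf(counts, N = 2, n = 1, rho = 2 / 400,
                        bin_edges = edges, mode = "shell")
  expect_equal(rdf2$g[12], 1 / (pi * (1.25^2 - 1.15^2) / 2 * (2 / 400) * 2))
  expect_error(normalize_rdf(counts, N = 2, n = 1, rho = 0.005,
                             bin_edges = rep(1, 25)), "positive width")
})

test_that("ideal-gas ensembles calibrate g to 1 within statistical error", {
  ens <- ideal_gas_ensemble(N = 120, box = box20, n = 80, seed = 81)
  for (mode in c("literal", "shell")) {
    rdf <- sq_rdf(ens, box = box20, mode = mode)
    sel <- rdf$r >= 2 & rdf$r <= 5
    m <- mean(rdf$g[sel])
    se <- sqrt(sum(rdf$se[sel]^2)) / sum(sel)
    expect_lt(abs(m - 1), 3 * se + 0.02)
  }
})

test_that("hard-core input yields g = 0 below contact", {
  ens <- run_ensemble(box20, stripe_pattern(0.1, 1), sq_potential(),
                      sq_sim_params(moves = 100, realizations = 5), seed = 91)
  rdf <- sq_rdf(ens)
  expect_true(all(rdf$g[rdf$r < 1] == 0))
  expect_true(all(rdf$count[rdf$r < 1] == 0L))
})

test_that("g decays to 1 at large r for homogeneous runs", {
  ens <- run_ensemble(box20, stripe_pattern(1, 1), sq_potential(),
                      sq_sim_params(moves = 300, realizations = 30),
                      seed = 92)
  rdf <- sq_rdf(ens)
  sel <- rdf$r >= 5 & rdf$r <= 9
  expect_lt(abs(mean(rdf$g[sel]) - 1), 0.05)
})

test_that("lattice RDF peaks at the analytic neighbour distances", {
  cfg <- lattice_configuration(2, box20)
  expect_equal(nrow(cfg), 100)
  rdf <- sq_rdf(list(cfg), box = box20, dr = 0.05)
  nz <- rdf$r[rdf$count > 0]
  expect_equal(min(nz), 2.025)                       # first shell at r = 2
  expect_true(all(rdf$count[rdf$r < 2] == 0L))
  # second shell at 2*sqrt(2): the containing bin is populated
  expect_gt(rdf$count[findInterval(2 * sqrt(2), attr(rdf, "bin_edges"))], 0)
})

test_that("first_peak scans [d, lambda d] and breaks ties toward smaller r", {
  edges <- seq(0, 3, by = 0.1)
  counts <- integer(30)
  counts[c(12, 14)] <- c(50L, 50L)  # bins centred at 1.15 and 1.35
  rdf <- normalize_rdf(counts, N = 50, n = 1, rho = 0.3, bin_edges = edges,
                       mode = "shell")
  # shell mode: equal counts give the smaller-r bin the larger g, but make
  # the literal-mode tie explicit too
  pk <- first_peak(rdf)
  expect_lt(pk$r, 1.2)
  rdf$g[c(12, 14)] <- 3              # exact tie in g
  expect_equal(first_peak(rdf)$r, 1.15)
  expect_error(first_peak(rdf, rmin = 2.8, rmax = 2.85), "no bins")
  # ideal gas has no structure: peak height near 1
  ens <- ideal_gas_ensemble(N = 200, box = box20, n = 40, seed = 93)
  expect_lt(abs(first_peak(sq_rdf(ens, box = box20))$g - 1), 0.15)
})

test_that("halving the bin width preserves the well integral of rho 2 pi r g", {
  ens <- run_ensemble(box20, stripe_pattern(0.5, 1), sq_potential(),
                      sq_sim_params(moves = 200, realizations = 20),
                      seed = 94)
  integral <- function(dr) {
    rdf <- sq_rdf(ens, dr = dr, mode = "shell")
    sel <- rdf$r > 1 & rdf$r < 1.5
    rho <- attr(rdf, "rho")
    sum(rho * 2 * pi * rdf$r[sel] * rdf$g[sel] * dr)
  }
  i1 <- integral(0.05)
  i2 <- integral(0.025)
  expect_equal(i1, i2, tolerance = 0.08)
})

test_that("region occupancy aggregates per-realization fractions", {
  pat <- stripe_pattern(1, 1)
  # uniform points: each stripe near its area fraction
  ens <- ideal_gas_ensemble(N = 300, box = box20, n = 40, seed = 95)
  occ <- region_occupancy(ens, pattern = pat, box = box20)
  expect_equal(occ$area_fraction, rep(1 / 3, 3))
  expect_true(all(abs(occ$mean_fraction - 1 / 3) < 4 * occ$se + 0.01))
  expect_equal(sum(occ$mean_fraction), 1)
  # all particles in R1
  cfg <- list(x = rep(2, 10), y = seq(1, 19, 2))
  occ2 <- region_occupancy(list(cfg), pattern = pat, box = box20)
  expect_equal(occ2$mean_fraction, c(1, 0, 0))
})
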