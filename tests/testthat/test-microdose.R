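# Dose-distribution container, convolution engine, compound-Poisson NDD,
# SHNDD / Monte Carlo NDD consistency, and distribution comparison.

test_that("dose_distribution enforces normalization and moment consistency", {
  edges <- seq(0, 1, length.out = 11)
  dens <- rep(1, 10)
  d <- dose_distribution(edges, dens)
  expect_equal(d$zero_mass + sum(d$density * diff(edges)), 1,
               tolerance = 1e-12)
  expect_equal(d$mean, 0.5, tolerance = 1e-12)
  expect_error(dose_distribution(edges, dens * 2), "mass")
  expect_error(dose_distribution(edges, dens, mean = 0.7), "inconsistent")
  expect_error(dose_distribution(edges, -dens), "non-negative")
  expect_error(dose_distribution(c(0, 0.1, 0.3), c(5, 5)), "uniformly")
})

test_that("poisson_pmf matches closed forms and the truncation model", {
  expect_equal(poisson_pmf(0, 2.5), exp(-2.5))
  expect_equal(poisson_pmf(2, 1.0), exp(-1) / 2, tolerance = 1e-12)
  expect_equal(poisson_pmf(2, 1.0), 0.18394, tolerance = 1e-4)
  hm <- hit_number_model(3, tail_tol = 1e-9)
  expect_lt(1 - sum(poisson_pmf(0:hm$truncation, 3)), 1e-9)
  expect_error(poisson_pmf(-1, 1), "non-negative")
  expect_error(poisson_pmf(1, -1), "lam")
})

test_that("self_convolve: identity, delta shifting, enumeration oracle", {
  f1 <- dd_point_mass(0.1, 0.0125, 64)
  expect_identical(self_convolve(f1, 1), f1)
  # point mass at q convolves to a point mass at i*q
  f3 <- self_convolve(f1, 3)
  mids <- f3$bin_edges[-length(f3$bin_edges)] + diff(f3$bin_edges) / 2
  expect_equal(sum(f3$density * diff(f3$bin_edges) * mids), 0.3,
               tolerance = 1e-9)
  expect_equal(mids[which.max(f3$density)], 0.3, tolerance = 1e-9)
  # two-atom distribution, i = 3: exhaustive enumeration of 2^3 outcomes
  bw <- 0.01
  edges <- (seq_len(9) - 0.5) * bw
  dens <- numeric(8)
  dens[2] <- 0.25 / bw   # z = 0.02 with p = 0.25
  dens[5] <- 0.75 / bw   # z = 0.05 with p = 0.75
  f2 <- dose_distribution(edges, dens)
  g <- self_convolve(f2, 3)
  pmf_at <- function(d, z) {
    k <- round(z / bw) + 1
    d$density[k] * bw
  }
  outcomes <- expand.grid(a = c(0.02, 0.05), b = c(0.02, 0.05),
                          c = c(0.02, 0.05))
  probs <- apply(outcomes, 1, function(r)
    prod(ifelse(r == 0.02, 0.25, 0.75)))
  sums <- rowSums(outcomes)
  for (s in unique(sums)) {
    expect_equal(pmf_at(g, s), sum(probs[abs(sums - s) < 1e-12]),
                 tolerance = 1e-9)
  }
  expect_equal(g$mean, 3 * f2$mean, tolerance = 1e-9)
})

test_that("analytic_ndd conserves mass and mean and matches Poisson for a
           degenerate SHNDD", {
  q <- 0.08
  f1 <- dd_point_mass(q, q / 64, 128)
  zbar <- 0.2
  ndd <- analytic_ndd(f1, zbar)
  lam <- zbar / q
  expect_equal(ndd$zero_mass, exp(-lam), tolerance = 1e-9)
  dz <- diff(ndd$bin_edges)
  expect_equal(ndd$zero_mass + sum(ndd$density * dz), 1, tolerance = 1e-9)
  expect_equal(ndd$mean, zbar, tolerance = 1e-6)
  # pmf on the lattice {0, q, 2q, ...} equals Poisson(lam)
  mids <- ndd$bin_edges[-length(ndd$bin_edges)] + dz / 2
  for (i in 1:6) {
    sel <- abs(mids - i * q) < q / 2 - 1e-12
    expect_equal(sum(ndd$density[sel] * dz[sel]), poisson_pmf(i, lam),
                 tolerance = 1e-9)
  }
  # zbar = 0 collapses to a pure zero atom
  n0 <- analytic_ndd(f1, 0)
  expect_equal(n0$zero_mass, 1)
  expect_equal(n0$mean, 0)
})

test_that("analytic_ndd normalization/mean hold for arbitrary SHNDDs", {
  set.seed(41)
  for (k in 1:20) {
    f1 <- random_shndd()
    zbar <- runif(1, 0.05, 0.8)
    ndd <- analytic_ndd(f1, zbar)
    dz <- diff(ndd$bin_edges)
    expect_equal(ndd$zero_mass + sum(ndd$density * dz), 1, tolerance = 1e-6)
    expect_equal(ndd$mean, zbar, tolerance = 1e-3 * zbar)
    expect_equal(ndd$zero_mass, exp(-zbar / f1$mean), tolerance = 1e-6)
  }
})

test_that("single centered track yields a point-mass SHNDD at the oracle dose", {
  # 4.3-um nucleus slab sitting on the foil (5 background layers below it)
  v <- slab_volume(nz_nuc = 10, nxy = 60, voxel = c(192, 192, 430),
                   origin = c(0, 0, 1.4))
  tr <- data.frame(x_um = 10, y_um = 10, z_um = 0, dx = 0, dy = 0, dz = 1,
                   energy_kev = 5486)
  tf <- track_field(tr, 20 * 20)
  sh <- compute_shndd(tf, v, placements = 40, seed = 1, bins = 50)
  # oracle: mylar, then the background layers (water), then the slab chord
  e_foil <- stepper_residual(5486, 1.4 * 1.2)
  e_in <- stepper_residual(e_foil, 5 * 0.430)
  edep <- e_in - stepper_residual(e_in, 4.30)
  mass <- sum(v$labels == 201L) * prod(v$voxel_size) * 1e-27 * 1000
  z_exp <- edep * 1.602176634e-16 / mass
  expect_gt(attr(sh, "n_hits"), 0)
  expect_equal(attr(sh, "q"), z_exp, tolerance = 2e-3)
  # a vertical ray sees the same chord wherever it lands: a point mass
  expect_equal(sum(sh$density > 0), 1)
})

test_that("compute_shndd integrates to one and reports hits", {
  tf <- test_field(1500)
  cell <- test_cell()
  sh <- compute_shndd(tf, cell, placements = 40, seed = 6)
  expect_equal(sum(sh$density * diff(sh$bin_edges)), 1, tolerance = 1e-9)
  expect_identical(sh$zero_mass, 0)
  expect_gt(attr(sh, "n_hits"), 100)
  expect_gt(attr(sh, "q"), 0)
})

test_that("mean_energy_per_hit: exchangeability and enumeration oracle", {
  v <- slab_volume(nz_nuc = 10, nxy = 60, voxel = c(192, 192, 430),
                   origin = c(0, 0, 1.4))
  tr <- data.frame(x_um = 10, y_um = 10, z_um = 0, dx = 0, dy = 0, dz = 1,
                   energy_kev = 5486)
  tf <- track_field(tr, 20 * 20)
  m1 <- mean_energy_per_hit(tf, v, placements = 40, seed = 2)
  e_foil <- stepper_residual(5486, 1.4 * 1.2)
  e_in <- stepper_residual(e_foil, 5 * 0.430)
  expect_equal(m1, e_in - stepper_residual(e_in, 4.30), tolerance = 2e-3)
  # two identical cells give the same value as one
  m2 <- mean_energy_per_hit(tf, list(v, v), placements = 40, seed = 2)
  expect_equal(m2, m1, tolerance = 1e-9)
  # small-field enumeration oracle: mean of per-(placement, track) deposits
  tf2 <- test_field(300)
  cell <- test_cell()
  # mean_energy_per_hit seeds volume k with seed + k
  s <- alphamicro:::.shndd_samples(tf2, cell, placements = 10, seed = 10)
  z <- unlist(s$z)
  oracle <- sum(z) * s$mass_kg / 1.602176634e-16 / length(z)
  expect_equal(mean_energy_per_hit(tf2, cell, placements = 10, seed = 9),
               oracle, tolerance = 1e-9)
})

test_that("mc_ndd honors the track-number relation and the Poisson zero mass", {
  tf <- test_field(2000)
  cell <- test_cell()
  h <- cell_height_um(cell)
  dt <- total_dose(tf, layer_thickness = h)
  # zbar = D_total draws exactly N_total tracks
  mc <- mc_ndd(tf, cell, zbar = dt, reps = 50, seed = 3, placements = 20,
               layer_thickness = h)
  expect_equal(attr(mc, "n_per_rep"), tf$n_total)
  # zero mass agrees with the Poisson prediction from the measured q
  zbar <- 0.25
  mc2 <- mc_ndd(tf, cell, zbar, reps = 10000, seed = 4, placements = 150,
                layer_thickness = h)
  lam_hat <- zbar / dt * tf$n_total *
    attr(compute_shndd(tf, cell, placements = 150, seed = 4), "hit_prob")
  p0 <- exp(-lam_hat)
  se <- sqrt(p0 * (1 - p0) / 10000)
  expect_lt(abs(mc2$zero_mass - p0), 4 * se + 0.01)
})

test_that("distribution_rmse: zero for identical, symmetric, hand arithmetic", {
  f <- random_shndd()
  expect_equal(as.numeric(distribution_rmse(f, f)), 0)
  g <- random_shndd()
  expect_equal(as.numeric(distribution_rmse(f, g)),
               as.numeric(distribution_rmse(g, f)), tolerance = 0.15)
  # 3-bin hand computation on a shared grid
  edges <- c(0, 1, 2, 3)
  a <- dose_distribution(edges, c(0.5, 0.3, 0.2))
  b <- dose_distribution(edges, c(0.4, 0.4, 0.2))
  expect_equal(as.numeric(distribution_rmse(a, b)),
               sqrt(mean(c(0.1, -0.1, 0)^2)), tolerance = 1e-12)
  expect_equal(attr(distribution_rmse(a, b), "zero_mass_diff"), 0)
})

test_that("distributions serialize to TSV and back", {
  f <- analytic_ndd(dd_point_mass(0.1, 0.0125, 64), 0.3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distribution(f, path)
  g <- read_distribution(path)
  expect_equal(g$zero_mass, f$zero_mass, tolerance = 1e-12)
  expect_equal(g$mean, f$mean, tolerance = 1e-12)
  expect_equal(g$density, f$density, tolerance = 1e-8)
})
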