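# HCP geometry, emission sampling, sphere chords, and the spheroid
# Monte Carlo's equilibrium and scaling properties.

test_that("effective_radius follows the cube-root packing rule", {
  expect_equal(effective_radius(1, eta = 1), 1)
  expect_equal(effective_radius(1, eta = 0.740), 0.740^(1 / 3),
               tolerance = 1e-12)
  expect_equal(effective_radius(1), 0.9045, tolerance = 1e-4)
  # volume identity: sphere of R_eff has eta times the cell volume
  r <- 8.4
  expect_equal(effective_radius(r)^3, 0.740 * r^3, tolerance = 1e-12)
  expect_error(effective_radius(-1), "positive")
  expect_error(effective_radius(1, eta = 1.2), "eta")
})

test_that("HCP lattice has the right spacing, coordination and origin", {
  r_eff <- 3
  lat <- hcp_lattice(r_eff, extent = 20)
  ctr <- lat$centers
  # one center at the origin
  expect_true(any(rowSums(ctr^2) < 1e-18))
  # nearest-neighbor distance is exactly 2 r_eff; interior sites have 12
  d0 <- sqrt(rowSums(ctr^2))
  interior <- which(d0 < 20 - 2.1 * r_eff)
  for (i in interior[seq(1, length(interior), length.out = 12)]) {
    dd <- sqrt(rowSums(sweep(ctr, 2, ctr[i, ])^2))
    dd <- sort(dd)[-1]
    expect_equal(dd[1], 2 * r_eff, tolerance = 1e-9)
    expect_equal(sum(dd < 2 * r_eff * 1.001), 12)
  }
})

test_that("Monte Carlo packing fraction of the HCP spheres is 0.740", {
  r_eff <- 2
  lat <- hcp_lattice(r_eff, extent = 18)
  set.seed(61)
  n <- 2e5
  # sample points in an interior box commensurate with the orthorhombic
  # HCP supercell (a, a*sqrt(3), 2h) so no boundary bias enters
  a <- lat$a
  h <- a * sqrt(2 / 3)
  half <- c(1.5 * a, a * sqrt(3), 2 * h)
  p <- cbind(runif(n, -half[1], half[1]), runif(n, -half[2], half[2]),
             runif(n, -half[3], half[3]))
  ctr <- lat$centers
  keep <- rowSums(ctr^2) < (sqrt(sum(half^2)) + 2.1 * r_eff)^2
  ctr <- ctr[keep, , drop = FALSE]
  inside <- rep(FALSE, n)
  for (i in seq_len(nrow(ctr))) {
    di <- (p[, 1] - ctr[i, 1])^2 + (p[, 2] - ctr[i, 2])^2 +
      (p[, 3] - ctr[i, 3])^2
    inside <- inside | di < r_eff^2
  }
  expect_equal(mean(inside), pi / (3 * sqrt(2)), tolerance = 0.002 / 0.74)
})

test_that("emission origins respect each scenario's support", {
  cfg <- spheroid_config("in_nucleus", seed = 1)
  lat <- hcp_lattice(cfg$r_eff, extent = 40)
  set.seed(62)
  em <- sample_emission(2000, "in_nucleus", lat, cfg)
  dmin <- nearest_center_distance(em$origin, lat$centers)
  expect_true(all(dmin <= cfg$r_nucleus + 1e-9))
  em2 <- sample_emission(2000, "on_nuclear_membrane", lat, cfg)
  dmin2 <- nearest_center_distance(em2$origin, lat$centers)
  expect_true(all(abs(dmin2 - cfg$r_nucleus) < 1e-9))
  em3 <- sample_emission(2000, "on_cell_membrane", lat, cfg)
  dmin3 <- nearest_center_distance(em3$origin, lat$centers)
  expect_true(all(dmin3 <= cfg$r_eff + 1e-9))
  # cell-membrane origins sit exactly R_eff from some center
  on_sphere <- abs(center_distances(em3$origin, lat$centers) - cfg$r_eff) <
    1e-9
  expect_true(all(apply(on_sphere, 1, any)))
  # cytoplasm origins exclude every nucleus
  em4 <- sample_emission(2000, "in_cytoplasm", lat, cfg)
  dmin4 <- nearest_center_distance(em4$origin, lat$centers)
  expect_true(all(dmin4 >= cfg$r_nucleus - 1e-9))
  expect_error(sample_emission(10, "bogus", lat, cfg), "unknown scenario")
})

test_that("emission directions are isotropic", {
  cfg <- spheroid_config("in_nucleus", seed = 1)
  lat <- hcp_lattice(cfg$r_eff, extent = 30)
  set.seed(63)
  u <- sample_emission(1e5, "in_nucleus", lat, cfg)$direction
  # first moments ~ 0, second moments ~ 1/3
  expect_true(all(abs(colMeans(u)) < 4 / sqrt(1e5)))
  expect_equal(unname(colMeans(u^2)), rep(1 / 3, 3), tolerance = 0.02)
})

test_that("sphere_chords matches closed forms and the sampling oracle", {
  # through the center: chord = 2r
  ch <- sphere_chords(c(-10, 0, 0), c(1, 0, 0), matrix(c(0, 0, 0), 1), 3)
  expect_equal(ch$chord, 6, tolerance = 1e-12)
  # tangent ray: no chord
  ch2 <- sphere_chords(c(-10, 3, 0), c(1, 0, 0), matrix(c(0, 0, 0), 1), 3)
  expect_equal(nrow(ch2), 0)
  # ordering by entry over several spheres
  ctrs <- rbind(c(5, 0, 0), c(15, 0, 0), c(10, 0, 0))
  ch3 <- sphere_chords(c(0, 0.5, 0), c(1, 0, 0), ctrs, 2)
  expect_equal(ch3$index, c(1, 3, 2))
  expect_true(all(diff(ch3$entry) > 0))
  # random rays against the 1-nm sampling oracle (within 2 nm)
  set.seed(64)
  for (k in 1:100) {
    c0 <- runif(3, -4, 4)
    r0 <- runif(1, 0.5, 3)
    dir <- alphamicro:::.isotropic_dirs(1)[1, ]
    o <- runif(3, -8, 8)
    ch <- sphere_chords(o, dir, matrix(c0, 1), r0)
    got <- if (nrow(ch) == 0) 0 else sum(ch$chord)
    oracle <- sampling_sphere_chord(o, dir, c0, r0, t_max = 30)
    expect_lt(abs(got - oracle), 2e-3 + 2e-3)
  }
})

test_that("uniform emission control sits at dose-ratio equilibrium", {
  res <- simulate_scenario(spheroid_config("uniform", target_hits = 4000,
                                           seed = 21))
  # unbounded uniform source in a uniform medium: equal dose everywhere
  expect_lt(abs(res$dose_ratio - 1), 2 * sqrt(2) * res$se_mean_dose + 0.01)
  expect_equal(res$n_hits, 4000L)
  expect_gt(res$mean_nucleus_dose, 0)
})

test_that("Monte Carlo standard error shrinks as 1/sqrt(hits)", {
  r1 <- simulate_scenario(spheroid_config("in_nucleus", target_hits = 2000,
                                          seed = 22))
  r2 <- simulate_scenario(spheroid_config("in_nucleus", target_hits = 8000,
                                          seed = 22))
  expect_equal(r2$se_mean_dose / r1$se_mean_dose, 0.5, tolerance = 0.3)
  expect_equal(r2$n_hits, 8000L)
})

test_that("transport energy bookkeeping closes along a contained ray", {
  # a particle emitted at the center deposits its full energy within its
  # range: nucleus + cytoplasm-sphere partition reconstructed from the
  # range-inversion energies
  e0 <- 5486
  r <- csda_range(e0)
  t <- c(2, 5, r)
  e_at <- alphamicro:::.energy_at_depth(e0, t)
  dep <- e0 - e_at
  expect_equal(dep[3], e0, tolerance = 1e-4 * e0)
  # segment additivity
  seg1 <- e0 - e_at[1]
  seg2 <- e_at[1] - e_at[2]
  expect_equal(seg1 + seg2, e0 - e_at[2], tolerance = 1e-9)
})

test_that("scenario results replay identically under the stored seed", {
  cfg <- spheroid_config("on_cell_membrane", target_hits = 800, seed = 23)
  r1 <- simulate_scenario(cfg)
  r2 <- simulate_scenario(cfg)
  expect_identical(r1$dose_ratio, r2$dose_ratio)
  expect_identical(r1$n_emissions, r2$n_emissions)
})

test_that("energy_sweep reports ranges and one row per scenario-energy", {
  cfg <- spheroid_config("in_nucleus", seed = 24, target_hits = 500)
  tab <- energy_sweep(cfg, energies = c(5486, 9000),
                      scenarios = c("in_nucleus", "on_cell_membrane"))
  expect_equal(nrow(tab), 4)
  expect_equal(tab$range_um, rep(csda_range(c(5486, 9000)), 2),
               tolerance = 1e-12)
  expect_equal(tab$range_cell_radii, tab$range_um / cfg$r_cell,
               tolerance = 1e-12)
  expect_true(all(tab$n_hits == 500))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(spheroid_config("in_nucleus", nucleus_fraction = 1.2),
               "nucleus_fraction")
  expect_error(spheroid_config("in_nucleus", eta = 0.8), "eta")
  expect_error(spheroid_config("in_nucleus", emission_energy = 3000),
               "emission_energy")
  expect_error(spheroid_config("wrong"), "arg")
})
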