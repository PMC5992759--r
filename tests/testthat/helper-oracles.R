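# Independent oracles and fixture builders shared across the test files.

# Brute-force continuous-slowing-down stepper: explicit Euler energy loss in
# fixed steps (default 1 nm of water). Independent of the range-inversion
# implementation in the package; only the interpolated LET curve is shared.
stepper_residual <- function(energy_kev, thickness_um, step_um = 1e-3) {
  e <- energy_kev
  s <- 0
  while (s < thickness_um && e > 10) {
    e <- e - let_water(e) * step_um
    s <- s + step_um
  }
  if (e <= 10) 0 else e
}

stepper_range <- function(energy_kev, step_um = 1e-3) {
  e <- energy_kev
  s <- 0
  while (e > 10) {
    e <- e - let_water(e) * step_um
    s <- s + step_um
  }
  s
}

# Point-sampling chord oracle: samples positions along a ray at a fixed step
# and counts label occupancy, giving per-label path lengths within one step
# of the exact traversal. Vectorized; step in um.
sampling_path_lengths <- function(start, dir, vol, t_max, step_um = 1e-3) {
  t <- seq(step_um / 2, t_max, by = step_um)
  px <- start[1] + dir[1] * t
  py <- start[2] + dir[2] * t
  pz <- start[3] + dir[3] * t
  vs <- vol$voxel_size * 1e-3
  d <- dim(vol$labels)
  ix <- floor((px - vol$origin[1]) / vs[1]) + 1
  iy <- floor((py - vol$origin[2]) / vs[2]) + 1
  iz <- floor((pz - vol$origin[3]) / vs[3]) + 1
  ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
  lab <- rep(0L, length(t))
  lab[ok] <- vol$labels[cbind(ix[ok], iy[ok], iz[ok])]
  c(tau2 = sum(lab == 182L) * step_um,
    tau3 = sum(lab == 201L) * step_um)
}

# Uniform-in-ball sphere-chord oracle by 1-nm point sampling along the ray.
sampling_sphere_chord <- function(origin, dir, center, radius, t_max,
                                  step_um = 1e-3) {
  t <- seq(step_um / 2, t_max, by = step_um)
  px <- origin[1] + dir[1] * t
  py <- origin[2] + dir[2] * t
  pz <- origin[3] + dir[3] * t
  inside <- (px - center[1])^2 + (py - center[2])^2 + (pz - center[3])^2 <
    radius^2
  sum(inside) * step_um
}

# A small slab-nucleus volume: nz_nuc nucleus z-layers (430 nm each)
# sandwiched in background, spanning the full lateral extent.
slab_volume <- function(nz_nuc = 10, nxy = 40, voxel = c(96, 96, 430),
                        origin = c(0, 0, 0)) {
  nz <- nz_nuc + 10
  lab <- array(0L, dim = c(nxy, nxy, nz))
  lab[, , 6:(5 + nz_nuc)] <- 201L
  label_volume(lab, voxel, origin)
}

# Distance matrix from points (n x 3) to lattice centers (m x 3).
center_distances <- function(points, centers) {
  d2 <- outer(rowSums(points^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(points)), rowSums(centers^2)) -
    2 * points %*% t(centers)
  sqrt(pmax(d2, 0))
}

nearest_center_distance <- function(points, centers)
  apply(center_distances(points, centers), 1, min)

# Number of nucleus voxels with at least one non-nucleus 6-neighbor: bounds
# the voxelization error of the nucleus volume.
surface_voxel_bound <- function(vol) {
  m <- vol$labels == 201L
  d <- dim(m)
  interior <- m
  interior[] <- FALSE
  ix <- 2:(d[1] - 1); iy <- 2:(d[2] - 1); iz <- 2:(d[3] - 1)
  interior[ix, iy, iz] <-
    m[ix, iy, iz] &
    m[ix - 1, iy, iz] & m[ix + 1, iy, iz] &
    m[ix, iy - 1, iz] & m[ix, iy + 1, iz] &
    m[ix, iy, iz - 1] & m[ix, iy, iz + 1]
  sum(m) - sum(interior)
}

# Random single-hit distributions for property tests: binned gamma densities
# with random shape/scale, normalized on a uniform grid.
random_shndd <- function(bins = 120) {
  shape <- runif(1, 1.5, 8)
  q_target <- runif(1, 0.03, 0.2)
  scale <- q_target / shape
  z_max <- stats::qgamma(1 - 1e-6, shape, scale = scale)
  edges <- seq(0, z_max, length.out = bins + 1)
  dens <- diff(stats::pgamma(edges, shape, scale = scale)) / diff(edges)
  dens <- dens / sum(dens * diff(edges))
  dose_distribution(edges, dens)
}

# Standard small study fixtures: a collimated field over a 150-um square and
# an oblate U87-like cell (nucleus 7.5 x 7.5 x 3.14 um = 740 um^3).
test_field <- function(n = 3000, seed = 2, side = 150)
  generate_collimated_field(n, side^2, seed = seed)

test_cell <- function()
  generate_synthetic_cell(c(7.5, 7.5, 3.14), cyto_margin = 1.0)

cell_height_um <- function(vol) dim(vol$labels)[3] * vol$voxel_size[3] * 1e-3
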