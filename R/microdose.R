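## Specific-energy (dose) distributions in the cell nucleus.
##
## The single-hit nucleus dose distribution (SHNDD) f1(z) is the distribution
## of specific energy z deposited by exactly one traversing particle,
## conditional on a hit; its mean is q. At mean absorbed dose zbar the number
## of hits is Poisson with lambda = zbar / q and the nucleus dose distribution
## (NDD) is the compound-Poisson mixture
##   f(z, zbar) = exp(-lambda) * delta(z) + sum_i p(i, lambda) f1*^i(z),
## where f1*^i is the i-fold convolution of the SHNDD. Distributions carry an
## explicit zero-dose mass for the delta term.

#' Binned specific-energy distribution with explicit zero-dose mass
#'
#' @param bin_edges Uniformly spaced bin edges in Gy (length `nbins + 1`,
#'   starting at or below 0).
#' @param density Probability density per Gy on each bin (`>= 0`).
#' @param zero_mass Probability of exactly zero dose (the delta(z) term).
#' @param mean First moment in Gy; computed from the bins when omitted.
#' @return An object of class `dose_distribution`. The invariant
#'   `zero_mass + sum(density * dz) = 1` is enforced to 1e-6.
#' @export
dose_distribution <- function(bin_edges, density, zero_mass = 0,
                              mean = NULL) {
  stopifnot(length(bin_edges) == length(density) + 1)
  dz <- diff(bin_edges)
  if (max(abs(dz - dz[1])) > 1e-9 * dz[1])
    stop("bin_edges must be uniformly spaced")
  if (any(density < -1e-12)) stop("density must be non-negative")
  density <- pmax(density, 0)
  tot <- zero_mass + sum(density * dz)
  if (abs(tot - 1) > 1e-6)
    stop(sprintf("distribution mass is %.8f, not 1", tot))
  mids <- bin_edges[-length(bin_edges)] + dz / 2
  m <- sum(density * dz * mids)
  if (is.null(mean)) mean <- m
  else if (m > 0 && abs(mean - m) > 1e-6 * max(mean, 1e-12) + 1e-9)
    stop("stated mean is inconsistent with the binned moments")
  structure(list(bin_edges = bin_edges, density = density,
                 zero_mass = zero_mass, mean = mean),
            class = "dose_distribution")
}

#' @export
print.dose_distribution <- function(x, ...) {
  cat(sprintf(
    "<dose_distribution> %d bins on [%g, %g] Gy; zero mass %.4g; mean %.4g Gy\n",
    length(x$density), min(x$bin_edges), max(x$bin_edges), x$zero_mass,
    x$mean))
  invisible(x)
}

# bin centers
.dd_mids <- function(d) {
  dz <- diff(d$bin_edges)
  d$bin_edges[-length(d$bin_edges)] + dz / 2
}

.dd_binwidth <- function(d) d$bin_edges[2] - d$bin_edges[1]

#' Point-mass dose distribution on a lattice grid
#'
#' Distribution concentrated at `z0 = k * bin_width` for integer `k`; handy
#' for closed-form compound-Poisson checks.
#'
#' @param z0 Location in Gy (must be an integer multiple of `bin_width`).
#' @param bin_width Grid spacing in Gy.
#' @param n_bins Number of bins (grid covers `(0, n_bins * bin_width]`).
#' @return A `dose_distribution` with all mass in the bin containing `z0`.
#' @export
dd_point_mass <- function(z0, bin_width, n_bins) {
  k <- round(z0 / bin_width)
  if (abs(k * bin_width - z0) > 1e-9 * bin_width)
    stop("z0 must be an integer multiple of bin_width")
  if (k < 1 || k > n_bins) stop("z0 outside the grid")
  # bin centers sit at integer multiples of bin_width: edges (j +- 1/2) * bw
  edges <- (seq_len(n_bins + 1) - 0.5) * bin_width
  dens <- numeric(n_bins)
  dens[k] <- 1 / bin_width
  dose_distribution(edges, dens, zero_mass = 0, mean = z0)
}

#' Poisson hit-number probability
#'
#' Probability of `i` particles traversing the nucleus when the mean hit
#' number is `lam = zbar / q`. Thin wrapper over the numerically stable
#' base-R Poisson mass function.
#'
#' @param i Non-negative hit count (vectorized).
#' @param lam Mean hit number, `>= 0`.
#' @return Probability.
#' @export
poisson_pmf <- function(i, lam) {
  if (any(i < 0) || any(i != floor(i))) stop("i must be a non-negative integer")
  if (any(lam < 0)) stop("lam must be >= 0")
  dpois(i, lam)
}

#' Poisson truncation model
#'
#' Smallest hit count `N` such that the neglected upper Poisson tail is
#' below `tail_tol` ("N chosen as a very large number").
#'
#' @param lam Mean hit number.
#' @param tail_tol Neglected-tail bound (default 1e-9).
#' @return List with `lam` and `truncation`.
#' @export
hit_number_model <- function(lam, tail_tol = 1e-9) {
  stopifnot(lam >= 0, tail_tol > 0)
  n <- if (lam == 0) 0L else as.integer(qpois(tail_tol, lam,
                                              lower.tail = FALSE)) + 1L
  list(lam = lam, truncation = n)
}

# Internal: pmf vector on the uniform lattice z = (k-1) * dz + offset,
# obtained by conservative rebinning of a dose_distribution through its CDF.
# Lattice bin k covers ((k-1.5) dz, (k-0.5) dz] around center (k-1) dz, with
# k = 1 the zero bin. Returns list(pmf (length m, zero bin first), dz).
.dd_to_lattice <- function(d, dz, m) {
  edges_src <- d$bin_edges
  cdf_src <- c(0, cumsum(d$density * diff(edges_src)))
  cdf <- function(z) {
    z <- pmin(pmax(z, edges_src[1]), edges_src[length(edges_src)])
    approx(edges_src, cdf_src, xout = z, rule = 2)$y
  }
  k <- seq_len(m)
  hi <- (k - 0.5) * dz
  lo <- (k - 1.5) * dz
  p <- cdf(hi) - cdf(lo)
  p[1] <- p[1] + d$zero_mass + cdf(max(lo[1], edges_src[1]))
  p <- pmax(p, 0)
  p / sum(p)
}

# Internal: pack a lattice pmf (zero bin first, spacing dz) into a
# dose_distribution with zero_mass taken from `zero_mass` (the residual mass
# in bin 1 beyond zero_mass is kept as density).
.lattice_to_dd <- function(pmf, dz, zero_mass = NULL, mean = NULL) {
  m <- length(pmf)
  if (is.null(zero_mass)) {
    zero_mass <- pmf[1]
    pmf[1] <- 0
  } else {
    pmf[1] <- max(pmf[1] - zero_mass, 0)
  }
  edges <- ((0:m) - 0.5) * dz
  dens <- pmf / dz
  # renormalize tiny FFT round-off
  tot <- zero_mass + sum(pmf)
  dens <- dens / tot
  zero_mass <- zero_mass / tot
  dose_distribution(edges, dens, zero_mass = zero_mass, mean = mean)
}

#' i-fold self-convolution of a single-hit distribution
#'
#' Distribution of the summed specific energy of `i` independent hits,
#' computed by discrete convolution on a common uniform lattice
#' (transform-space exponentiation). The grid is extended automatically to
#' `i` times the input support. The mean is `i` times the input mean.
#'
#' @param f1 A [dose_distribution()] (normalized single-hit distribution).
#' @param i Number of hits, `>= 1`.
#' @return A `dose_distribution`.
#' @export
self_convolve <- function(f1, i) {
  stopifnot(inherits(f1, "dose_distribution"), i >= 1, i == floor(i))
  if (i == 1) return(f1)
  dz <- .dd_binwidth(f1)
  m1 <- length(f1$density) + 1L
  m <- nextn(i * m1 + 1L, 2)
  p <- .dd_to_lattice(f1, dz, m)
  ph <- fft(p)
  conv <- Re(fft(ph^i, inverse = TRUE)) / m
  conv <- pmax(conv, 0)
  .lattice_to_dd(conv, dz)
}

#' Analytical compound-Poisson nucleus dose distribution
#'
#' Builds the NDD at mean absorbed dose `zbar` from the single-hit
#' distribution: a zero-dose mass `exp(-lambda)` plus the Poisson-weighted
#' sum of i-fold self-convolutions of the SHNDD, with `lambda = zbar / q`
#' and the hit-number truncation chosen so the neglected tail is below
#' `tail_tol`. The summation is evaluated exactly in transform space
#' (`exp(lambda * (F - 1))`, the compound-Poisson characteristic function).
#' The result conserves normalization and has mean `zbar` on the lattice.
#'
#' @param f1 A [dose_distribution()]: the SHNDD (zero mass 0).
#' @param zbar Mean absorbed dose in Gy, `>= 0`.
#' @param tail_tol Neglected Poisson-tail bound (used to size the grid).
#' @param bins Number of bins of the output grid (default 500).
#' @param z_max Upper edge of the output grid; defaults to
#'   `zbar + 8 * sqrt(lambda) * q + max(z1)`, extended automatically.
#' @return A `dose_distribution` with `zero_mass = exp(-lambda)`.
#' @export
analytic_ndd <- function(f1, zbar, tail_tol = 1e-9, bins = 500,
                         z_max = NULL) {
  stopifnot(inherits(f1, "dose_distribution"), zbar >= 0)
  q <- f1$mean
  if (q <= 0) stop("SHNDD mean q must be positive")
  if (zbar == 0) {
    dz <- .dd_binwidth(f1)
    return(.lattice_to_dd(c(1, numeric(15)), dz, zero_mass = 1, mean = 0))
  }
  lam0 <- zbar / q
  z1max <- max(f1$bin_edges)
  if (is.null(z_max)) z_max <- zbar + 8 * sqrt(lam0) * q + z1max
  # The lattice must resolve the single-hit distribution itself, not just
  # the compound grid (spacing at most a fraction of q), and must be
  # commensurate with f1's bin grid so that lattice-aligned distributions
  # (e.g. point masses) convolve without smearing.
  bw <- .dd_binwidth(f1)
  dz_target <- min(z_max / bins, q / 8, bw)
  dz <- bw / ceiling(bw / dz_target)
  n_lat <- ceiling(z_max / dz)
  m <- nextn(2L * as.integer(n_lat) + 2L, 2)
  if (m > 2^22) {
    m <- 2^22
    dz <- 2 * z_max / m
  }
  p1 <- .dd_to_lattice(f1, dz, m)
  # recompute q and lambda on the lattice so the compound mean is exact
  q_lat <- sum(p1 * ((seq_len(m) - 1) * dz))
  lam <- zbar / q_lat
  ph <- fft(p1)
  cf <- exp(lam * (ph - 1))
  pmf <- Re(fft(cf, inverse = TRUE)) / m
  pmf <- pmax(pmf, 0)
  out <- .lattice_to_dd(pmf, dz, zero_mass = exp(-lam), mean = zbar)
  attr(out, "lam") <- lam
  attr(out, "truncation") <- hit_number_model(lam, tail_tol)$truncation
  out
}

# Per-placement single-hit samples: returns list of per-placement numeric
# vectors of nucleus specific energies z (Gy) for tracks that hit, plus the
# nucleus mass. Placements are random lateral offsets of the cell over the
# field (uniform; cell kept fully inside).
# Placements are periodic: the offset is uniform over the field and track
# entry points are wrapped modulo the field side, centered on the cell, so
# that every track's position relative to the cell is exactly uniform. This
# continues the measured field periodically beyond its edges -- the same
# infinite-uniform-field assumption under which total_dose() scores the
# reference-layer dose -- and avoids edge bias for cells near the border.
.shndd_samples <- function(field, vol, placements = 64, seed = NULL,
                           mylar_thickness = 1.4,
                           mylar = material_model("mylar")) {
  stopifnot(inherits(field, "track_field"), inherits(vol, "label_volume"))
  if (field$n_total == 0) stop("track field is empty")
  if (!is.null(seed)) set.seed(seed)
  tr <- field$tracks
  n <- nrow(tr)
  dzc <- pmax(abs(tr$dz), 1e-12)
  tau1 <- mylar_thickness / dzc
  e1 <- residual_energy(tr$energy_kev, tau1, mylar)
  # stopping ray parameter: mylar segment plus the residual water range
  # (the medium between foil and nucleus is water-equivalent throughout)
  smax <- tau1 + csda_range(e1)
  m_nuc_kg <- nucleus_volume(vol) * 1e-18 * .RHO_WATER
  if (m_nuc_kg <= 0) stop("nucleus is empty")
  ext <- dim(vol$labels) * vol$voxel_size * 1e-3  # um
  side <- sqrt(field$area)
  # lateral drift of a track across the cell depth, capped by its range
  z_top <- vol$origin[3] + dim(vol$labels)[3] * vol$voxel_size[3] * 1e-3
  drift <- max(pmin(z_top * sqrt(tr$dx^2 + tr$dy^2) / dzc, smax))
  if (any(ext[1:2] + 2 * drift > side + 1e-9))
    warning("field side is small against the cell plus track drift; ",
            "periodic placements may alias")
  v <- vol
  v$origin[1:2] <- 0
  ctr <- ext[1:2] / 2
  dirs <- cbind(tr$dx, tr$dy, tr$dz)
  off_x <- runif(placements, 0, side)
  off_y <- runif(placements, 0, side)
  z_list <- vector("list", placements)
  for (p in seq_len(placements)) {
    # wrap entries onto (ctr - side/2, ctr + side/2], cell at [0, ext]
    ux <- (tr$x_um - off_x[p] - ctr[1] + side / 2) %% side -
      side / 2 + ctr[1]
    uy <- (tr$y_um - off_y[p] - ctr[2] + side / 2) %% side -
      side / 2 + ctr[2]
    taus <- .trace_rays_raw(cbind(ux, uy, tr$z_um), dirs, v, smax)
    hit <- taus[, 3] > 0
    if (!any(hit)) { z_list[[p]] <- numeric(0); next }
    upstream <- pmax(taus[hit, 1] - tau1[hit], 0)
    e_entry <- residual_energy(e1[hit], upstream)
    edep <- energy_deposited(e_entry, taus[hit, 3])
    z <- edep * .KEV_TO_J / m_nuc_kg
    z_list[[p]] <- z[z > 0]
  }
  list(z = z_list, mass_kg = m_nuc_kg, n_tracks = n)
}

#' Single-hit nucleus dose distribution from a track field and cell
#'
#' For each of `placements` random lateral placements of the cell in the
#' field and each track, computes the per-medium path lengths, the energy
#' entering the nucleus (after the mylar loss and continuous slowing along
#' the upstream path, which is water-equivalent throughout: cytoplasm,
#' nucleus and surrounding medium all have the stopping power of water), the
#' energy deposited over the nucleus chord, and the specific energy
#' `z = E_dep / (nucleus volume x 1000 kg/m^3)`. The distribution is the
#' histogram over hits only (z > 0): zero mass is 0 because the SHNDD
#' conditions on a hit. The recorded mean is the single-particle mean dose q.
#'
#' @param field A [track_field()].
#' @param vol A [label_volume()].
#' @param placements Number of random lateral placements (default 64).
#'   Placements are periodic: the field is continued beyond its edges by
#'   wrapping track entry points modulo the field side, so every relative
#'   cell-field offset is exactly uniform.
#' @param bins Number of histogram bins (default 200).
#' @param seed Integer seed for the placement draw.
#' @param mylar_thickness Foil thickness in um.
#' @return A `dose_distribution` with attributes `q` (mean, Gy), `hit_prob`
#'   (per-track hit probability) and `n_hits`.
#' @export
compute_shndd <- function(field, vol, placements = 64, bins = 200,
                          seed = NULL, mylar_thickness = 1.4) {
  s <- .shndd_samples(field, vol, placements, seed, mylar_thickness)
  z <- unlist(s$z)
  if (length(z) == 0)
    stop("no track ever hit the nucleus; enlarge placements or the field")
  out <- .hist_dd(z, bins)
  attr(out, "q") <- attr(out, "sample_mean")
  attr(out, "hit_prob") <- length(z) / (placements * s$n_tracks)
  attr(out, "n_hits") <- length(z)
  out
}

# histogram of positive samples as a dose_distribution (zero_mass = 0);
# the object mean is the binned moment, the exact sample mean is kept as
# attribute `sample_mean`
.hist_dd <- function(z, bins, z_max = NULL) {
  if (is.null(z_max)) z_max <- max(z) * (1 + 1e-9)
  dz <- z_max / bins
  idx <- pmin(floor(z / dz), bins - 1) + 1
  cnt <- tabulate(idx, nbins = bins)
  dens <- cnt / (length(z) * dz)
  out <- dose_distribution(seq(0, z_max, length.out = bins + 1), dens,
                           zero_mass = 0)
  attr(out, "sample_mean") <- sum(z) / length(z)
  out
}

#' Mean energy deposited per nucleus hit over a collection of cells
#'
#' Average deposited energy (keV) over all (placement, track) hits and all
#' cells; the per-cell single-particle mean dose q times the nucleus mass
#' recovers the same quantity cell by cell.
#'
#' @param field A [track_field()].
#' @param volumes A list of [label_volume()] (a single volume is accepted).
#' @param placements,seed,mylar_thickness As in [compute_shndd()].
#' @return Mean energy per hit in keV.
#' @export
mean_energy_per_hit <- function(field, volumes, placements = 64,
                                seed = NULL, mylar_thickness = 1.4) {
  if (inherits(volumes, "label_volume")) volumes <- list(volumes)
  tot_e <- 0; tot_n <- 0
  seeds <- if (is.null(seed)) rep(list(NULL), length(volumes)) else
    as.list(seed + seq_along(volumes))
  for (k in seq_along(volumes)) {
    s <- .shndd_samples(field, volumes[[k]], placements, seeds[[k]],
                        mylar_thickness)
    z <- unlist(s$z)
    tot_e <- tot_e + sum(z) * s$mass_kg / .KEV_TO_J
    tot_n <- tot_n + length(z)
  }
  if (tot_n == 0) stop("no hits over the collection")
  tot_e / tot_n
}

#' Monte Carlo nucleus dose distribution by track resampling
#'
#' Emulates the track-detector NDD estimate: per repetition, draw
#' `N = round(zbar / D_total * N_total)` tracks uniformly with replacement
#' from the measured field, place the cell at a random lateral offset, and
#' sum the nucleus specific energy over the tracks that hit. The histogram
#' over repetitions, with an explicit zero mass for repetitions without any
#' hit, estimates the NDD at mean absorbed dose `zbar`.
#'
#' @param field A [track_field()]; `D_total` is computed via [total_dose()]
#'   with the given layer thickness when not already set.
#' @param vol A [label_volume()].
#' @param zbar Target mean absorbed dose in Gy.
#' @param reps Number of repetitions (default 10000).
#' @param seed Integer seed.
#' @param placements Size of the pre-traced placement pool the repetitions
#'   draw from (default 200).
#' @param bins,z_max Output grid; defaults match [analytic_ndd()].
#' @param n_mode `"round"` (deterministic N per repetition, default) or
#'   `"poisson"` (N resampled as Poisson with that mean).
#' @param layer_thickness,mylar_thickness Passed to [total_dose()] and the
#'   path tracing.
#' @return A `dose_distribution` with attribute `n_per_rep`.
#' @export
mc_ndd <- function(field, vol, zbar, reps = 10000, seed = NULL,
                   placements = 200, bins = 500, z_max = NULL,
                   n_mode = c("round", "poisson"), layer_thickness = 8,
                   mylar_thickness = 1.4) {
  n_mode <- match.arg(n_mode)
  stopifnot(reps >= 1, zbar >= 0)
  field <- .with_total_dose(field, layer_thickness, mylar_thickness)
  if (!is.null(seed)) set.seed(seed)
  s <- .shndd_samples(field, vol, placements, seed = NULL,
                      mylar_thickness = mylar_thickness)
  n_draw <- round(zbar / field$d_total * field$n_total)
  if (n_draw < 1)
    warning("zbar corresponds to fewer than one drawn track; N = ", n_draw)
  q_hat <- mean(unlist(s$z))
  if (is.null(z_max)) {
    lam0 <- if (q_hat > 0) zbar / q_hat else 0
    z_max <- zbar + 8 * sqrt(max(lam0, 1)) * q_hat +
      max(unlist(s$z), 0)
  }
  n_tracks <- s$n_tracks
  pl <- sample.int(length(s$z), reps, replace = TRUE)
  n_per <- if (n_mode == "round") rep(n_draw, reps) else
    stats::rpois(reps, zbar / field$d_total * field$n_total)
  totals <- numeric(reps)
  # hit counts are binomial per placement; sample hit doses directly
  hit_n <- vapply(s$z, length, integer(1))
  for (r in seq_len(reps)) {
    zp <- s$z[[pl[r]]]
    k <- stats::rbinom(1, n_per[r], hit_n[pl[r]] / n_tracks)
    if (k > 0) totals[r] <- sum(zp[sample.int(length(zp), k, replace = TRUE)])
  }
  zero_mass <- mean(totals == 0)
  dz <- z_max / bins
  pos <- totals[totals > 0]
  cnt <- tabulate(pmin(floor(pos / dz), bins - 1) + 1, nbins = bins)
  dens <- cnt / (reps * dz)
  out <- dose_distribution(seq(0, z_max, length.out = bins + 1), dens,
                           zero_mass = zero_mass)
  attr(out, "sample_mean") <- mean(totals)
  attr(out, "n_per_rep") <- n_draw
  attr(out, "q") <- q_hat
  out
}

#' Root-mean-square difference between two dose distributions
#'
#' RMS difference of the densities over the bins of `a` (distribution `b` is
#' rebinned onto `a`'s grid through its CDF); the zero masses are compared
#' separately and reported as an attribute. Symmetric in its arguments up to
#' the choice of grid; zero for identical distributions.
#'
#' @param a,b [dose_distribution()] objects.
#' @return RMSE in per-Gy density units, with attribute `zero_mass_diff`.
#' @export
distribution_rmse <- function(a, b) {
  stopifnot(inherits(a, "dose_distribution"),
            inherits(b, "dose_distribution"))
  db <- .rebin_density(b, a$bin_edges)
  r <- sqrt(mean((a$density - db)^2))
  attr(r, "zero_mass_diff") <- a$zero_mass - b$zero_mass
  r
}

# density of d rebinned onto the given uniform edges (mass-conserving)
.rebin_density <- function(d, edges) {
  src_edges <- d$bin_edges
  cdf_src <- c(0, cumsum(d$density * diff(src_edges)))
  cdf <- approx(src_edges, cdf_src, xout = pmin(pmax(edges, src_edges[1]),
                                                src_edges[length(src_edges)]),
                rule = 2)$y
  diff(cdf) / diff(edges)
}

#' Kolmogorov distance between two dose distributions
#'
#' Maximum absolute difference of the cumulative distribution functions
#' (including the zero-dose mass), evaluated on the union of both bin grids.
#'
#' @param a,b [dose_distribution()] objects.
#' @return Kolmogorov distance in `[0, 1]`.
#' @export
ks_distance <- function(a, b) {
  pts <- sort(unique(c(a$bin_edges, b$bin_edges)))
  Fa <- .dd_cdf(a)(pts)
  Fb <- .dd_cdf(b)(pts)
  max(abs(Fa - Fb))
}

.dd_cdf <- function(d) {
  edges <- d$bin_edges
  cdf <- c(0, cumsum(d$density * diff(edges)))
  function(z) {
    out <- approx(edges, cdf, xout = z, rule = 2)$y
    out[z < edges[1]] <- 0
    # the zero-dose atom sits at exactly z = 0
    pmin(out + d$zero_mass * (z >= 0), 1)
  }
}

#' Serialize / read a dose distribution as TSV
#'
#' Two columns (`bin_center_gy`, `density_per_gy`) with `# zero_mass=` and
#' `# mean_gy=` metadata header lines.
#'
#' @param d A [dose_distribution()].
#' @param path File path.
#' @return `read_distribution()` returns a `dose_distribution`.
#' @export
write_distribution <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# zero_mass=%.17g", d$zero_mass),
               sprintf("# mean_gy=%.17g", d$mean),
               sprintf("# bin_width_gy=%.17g", .dd_binwidth(d)),
               "bin_center_gy\tdensity_per_gy"), con)
  utils::write.table(
    data.frame(bin_center_gy = sprintf("%.10g", .dd_mids(d)),
               density_per_gy = sprintf("%.10g", d$density)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  lines <- readLines(path)
  getmeta <- function(key) {
    m <- grep(paste0("^#\\s*", key, "="), lines, value = TRUE)
    as.numeric(sub(paste0("^#\\s*", key, "="), "", m[1]))
  }
  zero_mass <- getmeta("zero_mass")
  mean_gy <- getmeta("mean_gy")
  bw <- getmeta("bin_width_gy")
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          colClasses = "numeric")
  # rebuild an exactly uniform grid from the first center and the bin width
  edges <- df$bin_center_gy[1] - bw / 2 + (0:nrow(df)) * bw
  dose_distribution(edges, df$density_per_gy, zero_mass = zero_mass,
                    mean = mean_gy)
}
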