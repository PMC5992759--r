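## Track data model and field-level operations. A track field is the list of
## individual alpha-particle tracks measured (or synthesized) at the top of
## the mylar dish foil: entry point (um), unit direction (+z into the cell
## layer), kinetic energy at entry (keV), and optionally the measured track
## end point. Field-level quantities are the track count N_total and the
## absorbed dose D_total delivered to a reference water layer.

.TRACK_COLS <- c("x_um", "y_um", "z_um", "dx", "dy", "dz", "energy_kev")
.END_COLS <- c("end_x_um", "end_y_um", "end_z_um")

#' Construct a track field
#'
#' @param tracks Data frame with columns `x_um, y_um, z_um` (entry point at
#'   the top of the mylar plane, um), `dx, dy, dz` (unit direction, positive
#'   `dz` pointing into the cell layer) and `energy_kev` (kinetic energy at
#'   entry, keV). Optional columns `end_x_um, end_y_um, end_z_um` give the
#'   measured track end point.
#' @param area Lateral field area in um^2.
#' @return An object of class `track_field` with elements `tracks`, `area`,
#'   `n_total` and `d_total` (`NA` until computed by [total_dose()]).
#' @export
#' @examples
#' tf <- track_field(data.frame(x_um = 0, y_um = 0, z_um = 0,
#'                              dx = 0, dy = 0, dz = 1, energy_kev = 5486),
#'                   area = 100)
#' tf$n_total
track_field <- function(tracks, area) {
  stopifnot(is.data.frame(tracks))
  missing_cols <- setdiff(.TRACK_COLS, names(tracks))
  if (length(missing_cols) > 0)
    stop("tracks is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  if (!is.numeric(area) || length(area) != 1 || area <= 0)
    stop("area must be a positive scalar (um^2)")
  if (nrow(tracks) > 0) {
    nrm <- sqrt(tracks$dx^2 + tracks$dy^2 + tracks$dz^2)
    bad <- abs(nrm - 1) >= 1e-6
    if (any(bad))
      stop("non-unit direction vector(s) at row(s): ",
           paste(utils::head(which(bad), 5), collapse = ", "))
    # renormalize away round-off
    tracks$dx <- tracks$dx / nrm
    tracks$dy <- tracks$dy / nrm
    tracks$dz <- tracks$dz / nrm
    if (any(tracks$energy_kev <= 0)) stop("track energies must be positive")
  }
  structure(list(tracks = tracks, area = area, n_total = nrow(tracks),
                 d_total = NA_real_),
            class = "track_field")
}

#' @export
print.track_field <- function(x, ...) {
  cat(sprintf("<track_field> %d tracks over %g um^2", x$n_total, x$area))
  if (!is.na(x$d_total)) cat(sprintf("; D_total = %.4g Gy", x$d_total))
  cat("\n")
  if (x$n_total > 0)
    cat(sprintf("  energy: %.0f-%.0f keV, median polar angle %.1f deg\n",
                min(x$tracks$energy_kev), max(x$tracks$energy_kev),
                stats::median(acos(pmin(x$tracks$dz, 1)) * 180 / pi)))
  invisible(x)
}

#' Read / write track fields as TSV
#'
#' The track TSV dialect has a header row naming the columns
#' `x_um y_um z_um dx dy dz energy_kev` (optionally followed by
#' `end_x_um end_y_um end_z_um`) and `#`-prefixed metadata lines; the field
#' area is carried in a `# area_um2=` metadata line. Writing then reading a
#' field is an identity up to float round-trip.
#'
#' @param path File path.
#' @param area Field area in um^2; overrides the file's `# area_um2=`
#'   metadata line if given.
#' @return `read_tracks()` returns a [track_field()]; `write_tracks()`
#'   returns `path` invisibly.
#' @export
read_tracks <- function(path, area = NULL) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  if (is.null(area)) {
    m <- grep("^#\\s*area_um2=", meta, value = TRUE)
    if (length(m) == 1) area <- as.numeric(sub("^#\\s*area_um2=", "", m))
    else stop("no '# area_um2=' metadata line in ", path,
              "; pass area explicitly")
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) stop("no header row in ", path)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(.TRACK_COLS, header)
  if (length(missing_cols) > 0)
    stop("track file ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (length(body) == 1) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(header)),
                                 header))
    return(track_field(df, area))
  }
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          colClasses = "numeric")
  bad <- which(!stats::complete.cases(df))
  if (length(bad) > 0)
    stop("non-numeric or incomplete track row(s) at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  track_field(df, area)
}

#' @rdname read_tracks
#' @param field A [track_field()].
#' @export
write_tracks <- function(field, path) {
  stopifnot(inherits(field, "track_field"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# area_um2=%.17g", field$area),
               sprintf("# n_total=%d", field$n_total)), con)
  utils::write.table(format(field$tracks, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove tracks ending in the outer rim of the imaged stack
#'
#' Tracks whose measured end point lies within `rim` of any face of the
#' imaged stack are removed: such tracks likely came to rest outside the
#' field of view and their reconstruction is unreliable. Requires tracks to
#' carry end points. Never increases the track count and is idempotent.
#'
#' @param field A [track_field()] whose tracks have end-point columns.
#' @param stack_bounds Numeric length-6 vector
#'   `c(xmin, xmax, ymin, ymax, zmin, zmax)` in um.
#' @param rim Rim width in um (default 1); `rim = 0` leaves the field
#'   unchanged.
#' @return The filtered [track_field()].
#' @export
filter_edge_tracks <- function(field, stack_bounds, rim = 1.0) {
  stopifnot(inherits(field, "track_field"), length(stack_bounds) == 6)
  if (rim < 0) stop("rim must be >= 0")
  if (rim == 0 || field$n_total == 0) return(field)
  tr <- field$tracks
  if (!all(.END_COLS %in% names(tr)))
    stop("tracks carry no end points (columns ",
         paste(.END_COLS, collapse = ", "),
         "); skip the rim filter for this field")
  b <- stack_bounds
  keep <- tr$end_x_um >= b[1] + rim & tr$end_x_um <= b[2] - rim &
          tr$end_y_um >= b[3] + rim & tr$end_y_um <= b[4] - rim &
          tr$end_z_um >= b[5] + rim & tr$end_z_um <= b[6] - rim
  track_field(tr[keep, , drop = FALSE], field$area)
}

#' Absorbed dose delivered by a track field to a reference water layer
#'
#' Sums, over all tracks, the energy deposited in a water layer of the given
#' thickness (the average height of the measured cells) sitting on top of the
#' mylar foil, after correcting each track's energy for the mylar traversal,
#' and divides by the layer mass `area x thickness x 1000 kg/m^3`. The
#' in-layer chord is `thickness / |dz|`, truncated at the particle's
#' residual range. Linear in the track list and invariant under permutation.
#'
#' @param field A [track_field()].
#' @param layer_thickness Water layer thickness in um (default 8).
#' @param mylar_thickness Mylar foil thickness in um (default 1.4).
#' @param mylar Material model for the foil (default [material_model]`("mylar")`).
#' @return Absorbed dose in Gy.
#' @export
total_dose <- function(field, layer_thickness = 8, mylar_thickness = 1.4,
                       mylar = material_model("mylar")) {
  stopifnot(inherits(field, "track_field"))
  if (field$n_total == 0) return(0)
  tr <- field$tracks
  dz <- pmax(abs(tr$dz), 1e-12)        # guard: grazing tracks
  tau1 <- mylar_thickness / dz
  e1 <- residual_energy(tr$energy_kev, tau1, mylar)
  chord <- layer_thickness / dz
  edep_kev <- energy_deposited(e1, chord)   # truncation at stop is implicit
  mass_kg <- field$area * layer_thickness * 1e-18 * .RHO_WATER  # um^3 -> m^3
  sum(edep_kev) * .KEV_TO_J / mass_kg
}

# returns `field` with d_total filled in (computed lazily where needed)
.with_total_dose <- function(field, layer_thickness = 8,
                             mylar_thickness = 1.4) {
  if (is.na(field$d_total))
    field$d_total <- total_dose(field, layer_thickness, mylar_thickness)
  field
}

#' Generate a synthetic collimated track field
#'
#' Emulates a vertically collimated external alpha source: entry points
#' uniform over a square field, azimuth uniform, polar angle restricted to
#' `<= max_polar` degrees (honeycomb collimation), and entry energies drawn
#' from a configurable law standing in for the unmeasured post-air spectrum.
#' Within the cone the default sampling is uniform in solid angle
#' (`cos(theta)` uniform on `[cos(max_polar), 1]`); `angular = "fluence"`
#' weights by the additional `cos(theta)` of plane crossing. Track end points
#' are set at the water CSDA range along the direction so that rim filtering
#' can be exercised on synthetic data.
#'
#' @param n Number of tracks.
#' @param area Field area in um^2 (a square of side `sqrt(area)`).
#' @param max_polar Maximum polar angle in degrees (default 45).
#' @param energy_law List describing the entry-energy distribution:
#'   `list(type = "normal", mean = 4500, sd = 200)` (truncated at 0 and at
#'   the stopping-table maximum) or `list(type = "fixed", value = E)`.
#' @param angular `"solid_angle"` (default) or `"fluence"`.
#' @param seed Integer seed; identical seeds give identical fields.
#' @return A [track_field()] with end-point columns.
#' @export
#' @examples
#' tf <- generate_collimated_field(100, area = 100 * 100, seed = 1)
#' max(acos(tf$tracks$dz)) * 180 / pi   # <= 45
generate_collimated_field <- function(n, area, max_polar = 45,
                                      energy_law = list(type = "normal",
                                                        mean = 4500,
                                                        sd = 200),
                                      angular = c("solid_angle", "fluence"),
                                      seed = NULL) {
  stopifnot(n > 0, area > 0)
  angular <- match.arg(angular)
  if (!is.null(seed)) set.seed(seed)
  side <- sqrt(area)
  x <- runif(n, 0, side)
  y <- runif(n, 0, side)
  cmin <- cos(max_polar * pi / 180)
  u <- runif(n)
  cth <- switch(angular,
    solid_angle = cmin + u * (1 - cmin),
    fluence = sqrt(cmin^2 + u * (1 - cmin^2)))
  sth <- sqrt(pmax(0, 1 - cth^2))
  phi <- runif(n, 0, 2 * pi)
  e <- .sample_energy_law(n, energy_law)
  r <- csda_range(e)
  tr <- data.frame(x_um = x, y_um = y, z_um = 0,
                   dx = sth * cos(phi), dy = sth * sin(phi), dz = cth,
                   energy_kev = e)
  tr$end_x_um <- tr$x_um + tr$dx * r
  tr$end_y_um <- tr$y_um + tr$dy * r
  tr$end_z_um <- tr$z_um + tr$dz * r
  track_field(tr, area)
}

.sample_energy_law <- function(n, law) {
  if (!is.list(law) || is.null(law$type))
    stop("energy_law must be a list with a 'type' element")
  e_max <- .physics_interp()$e_max
  switch(law$type,
    normal = {
      if (is.null(law$mean) || is.null(law$sd))
        stop("energy_law 'normal' requires 'mean' and 'sd'")
      e <- rnorm(n, law$mean, law$sd)
      while (any(bad <- (e <= .E_CUTOFF_KEV | e > e_max)))
        e[bad] <- rnorm(sum(bad), law$mean, law$sd)
      e
    },
    fixed = {
      if (is.null(law$value)) stop("energy_law 'fixed' requires 'value'")
      rep(law$value, n)
    },
    stop("unknown energy_law type: ", law$type))
}
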