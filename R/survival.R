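## Survival functionals over nucleus dose distributions and the calibration
## of the microdosimetric survival slope alpha_z against the experimentally
## measured slope alpha_D. Survival is purely exponential in this model
## (quadratic LQ term deliberately omitted): S_D(D) = exp(-alpha_D * D) and
## S_z(zbar) = integral f(z, zbar) exp(-alpha_z z) dz. Because the
## exponential is convex, averaging over the NDD always predicts *higher*
## survival than the mean dose alone, hence alpha_z >= alpha_D (Jensen).

#' Expected survival from a nucleus dose distribution
#'
#' `S = zero_mass + integral f(z) exp(-alpha_z z) dz` over the binned NDD;
#' lies in (0, 1] and decreases in both `alpha_z` and the mean dose.
#'
#' @param ndd A [dose_distribution()].
#' @param alpha_z Microdosimetric survival slope in 1/Gy, `>= 0`.
#' @return Surviving fraction.
#' @export
#' @examples
#' f1 <- dd_point_mass(0.1, 0.01, 100)
#' survival_from_ndd(analytic_ndd(f1, 0.3), alpha_z = 1.92)
survival_from_ndd <- function(ndd, alpha_z) {
  stopifnot(inherits(ndd, "dose_distribution"))
  if (alpha_z < 0) stop("alpha_z must be >= 0")
  dz <- diff(ndd$bin_edges)
  mids <- .dd_mids(ndd)
  ndd$zero_mass + sum(ndd$density * dz * exp(-alpha_z * mids))
}

#' A collection of cells with their single-hit distributions
#'
#' @param shndds List of [dose_distribution()] objects, one SHNDD per cell.
#' @return Object of class `cell_collection` with per-cell mean doses `q`.
#' @export
cell_collection <- function(shndds) {
  if (inherits(shndds, "dose_distribution")) shndds <- list(shndds)
  stopifnot(length(shndds) >= 1,
            all(vapply(shndds, inherits, logical(1), "dose_distribution")))
  q <- vapply(shndds, function(d) d$mean, numeric(1))
  if (any(q <= 0)) stop("every SHNDD must have positive mean")
  structure(list(shndds = shndds, q = q, m = length(shndds)),
            class = "cell_collection")
}

#' @export
print.cell_collection <- function(x, ...) {
  cat(sprintf("<cell_collection> %d cells; q = %.4g-%.4g Gy\n",
              x$m, min(x$q), max(x$q)))
  invisible(x)
}

#' Collection-averaged microdosimetric survival
#'
#' `(1/M) * sum_l S_{z,l}(zbar)` where each cell's NDD is built from its own
#' SHNDD at absorbed dose `zbar` via [analytic_ndd()].
#'
#' @param collection A [cell_collection()].
#' @param zbar Mean absorbed dose in Gy.
#' @param alpha_z Survival slope in 1/Gy.
#' @param bins NDD grid size passed to [analytic_ndd()].
#' @return Surviving fraction.
#' @export
collection_survival <- function(collection, zbar, alpha_z, bins = 500) {
  stopifnot(inherits(collection, "cell_collection"))
  s <- vapply(collection$shndds, function(f1)
    survival_from_ndd(analytic_ndd(f1, zbar, bins = bins), alpha_z),
    numeric(1))
  mean(s)
}

#' Fit the experimental survival slope alpha_D
#'
#' Least-squares fit of `ln S = -alpha_D * D` through the origin on measured
#' (dose, surviving fraction) points; the uncertainty is the standard error
#' of the regression coefficient.
#'
#' @param doses Absorbed doses in Gy (positive, finite).
#' @param survival_fractions Surviving fractions in (0, 1].
#' @return List with `alpha_d` (1/Gy) and `sigma`.
#' @export
#' @examples
#' fit_alpha_d(c(0.5, 1, 2), exp(-2 * c(0.5, 1, 2)))  # alpha_d = 2
fit_alpha_d <- function(doses, survival_fractions) {
  if (any(survival_fractions <= 0))
    stop("survival fractions must be positive")
  if (any(!is.finite(doses)) || any(doses <= 0))
    stop("doses must be positive and finite")
  y <- -log(survival_fractions)
  fit <- lm(y ~ 0 + doses)
  # through-origin LS coefficient SE (avoids vcov's perfect-fit warning)
  sigma <- if (length(doses) >= 2) {
    rss <- sum(fit$residuals^2)
    sqrt(rss / (length(doses) - 1) / sum(doses^2))
  } else NA_real_
  list(alpha_d = unname(coef(fit)[1]), sigma = sigma)
}

# ln of collection survival, floored against underflow
.ln_surv <- function(collection, zbar, alpha_z, bins) {
  log(max(collection_survival(collection, zbar, alpha_z, bins), 1e-300))
}

#' Calibrate the microdosimetric survival slope alpha_z
#'
#' Finds `alpha_z` such that the microdosimetric survival prediction matches
#' the experimental exponential `exp(-alpha_D * D)` at the experimental dose
#' points: minimizes `sum_j (alpha_D * D_j + ln S_z^C(D_j))^2` by bounded
#' scalar optimization on `alpha_z` in `[alpha_d, upper * alpha_d]`.
#' Because the NDD is wider than a point mass, `alpha_z >= alpha_D` always
#' (Jensen), with equality in the small-q limit. The uncertainty follows
#' from `sigma_alpha_z = |d alpha_z / d alpha_D| * sigma_alpha_d` with a
#' central-difference derivative.
#'
#' @param doses Experimental absorbed-dose points `D_j` in Gy.
#' @param collection A [cell_collection()] of SHNDDs.
#' @param alpha_d Experimental slope in 1/Gy (consumed as a constant).
#' @param sigma_alpha_d Its 1-sigma uncertainty (default 0: no propagation).
#' @param upper Upper search bound as a multiple of `alpha_d` (default 20).
#' @param bins NDD grid size.
#' @param tol Optimizer tolerance on alpha_z (default 1e-8).
#' @return List with `alpha_z`, `sigma`, `residual` (objective at optimum)
#'   and `alpha_d`.
#' @export
fit_alpha_z <- function(doses, collection, alpha_d, sigma_alpha_d = 0,
                        upper = 20, bins = 500, tol = 1e-8) {
  stopifnot(inherits(collection, "cell_collection"), alpha_d > 0,
            length(doses) >= 1, all(doses > 0))
  solve_az <- function(ad) {
    obj <- function(az) {
      sum(vapply(doses, function(D)
        (ad * D + .ln_surv(collection, D, az, bins))^2, numeric(1)))
    }
    opt <- optimize(obj, interval = c(ad, upper * ad), tol = tol)
    if (opt$objective > sum((0.05 * ad * doses)^2))
      stop(sprintf(paste0("alpha_z fit did not converge: residual %.3g on ",
                          "bracket [%g, %g]"),
                   opt$objective, ad, upper * ad))
    opt
  }
  opt <- solve_az(alpha_d)
  sigma <- 0
  if (sigma_alpha_d > 0) {
    h <- 0.01 * alpha_d
    dadz <- (solve_az(alpha_d + h)$minimum -
             solve_az(alpha_d - h)$minimum) / (2 * h)
    sigma <- abs(dadz) * sigma_alpha_d
  }
  list(alpha_z = opt$minimum, sigma = sigma, residual = opt$objective,
       alpha_d = alpha_d)
}
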