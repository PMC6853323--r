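#' Quadratic-pyramid tip model
#'
#' Geometry of the indenter and sample elasticity assumptions for the
#' Hertzian contact analysis of AFM force curves.
#'
#' @param half_angle_deg half-front angle of the four-sided pyramid in
#'   degrees (default 15).
#' @param poisson Poisson ratio of the sample (default 0.5,
#'   incompressible).
#' @export
tip_model <- function(half_angle_deg = 15, poisson = 0.5) {
  m3d_assert(half_angle_deg > 0 && half_angle_deg < 90,
             "migr3d_validation_error", "half angle must be in (0, 90)")
  m3d_assert(poisson >= 0 && poisson <= 0.5, "migr3d_validation_error",
             "Poisson ratio must be in [0, 0.5]")
  structure(list(half_angle_deg = half_angle_deg, poisson = poisson),
            class = "tip_model")
}

#' Hertz coefficient for a four-sided pyramidal indenter
#'
#' The Bilodeau closed form for a quadratic (four-sided) pyramid:
#' `F = 0.7453 * tan(theta) / (1 - nu^2) * E * delta^2`, with `theta`
#' the half-front angle and `delta` the indentation depth.  This
#' function returns the dimensionless prefactor
#' `C = 0.7453 * tan(theta) / (1 - nu^2)` so that `F[N] = C * E[Pa] *
#' delta[m]^2` (equivalently `F[nN] = 1e-3 * C * E[Pa] * delta[um]^2`).
#'
#' @param half_angle_deg pyramid half-front angle in degrees.
#' @param poisson sample Poisson ratio.
#' @export
hertz_pyramid_coefficient <- function(half_angle_deg = 15, poisson = 0.5) {
  0.7453 * tan(half_angle_deg * pi / 180) / (1 - poisson^2)
}

#' Detect the tip-sample contact point of an approach curve
#'
#' The baseline force level and noise are estimated from the first
#' `baseline_fraction` of approach samples; the contact point is the
#' distance at which the force first exceeds
#' `baseline mean + kappa * baseline sd` for at least `min_run`
#' consecutive samples.  For soft samples this crossing is
#' systematically late (the force must rise above the noise), so the
#' Hertz fit refines the contact point afterwards.
#'
#' @param curve data.frame with `distance_um` (increasing along the
#'   approach) and `force_nN`.
#' @param kappa noise multiple for the crossing threshold (default 3).
#' @param baseline_fraction fraction of leading samples treated as
#'   baseline (default 0.4).
#' @param min_run required consecutive above-threshold samples
#'   (default 5).
#' @return contact distance in micrometres.
#' @export
detect_contact_point <- function(curve, kappa = 3, baseline_fraction = 0.4,
                                 min_run = 5L) {
  z <- curve$distance_um
  f <- curve$force_nN
  nb <- max(2L, floor(baseline_fraction * length(f)))
  base_mean <- mean(f[seq_len(nb)])
  base_sd <- sd(f[seq_len(nb)])
  thr <- base_mean + kappa * base_sd
  above <- f > thr
  run <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= min_run || (run > 0L && i == length(above))) {
      return(z[i - run + 1L])
    }
  }
  m3d_stop("migr3d_no_contact", "no contact point found (flat curve)")
}

#' Fit the quadratic-pyramid Hertz model to one force curve
#'
#' Least-squares fit of `F = C * E * delta^2` over the contact region,
#' with indentation `delta = (z - z_contact) - F / k` (piezo travel past
#' contact corrected by the cantilever deflection, `k` the spring
#' constant) and `C` the four-sided-pyramid coefficient from
#' [hertz_pyramid_coefficient()].  The contact point is initialized by
#' [detect_contact_point()] and refined by minimizing the full-curve
#' piecewise residual (zero force before contact, Hertz after) over a
#' window reaching back from the detected crossing, which removes the
#' late-crossing bias on soft samples.  For a fixed contact point the
#' modulus is profiled out in closed form, so the refinement is a 1-D
#' optimization.  Also reports the linear slope of force versus
#' distance over the contact region, the quantity mapped as "local
#' stiffness" in quantitative-imaging scans.
#'
#' @param curve data.frame with `distance_um`, `force_nN`.
#' @param tip a [tip_model()].
#' @param spring_constant_N_per_m cantilever spring constant.
#' @param kappa,baseline_fraction,min_run passed to
#'   [detect_contact_point()].
#' @return list of class `hertz_fit`: `contact_um`, `E_pa`,
#'   `slope_nN_per_um`, `residual_norm`, `n_contact_samples`,
#'   `clipped` (TRUE when a negative fitted modulus was clipped to 0).
#' @export
fit_hertz_pyramid <- function(curve, tip = tip_model(),
                              spring_constant_N_per_m = 0.03,
                              kappa = 3, baseline_fraction = 0.4,
                              min_run = 5L) {
  z <- curve$distance_um
  f <- curve$force_nN
  k_nN_um <- spring_constant_N_per_m * 1000
  C0 <- hertz_pyramid_coefficient(tip$half_angle_deg, tip$poisson)
  a_unit <- 1e-3 * C0                      # nN/um^2 per Pa

  crossing <- detect_contact_point(curve, kappa, baseline_fraction, min_run)

  E_for <- function(zc) {
    delta <- (z - zc) - f / k_nN_um
    use <- z >= zc & delta > 0
    if (sum(use) < 5L) return(list(E = NA_real_, rss = Inf, n = sum(use)))
    d2 <- delta[use]^2
    E <- sum(f[use] * d2) / (a_unit * sum(d2^2))
    E <- max(E, 0)
    pred <- numeric(length(z))
    pred[use] <- a_unit * E * d2
    list(E = E, rss = sum((f - pred)^2), n = sum(use))
  }

  # refine the contact point over a window reaching back from the
  # detected crossing: coarse grid, then golden-section polish
  lo <- z[2]
  hi <- min(crossing + 2 * mean(diff(z)), max(z))
  grid <- seq(lo, hi, length.out = 64L)
  rss_grid <- vapply(grid, function(zc) E_for(zc)$rss, numeric(1))
  best <- which.min(rss_grid)
  bl <- grid[max(1L, best - 1L)]
  bh <- grid[min(length(grid), best + 1L)]
  zc <- if (bh > bl) {
    optimize(function(zc) E_for(zc)$rss, c(bl, bh), tol = 1e-9)$minimum
  } else grid[best]
  fit <- E_for(zc)
  m3d_assert(is.finite(fit$rss), "migr3d_length_error",
             "fewer than 5 samples in the contact region")

  use <- z >= zc
  slope <- unname(coef(lm(f[use] ~ z[use]))[2])
  structure(list(contact_um = zc, E_pa = fit$E,
                 slope_nN_per_um = slope,
                 residual_norm = sqrt(fit$rss),
                 n_contact_samples = fit$n,
                 clipped = fit$E == 0 && any(f[use] < 0)),
            class = "hertz_fit")
}

#' Per-pixel stiffness map of a force-curve grid
#'
#' Runs [fit_hertz_pyramid()] on every pixel of a quantitative-imaging
#' bundle and assembles slope and Young's-modulus maps.  Pixels where
#' no contact is found are flagged `NA` and excluded from summaries.
#' Optional map pre-filters mirror common AFM post-processing: a 3x3
#' median filter and background subtraction of the map minimum.
#'
#' @param bundle a [force_bundle()].
#' @param tip a [tip_model()].
#' @param median_filter apply a 3x3 median filter to the maps.
#' @param subtract_background subtract the map minimum.
#' @param ... passed to [fit_hertz_pyramid()].
#' @return list of class `stiffness_map`: `slope_nN_per_um` and `E_pa`
#'   (matrices), `failed` (logical matrix), `pitch_um`.
#' @export
build_stiffness_map <- function(bundle, tip = tip_model(),
                                median_filter = FALSE,
                                subtract_background = FALSE, ...) {
  stopifnot(inherits(bundle, "force_bundle"))
  sh <- bundle$shape
  slope <- E <- matrix(NA_real_, sh[1], sh[2])
  for (r in seq_len(sh[1])) {
    for (cl in seq_len(sh[2])) {
      fit <- tryCatch(
        fit_hertz_pyramid(bundle_curve(bundle, r, cl), tip,
                          bundle$spring_constant_N_per_m, ...),
        migr3d_no_contact = function(e) NULL,
        migr3d_length_error = function(e) NULL)
      if (!is.null(fit)) {
        slope[r, cl] <- fit$slope_nN_per_um
        E[r, cl] <- fit$E_pa
      }
    }
  }
  failed <- is.na(E)
  m3d_assert(mean(failed) <= 0.5, "migr3d_map_quality_error",
             "more than 50%% of pixels failed to fit (%d of %d)",
             sum(failed), length(failed))
  if (median_filter) {
    slope <- .median3x3(slope)
    E <- .median3x3(E)
  }
  if (subtract_background) {
    slope <- slope - min(slope, na.rm = TRUE)
    E <- pmax(E - min(E, na.rm = TRUE), 0)
  }
  structure(list(slope_nN_per_um = slope, E_pa = E, failed = failed,
                 pitch_um = bundle$pitch_um),
            class = "stiffness_map")
}

.median3x3 <- function(m) {
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (r in seq_len(nr)) {
    for (cl in seq_len(nc)) {
      patch <- m[max(1, r - 1):min(nr, r + 1),
                 max(1, cl - 1):min(nc, cl + 1)]
      out[r, cl] <- median(patch, na.rm = TRUE)
    }
  }
  out
}

#' Segment a stiffness map into fiber and background pixels
#'
#' Otsu threshold on the slope map (slope is proportional to local
#' stiffness), with a manual override.
#'
#' @param map a `stiffness_map`.
#' @param threshold optional manual slope threshold (nN/um).
#' @return logical matrix, `TRUE` for fiber pixels (`NA` where the fit
#'   failed).
#' @export
segment_stiffness_map <- function(map, threshold = NULL) {
  stopifnot(inherits(map, "stiffness_map"))
  s <- map$slope_nN_per_um
  if (is.null(threshold)) threshold <- otsu_threshold(s[!is.na(s)])
  fiber <- s > threshold
  fiber[map$failed] <- NA
  fiber
}

#' Fiber-to-background stiffness ratio
#'
#' Mean Young's modulus over fiber pixels divided by the mean over
#' background pixels — the dimensionless contrast that separates gels
#' with stiff fibers from gels whose fibers barely rise above the
#' background.
#'
#' @param map a `stiffness_map`.
#' @param fiber logical matrix of fiber labels, e.g. from
#'   [segment_stiffness_map()].
#' @return ratio (dimensionless).
#' @export
fiber_background_ratio <- function(map, fiber = segment_stiffness_map(map)) {
  stopifnot(inherits(map, "stiffness_map"))
  fe <- map$E_pa[which(fiber)]
  be <- map$E_pa[which(!fiber)]
  m3d_assert(length(fe) > 0 && length(be) > 0, "migr3d_degenerate_input",
             "both fiber and background pixels are required")
  mean(fe, na.rm = TRUE) / mean(be, na.rm = TRUE)
}

#' Bulk Young's modulus from an oscillatory shear measurement
#'
#' Converts a storage shear modulus from bulk rheometry to a Young's
#' modulus under linear isotropic elasticity, `E = 2 * G' * (1 + nu)`;
#' with the incompressible default `nu = 0.5` this is `E = 3 G'`,
#' consistent with the Poisson ratio used for the AFM analysis.
#'
#' @param G_prime_pa storage shear modulus G' in Pa.
#' @param poisson Poisson ratio (default 0.5).
#' @return Young's modulus in Pa.
#' @export
bulk_young_from_shear <- function(G_prime_pa, poisson = 0.5) {
  m3d_assert(all(G_prime_pa >= 0), "migr3d_validation_error", "G' must be >= 0")
  m3d_assert(poisson >= 0 && poisson <= 0.5, "migr3d_validation_error",
             "Poisson ratio must be in [0, 0.5]")
  2 * G_prime_pa * (1 + poisson)
}
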