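#' Specification of a synthetic AFM force-curve grid
#'
#' Generates quantitative-imaging style approach curves from the
#' quadratic-pyramid Hertz contact model.  Before the contact point the
#' force is pure baseline noise; past it the recorded force solves the
#' implicit deflection-corrected relation
#' `F = C(theta, nu) * E * ((z - z_c) - F / k)^2`, where `k` is the
#' cantilever spring constant, so the generated curves are consistent
#' with the indentation definition used by the fitting routine.
#'
#' @param E_pa true Young's modulus in Pa; a scalar (uniform grid) or a
#'   matrix of the grid shape (e.g. stiff-fiber stripes on a soft
#'   background).
#' @param contact_um contact point along the piezo axis.
#' @param z_range_um total piezo travel of the approach segment
#'   (default 5 um, the acquisition ramp size).
#' @param half_angle_deg pyramid half-front angle (default 15).
#' @param poisson sample Poisson ratio (default 0.5, incompressible).
#' @param noise_nN baseline force noise sd.
#' @param n_samples samples per curve.
#' @param shape grid (rows, cols).
#' @param pitch_um grid pitch.
#' @param spring_constant_N_per_m cantilever spring constant (default
#'   0.03).
#' @param seed RNG seed.
#' @return an `afm_sim_spec` list.
#' @export
afm_sim_spec <- function(E_pa, contact_um = 2, z_range_um = 5,
                         half_angle_deg = 15, poisson = 0.5,
                         noise_nN = 0, n_samples = 512L, shape = c(1L, 1L),
                         pitch_um = 20 / 128,
                         spring_constant_N_per_m = 0.03, seed = NULL) {
  m3d_assert(all(E_pa >= 0), "migr3d_validation_error", "E must be >= 0")
  m3d_assert(half_angle_deg > 0 && half_angle_deg < 90,
             "migr3d_validation_error", "half angle must be in (0, 90)")
  m3d_assert(poisson >= 0 && poisson <= 0.5, "migr3d_validation_error",
             "Poisson ratio must be in [0, 0.5]")
  m3d_assert(contact_um > 0 && contact_um < z_range_um,
             "migr3d_validation_error",
             "contact point must lie inside the piezo range")
  shape <- as.integer(shape)
  if (is.matrix(E_pa)) {
    m3d_assert(all(dim(E_pa) == shape), "migr3d_validation_error",
               "E matrix does not match grid shape")
  }
  structure(list(E_pa = E_pa, contact_um = contact_um,
                 z_range_um = z_range_um, half_angle_deg = half_angle_deg,
                 poisson = poisson, noise_nN = noise_nN,
                 n_samples = as.integer(n_samples), shape = shape,
                 pitch_um = pitch_um,
                 spring_constant_N_per_m = spring_constant_N_per_m,
                 seed = seed),
            class = "afm_sim_spec")
}

# physical root of F = a * (s - F/k)^2 with a in nN/um^2, k in nN/um;
# s = piezo travel past contact (um), vectorized over s >= 0
.hertz_force_implicit <- function(s, a, k_nN_um) {
  if (a == 0) return(rep(0, length(s)))
  A <- a / k_nN_um^2
  B <- -(2 * a * s / k_nN_um + 1)
  C <- a * s^2
  disc <- pmax(B^2 - 4 * A * C, 0)
  # smaller root (F -> a s^2 as k -> Inf), in the cancellation-free
  # conjugate form: the naive (-B - sqrt(disc)) / (2A) loses all
  # precision for stiff cantilevers where 4AC << B^2
  2 * C / (-B + sqrt(disc))
}

#' Simulate an AFM force-curve bundle with known ground truth
#'
#' @param spec an [afm_sim_spec()].
#' @return a [force_bundle()]; identical spec + seed gives identical
#'   output.
#' @export
simulate_force_bundle <- function(spec) {
  stopifnot(inherits(spec, "afm_sim_spec"))
  k_nN_um <- spec$spring_constant_N_per_m * 1000
  C0 <- hertz_pyramid_coefficient(spec$half_angle_deg, spec$poisson)
  z <- seq(0, spec$z_range_um, length.out = spec$n_samples)
  Emat <- if (is.matrix(spec$E_pa)) spec$E_pa else
    matrix(spec$E_pa, spec$shape[1], spec$shape[2])
  build <- function() {
    curves <- vector("list", prod(spec$shape))
    for (r in seq_len(spec$shape[1])) {
      for (cl in seq_len(spec$shape[2])) {
        a <- 1e-3 * C0 * Emat[r, cl]            # nN/um^2 per (um)^2
        s <- pmax(z - spec$contact_um, 0)
        f <- .hertz_force_implicit(s, a, k_nN_um)
        if (spec$noise_nN > 0) f <- f + rnorm(length(f), sd = spec$noise_nN)
        curves[[(r - 1L) * spec$shape[2] + cl]] <-
          data.frame(distance_um = z, force_nN = f)
      }
    }
    force_bundle(curves, spec$shape, spec$pitch_um,
                 spec$spring_constant_N_per_m)
  }
  if (is.null(spec$seed)) build() else withr::with_seed(spec$seed, build())
}
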