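#' Specification of a synthetic fiber-network volume
#'
#' Emulates labeled collagen gels as a binary voxel mask of cylindrical
#' fibers.  Two placement modes:
#' \describe{
#'   \item{`uniform_random_lines`}{straight fibers with uniform random
#'     position and orientation, the idealized isotropic gel; pore size
#'     falls as fiber count rises.}
#'   \item{`parallel_pairs`}{two dense parallel walls of touching
#'     fibers (along x, tiled in y) whose clear face-to-face gap is
#'     `pair_spacing_um`, emulating migration channels between two
#'     parallel fibers; the local thickness inside the gap equals the
#'     spacing up to voxel discretization.}
#' }
#'
#' @param extent_um length-3 physical volume extent (z, y, x) in um.
#' @param voxel_um isotropic voxel size in um.
#' @param n_fibers number of fibers (`uniform_random_lines` only).
#' @param fiber_radius_um fiber radius; must be at least one voxel.
#' @param placement `"uniform_random_lines"` or `"parallel_pairs"`.
#' @param pair_spacing_um clear gap between the two fiber walls.
#' @param seed RNG seed.
#' @return a `network_sim_spec` list.
#' @export
network_sim_spec <- function(extent_um, voxel_um, n_fibers = 20L,
                             fiber_radius_um = 1,
                             placement = c("uniform_random_lines",
                                           "parallel_pairs"),
                             pair_spacing_um = 14, seed = NULL) {
  placement <- match.arg(placement)
  if (length(extent_um) == 1L) extent_um <- rep(extent_um, 3L)
  m3d_assert(all(extent_um > 0) && voxel_um > 0, "migr3d_validation_error",
             "volume extent and voxel size must be positive")
  m3d_assert(fiber_radius_um >= voxel_um, "migr3d_validation_error",
             "fiber radius (%g um) below one voxel (%g um)",
             fiber_radius_um, voxel_um)
  m3d_assert(n_fibers >= 0, "migr3d_validation_error", "n_fibers < 0")
  structure(list(extent_um = extent_um, voxel_um = voxel_um,
                 n_fibers = as.integer(n_fibers),
                 fiber_radius_um = fiber_radius_um, placement = placement,
                 pair_spacing_um = pair_spacing_um, seed = seed),
            class = "network_sim_spec")
}

#' Simulate a binary fiber-network volume
#'
#' Voxels whose centers lie within `fiber_radius_um` of any fiber axis
#' are foreground (1); everything else is pore space (0).
#'
#' @param spec a [network_sim_spec()].
#' @return a binary [volume_image()].
#' @export
simulate_network <- function(spec) {
  stopifnot(inherits(spec, "network_sim_spec"))
  h <- spec$voxel_um
  d <- pmax(1L, as.integer(round(spec$extent_um / h)))  # (z, y, x)
  # voxel-center coordinate grids in um, axis order (z, y, x)
  zc <- (seq_len(d[1]) - 0.5) * h
  yc <- (seq_len(d[2]) - 0.5) * h
  xc <- (seq_len(d[3]) - 0.5) * h
  Z <- array(rep(zc, times = d[2] * d[3]), dim = d)
  Y <- array(rep(yc, each = d[1], times = d[3]), dim = d)
  X <- array(rep(xc, each = d[1] * d[2]), dim = d)
  mask <- array(0, dim = d)

  paint_line <- function(p0, u) {
    # squared distance from voxel centers to the infinite line p0 + t*u
    wx <- X - p0[1]; wy <- Y - p0[2]; wz <- Z - p0[3]
    proj <- wx * u[1] + wy * u[2] + wz * u[3]
    d2 <- wx^2 + wy^2 + wz^2 - proj^2
    mask[d2 <= spec$fiber_radius_um^2] <<- 1
  }

  build <- function() {
    if (spec$placement == "uniform_random_lines") {
      if (spec$n_fibers > 0) {
        for (i in seq_len(spec$n_fibers)) {
          p0 <- runif(3) * rev(spec$extent_um)    # (x, y, z)
          u <- .unit_sphere(1)[1, ]
          paint_line(p0, u)
        }
      }
    } else {
      r <- spec$fiber_radius_um
      # two walls of touching fibers along x, tiled in y, centered in z
      z_lo <- spec$extent_um[1] / 2 - spec$pair_spacing_um / 2 - r
      z_hi <- spec$extent_um[1] / 2 + spec$pair_spacing_um / 2 + r
      m3d_assert(z_lo >= 0 && z_hi <= spec$extent_um[1],
                 "migr3d_validation_error",
                 "pair spacing plus fibers exceeds volume extent")
      for (y0 in seq(r, spec$extent_um[2] + r, by = 2 * r)) {
        paint_line(c(0, y0, z_lo), c(1, 0, 0))
        paint_line(c(0, y0, z_hi), c(1, 0, 0))
      }
    }
    volume_image(mask, rep(h, 3))
  }
  if (is.null(spec$seed)) build() else withr::with_seed(spec$seed, build())
}
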