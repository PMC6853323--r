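#' Local thickness (largest inscribed sphere) of a binary volume
#'
#' For every voxel of the selected phase, the value is the diameter (in
#' micrometres) of the largest sphere that lies entirely inside that
#' phase and covers the voxel — the classic local-thickness definition
#' used for pore- and cell-size estimation in fibrous gels.  Applied to
#' the background phase of a fiber mask it yields a pore-size map;
#' applied to the foreground of a cell mask, a cell-size map.
#'
#' The discrete model is evaluated on voxel centers: a sphere centered
#' at phase voxel `c` has maximal radius `R(c) = d(c) - h/2`, with
#' `d(c)` the Euclidean distance from `c` to the nearest
#' complement-phase voxel center and `h` the (isotropic) voxel size,
#' and it covers every voxel within `R(c)` of `c`.  So an isolated
#' single-voxel pore has thickness one voxel, and a slab of `n` voxels
#' has thickness `n` voxels up to one-voxel discretization.  Spheres
#' may protrude through the volume faces (the border is not treated as
#' complement), which keeps slab and channel measurements unbiased near
#' the edges.  Computed via an exact squared Euclidean distance
#' transform followed by sphere-covering propagation in compiled code.
#'
#' @param mask a binary [volume_image()] with isotropic voxels.
#' @param phase `"background"` (pores, value 0) or `"foreground"`
#'   (objects, value 1).
#' @return a `pore_map`: a [volume_image()] whose data holds the
#'   thickness in micrometres (0 on the complementary phase), with the
#'   analyzed phase recorded in `$phase`.
#' @export
local_thickness <- function(mask, phase = c("background", "foreground")) {
  phase <- match.arg(phase)
  stopifnot(inherits(mask, "volume_image"))
  m3d_assert(mask$binary, "migr3d_validation_error",
             "local_thickness requires a binary mask")
  h <- mask$voxel_size_um
  m3d_assert(diff(range(h)) < 1e-9 * max(h), "migr3d_validation_error",
             "local_thickness requires isotropic voxels")
  sel <- if (phase == "background") mask$data == 0 else mask$data == 1
  m3d_assert(any(sel), "migr3d_degenerate_input",
             "selected phase '%s' is empty", phase)
  tv <- cpp_local_thickness(as.logical(sel), dim(mask$data))
  out <- volume_image(array(tv * h[1], dim = dim(mask$data)), h)
  out$binary <- FALSE
  out$phase <- phase
  class(out) <- c("pore_map", class(out))
  out
}

#' Summarize a thickness map into a size distribution
#'
#' Voxel-weighted mean and spread of the local-thickness map over the
#' analyzed phase: each phase voxel contributes its thickness value, the
#' convention of the standard local-thickness implementations.
#'
#' @param pore_map a `pore_map` from [local_thickness()].
#' @param breaks histogram break specification passed to [graphics::hist()]
#'   semantics via [base::cut()]; default 16 equal-width bins.
#' @return list of class `size_summary`: `mean_um`, `sd_um`, `n`
#'   (phase voxel count), `hist` (data.frame `mid_um`, `count`).
#' @export
summarize_sizes <- function(pore_map, breaks = 16L) {
  stopifnot(inherits(pore_map, "pore_map"))
  v <- pore_map$data[pore_map$data > 0]
  m3d_assert(length(v) > 0, "migr3d_degenerate_input", "empty thickness map")
  edges <- seq(min(v), max(v), length.out = breaks + 1L)
  if (edges[1] == edges[length(edges)]) {
    hist <- data.frame(mid_um = edges[1], count = length(v))
  } else {
    idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
                breaks)
    hist <- data.frame(mid_um = (edges[-1] + edges[-length(edges)]) / 2,
                       count = tabulate(idx, breaks))
  }
  structure(list(mean_um = mean(v), sd_um = if (length(v) > 1) sd(v) else 0,
                 n = length(v), hist = hist),
            class = "size_summary")
}

#' Local pore size at a physical position
#'
#' Looks up the pore-size map at the voxel enclosing a cell position
#' (e.g. the first tracked position of a cell).  If that voxel lies on
#' the complementary phase — the cell center rests on a fiber voxel —
#' the maximum within the 1-voxel neighborhood is returned, since a
#' cell occupies the pore around it.
#'
#' @param pore_map a `pore_map` from [local_thickness()].
#' @param position_um length-3 position `(x, y, z)` in micrometres.
#' @return local thickness in micrometres.
#' @export
local_pore_size_at <- function(pore_map, position_um) {
  stopifnot(inherits(pore_map, "pore_map"))
  h <- pore_map$voxel_size_um          # (z, y, x)
  d <- dim(pore_map$data)
  # physical (x, y, z) -> 0-based voxel index (i=z, j=y, k=x)
  idx0 <- floor(c(position_um[3] / h[1], position_um[2] / h[2],
                  position_um[1] / h[3]))
  m3d_assert(all(idx0 >= 0) && all(idx0 <= d - 1), "migr3d_bounds_error",
             "position (%g, %g, %g) um outside the volume",
             position_um[1], position_um[2], position_um[3])
  idx <- as.integer(idx0) + 1L
  val <- pore_map$data[idx[1], idx[2], idx[3]]
  if (val == 0) {
    lo <- pmax(idx - 1L, 1L)
    hi <- pmin(idx + 1L, d)
    val <- max(pore_map$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
  }
  val
}
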