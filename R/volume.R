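#' Construct a 3D volume image
#'
#' Volumes are stored as `(z, y, x)` arrays with voxel sizes in
#' micrometres per axis, matching stack acquisition order.  Physical
#' coordinates are right-handed with x/y in the image plane; the voxel
#' with 0-based index `(i, j, k)` has its center at
#' `((k + 0.5) * vx, (j + 0.5) * vy, (i + 0.5) * vz)` in (x, y, z) um.
#'
#' @param data 3D numeric array, axis order `(z, y, x)`.
#' @param voxel_size_um numeric length-3, voxel size per `(z, y, x)`
#'   axis in micrometres.
#' @param normalize_two_level rescale a stack holding exactly two
#'   levels `{0, v}` (e.g. an 8-bit `{0, 255}` mask) to a binary
#'   `{0, 1}` mask; [read_volume()] enables this, the plain constructor
#'   leaves values untouched so continuous maps with two levels are not
#'   mangled.
#' @return object of class `volume_image` with elements `data`,
#'   `voxel_size_um`, `axis_order` (always `"zyx"`) and `binary`.
#' @export
volume_image <- function(data, voxel_size_um, normalize_two_level = FALSE) {
  m3d_assert(is.array(data) && length(dim(data)) == 3L,
             "migr3d_shape_error", "volume data must be a 3D array")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  m3d_assert(length(voxel_size_um) == 3L && all(voxel_size_um > 0),
             "migr3d_config_error", "voxel sizes must be 3 positive numbers")
  vals <- unique(as.vector(data))
  binary <- all(vals %in% c(0, 1))
  if (!binary && normalize_two_level && length(vals) == 2L && 0 %in% vals) {
    data <- data / max(vals)
    binary <- TRUE
  }
  structure(list(data = data, voxel_size_um = voxel_size_um,
                 axis_order = "zyx", binary = binary),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume_image %d x %d x %d (z,y,x), voxel %s um%s\n",
              d[1], d[2], d[3],
              paste(signif(x$voxel_size_um, 4), collapse = " x "),
              if (x$binary) ", binary" else ""))
  invisible(x)
}

.sidecar_path <- function(path) paste0(path, ".json")

#' Write a volume as a multi-page TIFF plus JSON sidecar
#'
#' One TIFF page per z-slice.  Values are rescaled into `[0, 1]` for
#' storage; the scale and the voxel size are recorded in a JSON sidecar
#' `<path>.json` so that [read_volume()] restores physical values.
#'
#' @param vol a [volume_image()].
#' @param path output TIFF path.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  scale <- max(vol$data, 1e-300)
  if (scale <= 1) scale <- 1
  pages <- lapply(seq_len(dim(vol$data)[1]),
                  function(i) vol$data[i, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(voxel_size_um = vol$voxel_size_um, value_scale = scale,
         axis_order = "zyx"),
    .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume from a multi-page TIFF
#'
#' @param path TIFF path; a JSON sidecar `<path>.json` with
#'   `voxel_size_um` (and optionally `value_scale`) is used when
#'   present.
#' @param voxel_size_um fallback voxel size when no sidecar exists.
#' @return a [volume_image()]; stacks with exactly two levels including
#'   zero are normalized to a binary `{0, 1}` mask.
#' @export
read_volume <- function(path, voxel_size_um = NULL) {
  m3d_assert(file.exists(path), "migr3d_io_error", "no such file: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  m3d_assert(length(dim(pages[[1]])) == 2L, "migr3d_shape_error",
             "expected single-channel slices in %s", path)
  scale <- 1
  sc <- .sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$voxel_size_um)) voxel_size_um <- meta$voxel_size_um
    if (!is.null(meta$value_scale)) scale <- meta$value_scale
  }
  m3d_assert(!is.null(voxel_size_um), "migr3d_config_error",
             "no voxel size: provide voxel_size_um or a %s sidecar", sc)
  d <- c(length(pages), dim(pages[[1]]))
  data <- array(0, dim = d)
  for (i in seq_along(pages)) data[i, , ] <- pages[[i]] * scale
  # undo 16-bit quantization for near-integer data
  if (max(abs(data - round(data))) < 1e-3) data <- round(data)
  volume_image(data, voxel_size_um, normalize_two_level = TRUE)
}

#' Otsu threshold of an intensity sample
#'
#' Utility for turning fluorescence intensities (volumes or AFM slope
#' maps) into binary masks when no segmentation is supplied.  Maximizes
#' between-class variance over a histogram of `n_bins` equal-width bins.
#'
#' @param x numeric vector/array of intensities.
#' @param n_bins histogram resolution.
#' @return scalar threshold; values strictly above it are "foreground".
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.vector(x[is.finite(x)])
  m3d_assert(length(x) > 0, "migr3d_degenerate_input", "empty intensity sample")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w1 <- cumsum(counts); w2 <- sum(counts) - w1
  m1 <- cumsum(counts * mids) / pmax(w1, 1)
  m2 <- (sum(counts * mids) - cumsum(counts * mids)) / pmax(w2, 1)
  valid <- w1 > 0 & w2 > 0
  between <- ifelse(valid, w1 * w2 * (m1 - m2)^2, -Inf)
  edges[which.max(between) + 1L]
}
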