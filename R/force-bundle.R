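#' Construct an AFM force-curve bundle
#'
#' A bundle holds one force-distance approach curve per pixel of a
#' quantitative-imaging scan grid, plus the grid geometry and the
#' cantilever spring constant.  Each curve is a data.frame with columns
#' `distance_um` (piezo extension toward the sample, strictly
#' increasing along the approach) and `force_nN`.
#'
#' @param curves list of curve data.frames in row-major pixel order
#'   (row 1 col 1, row 1 col 2, ...).
#' @param shape integer (rows, cols) of the scan grid.
#' @param pitch_um grid pitch in micrometres.
#' @param spring_constant_N_per_m cantilever spring constant.
#' @return object of class `force_bundle`.
#' @export
force_bundle <- function(curves, shape, pitch_um,
                         spring_constant_N_per_m = 0.03) {
  shape <- as.integer(shape)
  m3d_assert(length(shape) == 2L && all(shape > 0L),
             "migr3d_validation_error", "grid shape must be 2 positive counts")
  m3d_assert(pitch_um > 0, "migr3d_validation_error", "grid pitch must be > 0")
  m3d_assert(length(curves) == prod(shape), "migr3d_validation_error",
             "pixel count mismatch: %d curves for a %d x %d grid",
             length(curves), shape[1], shape[2])
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    m3d_assert(is.data.frame(cv) &&
                 all(c("distance_um", "force_nN") %in% names(cv)),
               "migr3d_format_error",
               "curve %d lacks distance_um/force_nN columns", i)
    m3d_assert(nrow(cv) >= 2L, "migr3d_validation_error",
               "curve %d has fewer than 2 samples", i)
    m3d_assert(all(diff(cv$distance_um) > 0), "migr3d_validation_error",
               "curve %d: distances not monotone along approach", i)
  }
  structure(list(curves = curves, shape = shape, pitch_um = pitch_um,
                 spring_constant_N_per_m = spring_constant_N_per_m),
            class = "force_bundle")
}

#' Index a bundle curve by grid position
#' @param bundle a [force_bundle()].
#' @param row,col 1-based grid indices.
#' @export
bundle_curve <- function(bundle, row, col) {
  stopifnot(inherits(bundle, "force_bundle"))
  m3d_assert(row >= 1 && row <= bundle$shape[1] &&
               col >= 1 && col <= bundle$shape[2],
             "migr3d_bounds_error", "pixel (%d, %d) outside grid", row, col)
  bundle$curves[[(row - 1L) * bundle$shape[2] + col]]
}

#' Write a force bundle to a directory
#'
#' Layout: `grid.json` with `shape`, `pitch_um` and
#' `spring_constant_N_per_m`, plus one `curve_<row>_<col>.tsv` per pixel
#' (tab-separated, columns `distance_um`, `force_nN`; indices 1-based).
#'
#' @param bundle a [force_bundle()].
#' @param dir output directory (created if needed).
#' @export
write_force_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "force_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(shape = bundle$shape, pitch_um = bundle$pitch_um,
         spring_constant_N_per_m = bundle$spring_constant_N_per_m),
    file.path(dir, "grid.json"), auto_unbox = TRUE, digits = NA)
  for (r in seq_len(bundle$shape[1])) {
    for (cl in seq_len(bundle$shape[2])) {
      cv <- bundle_curve(bundle, r, cl)
      write.table(cv[, c("distance_um", "force_nN")],
                  file.path(dir, sprintf("curve_%d_%d.tsv", r, cl)),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}

#' Read a force bundle from a directory
#' @param dir directory written by [write_force_bundle()].
#' @return a [force_bundle()].
#' @export
read_force_bundle <- function(dir) {
  gj <- file.path(dir, "grid.json")
  m3d_assert(file.exists(gj), "migr3d_io_error", "no grid.json in %s", dir)
  meta <- jsonlite::read_json(gj, simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  files <- list.files(dir, pattern = "^curve_\\d+_\\d+\\.tsv$")
  m3d_assert(length(files) == prod(shape), "migr3d_validation_error",
             "pixel count mismatch: %d curve files for a %d x %d grid",
             length(files), shape[1], shape[2])
  curves <- vector("list", prod(shape))
  for (r in seq_len(shape[1])) {
    for (cl in seq_len(shape[2])) {
      f <- file.path(dir, sprintf("curve_%d_%d.tsv", r, cl))
      m3d_assert(file.exists(f), "migr3d_validation_error",
                 "missing curve file for pixel (%d, %d)", r, cl)
      curves[[(r - 1L) * shape[2] + cl]] <-
        read.table(f, header = TRUE, sep = "\t")
    }
  }
  force_bundle(curves, shape, meta$pitch_um, meta$spring_constant_N_per_m)
}
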