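#' Specification of a synthetic trajectory cohort
#'
#' Defines one homogeneous group of ground-truth trajectories.  Motion
#' models:
#' \describe{
#'   \item{`fbm`}{each coordinate an independent fractional Brownian
#'     motion with Hurst exponent `hurst`, so the ensemble MSD grows as
#'     `tau^(2 * hurst)`; increments have per-frame standard deviation
#'     `step_um`.  Generation is exact in covariance (Cholesky factor of
#'     the fractional-Gaussian-noise covariance).}
#'   \item{`confined_box`}{Gaussian random walk with reflecting
#'     boundaries inside a cube of edge `box_um`, mimicking a cell
#'     trapped in a pore; produces a saturating MSD (anomalous exponent
#'     below one) and a backtracking excess in the turning angles.}
#'   \item{`persistent`}{correlated random walk with fixed step length
#'     `step_um`: direction(t+1) = normalize(p * direction(t) +
#'     (1 - p) * u) with u a uniform random unit vector; superdiffusive
#'     over the first few lags for `persistence` near one.}
#'   \item{`ballistic`}{straight line, constant step `step_um` per
#'     frame.}
#' }
#'
#' @param n_tracks number of tracks.
#' @param n_frames frames per track (default 50, the acquisition
#'   length).
#' @param frame_interval_s frame interval (default 1200 s = 20 min).
#' @param model one of `"fbm"`, `"confined_box"`, `"persistent"`,
#'   `"ballistic"`.
#' @param hurst Hurst exponent in (0, 1) for `fbm`.
#' @param step_um per-frame step scale in micrometres (per-coordinate
#'   increment sd for `fbm`/`confined_box`; full 3D step length for
#'   `persistent`/`ballistic`).
#' @param box_um cube edge for `confined_box`.
#' @param persistence direction-correlation parameter in [0, 1) for
#'   `persistent`.
#' @param phenotype,condition labels attached to every generated track.
#' @param start length-3 start position (x, y, z) in micrometres.
#' @param seed RNG seed; identical spec + seed gives identical output.
#' @return a `track_sim_spec` list.
#' @export
track_sim_spec <- function(n_tracks, n_frames = 50L, frame_interval_s = 1200,
                           model = c("fbm", "confined_box", "persistent",
                                     "ballistic"),
                           hurst = 0.5, step_um = 1, box_um = 10,
                           persistence = 0.9, phenotype = "unknown",
                           condition = "unknown", start = c(0, 0, 0),
                           seed = NULL) {
  model <- match.arg(model)
  m3d_assert(n_tracks >= 1 && n_frames >= 2, "migr3d_validation_error",
             "need at least 1 track and 2 frames")
  m3d_assert(step_um > 0, "migr3d_validation_error", "step_um must be > 0")
  if (model == "fbm") {
    m3d_assert(hurst > 0 && hurst < 1, "migr3d_validation_error",
               "hurst must lie in (0, 1)")
  }
  if (model == "confined_box") {
    m3d_assert(box_um > 0, "migr3d_validation_error", "box_um must be > 0")
  }
  if (model == "persistent") {
    m3d_assert(persistence >= 0 && persistence < 1,
               "migr3d_validation_error", "persistence must lie in [0, 1)")
  }
  structure(list(n_tracks = as.integer(n_tracks),
                 n_frames = as.integer(n_frames),
                 frame_interval_s = frame_interval_s, model = model,
                 hurst = hurst, step_um = step_um, box_um = box_um,
                 persistence = persistence, phenotype = phenotype,
                 condition = condition, start = start, seed = seed),
            class = "track_sim_spec")
}

# Cholesky factor of the fractional-Gaussian-noise covariance for n
# increments at unit step sd: gamma(k) = (|k+1|^2H - 2|k|^2H + |k-1|^2H)/2
.fgn_chol <- function(n, hurst) {
  k <- 0:(n - 1)
  gamma <- ((k + 1)^(2 * hurst) - 2 * k^(2 * hurst) +
              abs(k - 1)^(2 * hurst)) / 2
  chol(stats::toeplitz(gamma))
}

.unit_sphere <- function(n) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Simulate a cohort of ground-truth 3D trajectories
#'
#' @param spec a [track_sim_spec()].
#' @return a [track_table()] with track ids `<model>_<i>` and the
#'   spec's condition/phenotype labels.
#' @export
simulate_tracks <- function(spec) {
  stopifnot(inherits(spec, "track_sim_spec"))
  gen <- function() {
    n_inc <- spec$n_frames - 1L
    steps <- switch(
      spec$model,
      fbm = {
        L <- .fgn_chol(n_inc, spec$hurst)
        function() spec$step_um * crossprod(L, matrix(rnorm(3 * n_inc),
                                                      ncol = 3))
      },
      confined_box = function() {
        matrix(rnorm(3 * n_inc, sd = spec$step_um), ncol = 3)
      },
      persistent = function() {
        dirs <- matrix(0, n_inc, 3)
        d <- .unit_sphere(1)[1, ]
        u <- .unit_sphere(n_inc)
        for (i in seq_len(n_inc)) {
          d <- spec$persistence * d + (1 - spec$persistence) * u[i, ]
          d <- d / sqrt(sum(d^2))
          dirs[i, ] <- d
        }
        spec$step_um * dirs
      },
      ballistic = function() {
        matrix(rep(c(spec$step_um, 0, 0), each = n_inc), ncol = 3)
      })
    rows <- vector("list", spec$n_tracks)
    for (tr in seq_len(spec$n_tracks)) {
      cs <- apply(steps(), 2, cumsum)
      if (is.null(dim(cs))) cs <- matrix(cs, ncol = 3)
      pos <- rbind(spec$start, sweep(cs, 2, spec$start, `+`))
      if (spec$model == "confined_box") {
        # reflecting boundaries on [0, box] via triangle-wave folding
        pos <- apply(pos, 2, function(p) {
          f <- abs(((p %% (2 * spec$box_um)) + 2 * spec$box_um) %%
                     (2 * spec$box_um))
          ifelse(f > spec$box_um, 2 * spec$box_um - f, f)
        })
      }
      fr <- 0:(spec$n_frames - 1L)
      rows[[tr]] <- data.frame(
        track_id = sprintf("%s_%03d", spec$model, tr), frame = fr,
        time_s = fr * spec$frame_interval_s,
        x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
        condition = spec$condition, phenotype = spec$phenotype)
    }
    track_table(do.call(rbind, rows),
                frame_interval_s = spec$frame_interval_s)
  }
  if (is.null(spec$seed)) gen() else withr::with_seed(spec$seed, gen())
}

#' Concatenate track tables into one cohort
#'
#' Track ids are prefixed with a group index so cohorts built from
#' several specs keep per-track ground truth unambiguous.
#'
#' @param ... track tables (or a single list of them).
#' @export
bind_cohort <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && !is.data.frame(parts[[1]])) parts <- parts[[1]]
  for (i in seq_along(parts)) {
    parts[[i]]$track_id <- sprintf("g%d_%s", i, parts[[i]]$track_id)
  }
  track_table(do.call(rbind, parts))
}
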