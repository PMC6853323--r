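#' Time-averaged mean squared displacement of one track
#'
#' For each lag `k` the MSD is the average of the squared 3D Euclidean
#' displacement over all overlapping frame pairs `(t, t + k)`:
#' `msd_k = mean_t |r(t + k) - r(t)|^2`.  Overlapping time-averaging is
#' standard single-particle-tracking practice and maximizes the number
#' of pairs on short (50-frame) tracks.
#'
#' @param pos n x 3 matrix of positions (x, y, z) in micrometres, one
#'   row per frame, or a single-track [track_table()].
#' @param max_lag largest lag (frames) to evaluate.
#' @param frame_interval_s frame interval, used for the lag times.
#' @return data.frame of class `msd_curve` with columns `lag`, `tau_s`,
#'   `msd_um2`, `n_pairs`.
#' @export
compute_msd <- function(pos, max_lag, frame_interval_s = 1200) {
  pos <- .as_positions(pos, frame_interval_s)
  frame_interval_s <- attr(pos, "frame_interval_s")
  n <- nrow(pos)
  m3d_assert(n >= max_lag + 1, "migr3d_length_error",
             "track too short (%d frames) for max_lag %d", n, max_lag)
  msd <- n_pairs <- numeric(max_lag)
  for (k in seq_len(max_lag)) {
    d <- pos[(k + 1):n, , drop = FALSE] - pos[1:(n - k), , drop = FALSE]
    msd[k] <- mean(rowSums(d^2))
    n_pairs[k] <- n - k
  }
  structure(data.frame(lag = seq_len(max_lag),
                       tau_s = seq_len(max_lag) * frame_interval_s,
                       msd_um2 = msd, n_pairs = n_pairs),
            class = c("msd_curve", "data.frame"))
}

# accept a position matrix or a single-track track table; check uniform
# frame spacing and return the matrix with the frame interval attached
.as_positions <- function(pos, frame_interval_s) {
  if (inherits(pos, "track_table") || is.data.frame(pos)) {
    m3d_assert(length(unique(pos$track_id)) == 1L, "migr3d_validation_error",
               "expected a single track")
    fr <- pos$frame
    m3d_assert(length(unique(diff(fr))) <= 1L, "migr3d_validation_error",
               "non-uniform frame spacing in track '%s'", pos$track_id[1])
    if (nrow(pos) >= 2) {
      dt <- unique(diff(pos$time_s))
      m3d_assert(diff(range(dt)) < 1e-9 * max(dt, 1),
                 "migr3d_validation_error",
                 "non-uniform time spacing in track '%s'", pos$track_id[1])
      frame_interval_s <- dt[1]
    }
    pos <- as.matrix(pos[, c("x_um", "y_um", "z_um")])
  }
  m3d_assert(is.matrix(pos) && ncol(pos) == 3, "migr3d_validation_error",
             "positions must be an n x 3 matrix")
  attr(pos, "frame_interval_s") <- frame_interval_s
  pos
}

#' Fit the anomalous-diffusion power law to an MSD curve
#'
#' Fits `MSD(tau) = D * tau^alpha` over the first `n_lags` lags with
#' `D` and `alpha` free.  The canonical fit is ordinary least squares
#' in log-log space (deterministic, no initialization); a direct
#' nonlinear least-squares option is available for sensitivity checks.
#' `alpha` near 1 indicates diffusive motion, below 1 subdiffusive
#' (confined) and above 1 superdiffusive (persistent) motion.
#'
#' @param msd an `msd_curve` from [compute_msd()].
#' @param n_lags number of leading lags to use (default 5).
#' @param method `"loglog"` (default) or `"nls"`.
#' @return list of class `anomalous_fit` with `D_um2_per_s_alpha`,
#'   `alpha`, `n_lags_used`, `residual_norm` (log-space for
#'   `"loglog"`).
#' @export
fit_anomalous <- function(msd, n_lags = 5L, method = c("loglog", "nls")) {
  method <- match.arg(method)
  m3d_assert(nrow(msd) >= n_lags, "migr3d_length_error",
             "MSD curve has %d lags, need %d", nrow(msd), n_lags)
  sub <- msd[seq_len(n_lags), ]
  m3d_assert(all(sub$msd_um2 > 0), "migr3d_degenerate_input",
             "zero MSD among fit lags (stationary track): alpha undefined")
  if (method == "loglog") {
    fit <- lm(log(msd_um2) ~ log(tau_s), data = sub)
    alpha <- unname(coef(fit)[2])
    D <- exp(unname(coef(fit)[1]))
    rn <- sqrt(sum(stats::residuals(fit)^2))
  } else {
    start <- list(logD = log(sub$msd_um2[1] / sub$tau_s[1]), alpha = 1)
    nlfit <- if (requireNamespace("minpack.lm", quietly = TRUE)) {
      minpack.lm::nlsLM(msd_um2 ~ exp(logD) * tau_s^alpha, data = sub,
                        start = start)
    } else {
      stats::nls(msd_um2 ~ exp(logD) * tau_s^alpha, data = sub,
                 start = start)
    }
    alpha <- unname(coef(nlfit)["alpha"])
    D <- exp(unname(coef(nlfit)["logD"]))
    rn <- sqrt(sum(stats::residuals(nlfit)^2))
  }
  structure(list(D_um2_per_s_alpha = D, alpha = alpha,
                 n_lags_used = as.integer(n_lags), residual_norm = rn,
                 method = method),
            class = "anomalous_fit")
}

#' Cell speed from the first-lag MSD
#'
#' Speed is the root of the time-averaged squared single-frame
#' displacement divided by the frame time,
#' `sqrt(msd_1) / frame_interval`, reported in nm/s.  (The first
#' nonzero lag is used: the literal zero-lag MSD vanishes identically,
#' so only the first-lag reading yields a finite speed.)
#'
#' @inheritParams compute_msd
#' @return speed in nm/s.
#' @export
compute_speed <- function(pos, frame_interval_s = 1200) {
  pos <- .as_positions(pos, frame_interval_s)
  frame_interval_s <- attr(pos, "frame_interval_s")
  m3d_assert(nrow(pos) >= 2, "migr3d_length_error",
             "need at least 2 frames for a speed")
  msd1 <- compute_msd(pos, 1L, frame_interval_s)$msd_um2[1]
  1000 * sqrt(msd1) / frame_interval_s
}

#' Turning angles between successive steps
#'
#' For each interior frame, the angle (degrees, in \[0, 180\]) between
#' the incoming and outgoing displacement vectors; 0 is straight
#' motion, 180 is backtracking.  Zero-length steps have no direction
#' and are skipped.
#'
#' @inheritParams compute_msd
#' @return numeric vector of angles in degrees.
#' @export
compute_turning_angles <- function(pos, frame_interval_s = 1200) {
  pos <- .as_positions(pos, frame_interval_s)
  m3d_assert(nrow(pos) >= 3, "migr3d_length_error",
             "need at least 3 frames for turning angles")
  steps <- diff(pos)
  len <- sqrt(rowSums(steps^2))
  m3d_assert(any(len > 0), "migr3d_degenerate_input",
             "all steps have zero length: angles undefined")
  keep <- which(len[-length(len)] > 0 & len[-1] > 0)
  if (length(keep) == 0) return(numeric(0))
  a <- steps[keep, , drop = FALSE]
  b <- steps[keep + 1, , drop = FALSE]
  cosang <- rowSums(a * b) / (len[keep] * len[keep + 1])
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Net track displacement
#'
#' Euclidean distance between the first and last recorded positions of
#' the cell center of mass (the end-to-end distance of the track).
#'
#' @inheritParams compute_msd
#' @return displacement in micrometres.
#' @export
compute_track_displacement <- function(pos, frame_interval_s = 1200) {
  pos <- .as_positions(pos, frame_interval_s)
  m3d_assert(nrow(pos) >= 2, "migr3d_length_error",
             "need at least 2 frames for a displacement")
  sqrt(sum((pos[nrow(pos), ] - pos[1, ])^2))
}

#' Per-track motility feature table
#'
#' Runs the full per-track feature set over a cohort: speed (nm/s),
#' anomalous exponent and generalized diffusion coefficient from the
#' first `n_fit_lags` MSD lags, and track displacement.  Tracks that
#' are stationary over the fit lags get `NA` for `alpha` and `D`.
#'
#' @param table a [track_table()].
#' @param config a [run_config()].
#' @return data.frame with one row per track: `track_id`, `condition`,
#'   `phenotype`, `speed_nm_s`, `alpha`, `D_um2_per_s_alpha`,
#'   `track_displacement_um`, `n_frames`.
#' @export
track_features <- function(table, config = run_config()) {
  tracks <- split_tracks(table)
  rows <- lapply(names(tracks), function(id) {
    tr <- tracks[[id]]
    dt <- if (length(tr$time_s) >= 2) diff(tr$time_s)[1] else
      config$frame_interval_s
    fit <- tryCatch({
      msd <- compute_msd(tr$pos, config$n_fit_lags, dt)
      fit_anomalous(msd, config$n_fit_lags)
    }, migr3d_degenerate_input = function(e) NULL)
    data.frame(
      track_id = id, condition = tr$condition, phenotype = tr$phenotype,
      speed_nm_s = compute_speed(tr$pos, dt),
      alpha = if (is.null(fit)) NA_real_ else fit$alpha,
      D_um2_per_s_alpha = if (is.null(fit)) NA_real_ else
        fit$D_um2_per_s_alpha,
      track_displacement_um = compute_track_displacement(tr$pos, dt),
      n_frames = nrow(tr$pos))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled turning angles for a cohort
#'
#' @param table a [track_table()].
#' @return long-format data.frame `track_id`, `condition`, `phenotype`,
#'   `angle_deg`.
#' @export
cohort_angles <- function(table) {
  tracks <- split_tracks(table)
  rows <- lapply(names(tracks), function(id) {
    tr <- tracks[[id]]
    ang <- tryCatch(compute_turning_angles(tr$pos),
                    migr3d_degenerate_input = function(e) numeric(0),
                    migr3d_length_error = function(e) numeric(0))
    if (length(ang) == 0) return(NULL)
    data.frame(track_id = id, condition = tr$condition,
               phenotype = tr$phenotype, angle_deg = ang)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
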