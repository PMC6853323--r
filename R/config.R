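#' Pipeline run configuration
#'
#' Central defaults for the analysis pipeline.  The acquisition defaults
#' mirror the live-cell imaging protocol (20-min frame interval, 50
#' frames); the statistical defaults mirror the reported analysis
#' conventions (power-law fit to the first 5 MSD lags, 75th-percentile
#' fast/high thresholds, 4-um pore-size binning with a 2-um variant).
#'
#' @param frame_interval_s frame interval in seconds.
#' @param n_fit_lags number of leading MSD lags used in the anomalous
#'   fit.
#' @param percentile pooled percentile defining "fast" / "high" cells,
#'   in (0, 1).
#' @param bin_width_um pore-size bin width in micrometres.
#' @param seed RNG seed for stochastic stages.
#' @param paths named list of input/output paths (free-form).
#' @return a `run_config` list.
#' @export
run_config <- function(frame_interval_s = 1200, n_fit_lags = 5L,
                       percentile = 0.75, bin_width_um = 4,
                       seed = 1L, paths = list()) {
  m3d_assert(frame_interval_s > 0 && n_fit_lags > 0 && bin_width_um > 0,
             "migr3d_config_error", "numeric config parameters must be > 0")
  m3d_assert(percentile > 0 && percentile < 1, "migr3d_config_error",
             "percentile must lie in (0, 1)")
  structure(list(frame_interval_s = frame_interval_s,
                 n_fit_lags = as.integer(n_fit_lags),
                 percentile = percentile, bin_width_um = bin_width_um,
                 seed = as.integer(seed), paths = paths),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file; keys as in [run_config()]; missing keys take
#'   the defaults.
#' @export
read_run_config <- function(path) {
  m3d_assert(file.exists(path), "migr3d_io_error", "no such file: %s", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- names(formals(run_config))
  do.call(run_config, y[intersect(names(y), known)])
}

# one-line structured stage log with config echo, for reproducibility
m3d_log <- function(stage, cfg = NULL, ...) {
  extra <- list(...)
  msg <- sprintf("[migr3d:%s]", stage)
  if (!is.null(cfg)) {
    msg <- paste0(msg, sprintf(" seed=%d dt=%gs lags=%d q=%g bin=%gum",
                               cfg$seed, cfg$frame_interval_s,
                               cfg$n_fit_lags, cfg$percentile,
                               cfg$bin_width_um))
  }
  if (length(extra)) {
    msg <- paste(msg, paste(names(extra), unlist(extra),
                            sep = "=", collapse = " "))
  }
  message(msg)
  invisible(msg)
}
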