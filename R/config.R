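#' Analysis run configuration
#'
#' Bundles every tunable parameter of the surface-association analysis in one
#' validated object. Defaults reproduce the reference analysis: 3-hour bins,
#' an 8-bin (24-hour) trailing running mean, an event threshold of 0.75 and a
#' threshold sweep over 0.01--0.99 in steps of 0.02.
#'
#' @param bin_hours Width of the observation bins in hours. The default 3 h
#'   yields eight bins per day.
#' @param window_bins Length of the running-mean window in bins. With the
#'   defaults `window_bins * bin_hours` is 24 h, the definition of the
#'   surface-association probability.
#' @param window_align `"trailing"` (window ends at the current bin; default)
#'   or `"centered"`.
#' @param event_threshold Surface-association probability above which a bin
#'   belongs to an event. Must lie strictly inside (0, 1).
#' @param min_event_bins Minimum run length (bins above threshold) for a run
#'   to count as an event. Default 1.
#' @param sweep_lo,sweep_hi,sweep_step Range and step of the threshold sweep.
#' @param raster_cell_deg Raster cell size in degrees for the spatial
#'   combination (default 0.1).
#' @param ellipse_axis Whether geolocation CI widths are the full ellipse
#'   axes (`"full"`, default: semi-axis = half the CI width) or already the
#'   semi-axes (`"half"`).
#' @param month_days Days per month used for events-per-month-at-liberty
#'   (default 30.4375, the mean Gregorian month).
#' @param min_days Minimum series span in days for eligibility (default 30).
#' @param max_gap_hours Maximum tolerated inter-sample gap in hours
#'   (default 1).
#' @param coverage_floor Minimum fraction of expected samples for a bin to be
#'   valid (default 0.5).
#' @param min_fit_bins Minimum number of valid bins required to fit the HMM
#'   (default 64, i.e. eight windows).
#' @param log_depth_sd If `TRUE`, fit emissions on `log1p(depth_sd)` instead
#'   of raw diving amplitude. Default `FALSE`.
#' @param em_restarts Number of EM initialisations (1 moment-based + the rest
#'   randomly perturbed). Default 3.
#' @param em_max_iter Maximum EM iterations per restart. Default 500.
#' @param em_tol Relative log-likelihood change declaring convergence.
#'   Default 1e-6.
#' @param seed Integer seed from which all randomness (EM restarts,
#'   simulation, bootstrap) is derived.
#'
#' @return An object of class `run_config` (a validated named list).
#' @examples
#' cfg <- run_config(event_threshold = 0.8)
#' cfg$window_bins * cfg$bin_hours  # 24 hours
#' @export
run_config <- function(bin_hours = 3,
                       window_bins = 8,
                       window_align = c("trailing", "centered"),
                       event_threshold = 0.75,
                       min_event_bins = 1,
                       sweep_lo = 0.01, sweep_hi = 0.99, sweep_step = 0.02,
                       raster_cell_deg = 0.1,
                       ellipse_axis = c("full", "half"),
                       month_days = 30.4375,
                       min_days = 30, max_gap_hours = 1,
                       coverage_floor = 0.5,
                       min_fit_bins = 64,
                       log_depth_sd = FALSE,
                       em_restarts = 3, em_max_iter = 500, em_tol = 1e-6,
                       seed = 1L) {
  window_align <- match.arg(window_align)
  ellipse_axis <- match.arg(ellipse_axis)
  stopifnot(
    bin_hours > 0, window_bins >= 1,
    min_event_bins >= 1,
    sweep_lo < sweep_hi, sweep_step > 0,
    raster_cell_deg > 0, month_days > 0,
    min_days > 0, max_gap_hours > 0,
    coverage_floor >= 0, coverage_floor <= 1,
    min_fit_bins >= 2,
    em_restarts >= 1, em_max_iter >= 1, em_tol > 0
  )
  if (!(event_threshold > 0 && event_threshold < 1)) {
    stop("`event_threshold` must lie strictly between 0 and 1")
  }
  cfg <- list(
    bin_hours = bin_hours, window_bins = window_bins,
    window_align = window_align,
    event_threshold = event_threshold, min_event_bins = min_event_bins,
    sweep_lo = sweep_lo, sweep_hi = sweep_hi, sweep_step = sweep_step,
    raster_cell_deg = raster_cell_deg, ellipse_axis = ellipse_axis,
    month_days = month_days,
    min_days = min_days, max_gap_hours = max_gap_hours,
    coverage_floor = coverage_floor, min_fit_bins = min_fit_bins,
    log_depth_sd = log_depth_sd,
    em_restarts = em_restarts, em_max_iter = em_max_iter, em_tol = em_tol,
    seed = as.integer(seed)
  )
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("surfassoc run configuration\n")
  cat(sprintf("  bins: %g h, window: %d bins (%g h, %s)\n",
              x$bin_hours, x$window_bins, x$window_bins * x$bin_hours,
              x$window_align))
  cat(sprintf("  event threshold: %g (min run %d bin(s)); sweep %g-%g by %g\n",
              x$event_threshold, x$min_event_bins,
              x$sweep_lo, x$sweep_hi, x$sweep_step))
  cat(sprintf("  eligibility: >= %g days, gaps <= %g h\n",
              x$min_days, x$max_gap_hours))
  cat(sprintf("  EM: %d restart(s), max %d iter, tol %g; seed %d\n",
              x$em_restarts, x$em_max_iter, x$em_tol, x$seed))
  invisible(x)
}
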