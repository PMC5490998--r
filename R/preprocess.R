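## Eligibility screening and reduction of raw sensor samples to the
## bivariate 3-hour observation series (diving amplitude, thermal habitat).

#' Screen a tag series for eligibility
#'
#' A series is eligible when it spans at least `min_days` days and contains
#' no inter-sample gap longer than `max_gap` hours.
#'
#' @param series A [tag_series()].
#' @param min_days Minimum span in days (default 30).
#' @param max_gap Maximum tolerated gap in hours (default 1).
#' @return A list with elements `eligible` (logical), `reasons` (character
#'   vector, empty when eligible), `span_days` and `max_gap_hours`.
#' @export
screen_eligibility <- function(series, min_days = 30, max_gap = 1) {
  stopifnot(inherits(series, "tag_series"))
  ts <- series$samples$timestamp
  if (length(ts) == 0L) stop("empty series")
  span_days <- as.numeric(difftime(ts[length(ts)], ts[1L], units = "days"))
  gaps <- if (length(ts) > 1L) diff(as.numeric(ts)) / 3600 else 0
  max_gap_hours <- max(gaps)
  reasons <- character()
  if (span_days < min_days) {
    reasons <- c(reasons, sprintf("span < %g days (%.2f days)",
                                  min_days, span_days))
  }
  if (max_gap_hours > max_gap) {
    reasons <- c(reasons, sprintf("gap > %g h (largest gap %.2f h)",
                                  max_gap, max_gap_hours))
  }
  list(eligible = length(reasons) == 0L, reasons = reasons,
       span_days = span_days, max_gap_hours = max_gap_hours)
}

#' Bin a tag series into the bivariate observation series
#'
#' Divides the record into contiguous `bin_hours`-hour periods anchored at
#' 00:00 UTC of the release day and computes, per bin, the sample standard
#' deviation of depth (diving amplitude, m) and the mean ambient water
#' temperature (thermal habitat, deg C). Bins with fewer than 2 samples, or
#' with fewer than `coverage_floor` of the expected samples, are marked
#' invalid but kept so the grid stays contiguous; the HMM treats them as
#' missing observations.
#'
#' @param series A [tag_series()].
#' @param bin_hours Bin width in hours (default 3).
#' @param coverage_floor Minimum fraction of expected samples per bin
#'   (default 0.5). Expected count is `bin_hours` over the median sampling
#'   interval.
#' @param anchor Optional `POSIXct` overriding the default grid anchor
#'   (midnight UTC of the release day).
#' @return A `data.frame` of class `binned_series` with columns `fish_id`,
#'   `bin` (index on the anchored grid), `bin_start`, `depth_sd`,
#'   `temp_mean`, `n_samples`, `valid`, and attributes `bin_hours`, `anchor`
#'   and `meta` (deployment metadata carried forward).
#' @examples
#' sc <- sim_scenario(n_fish = 1, deployment_days = c(35, 35))
#' fish <- simulate_fish(sc, 1)
#' b <- bin_series(fish$series)
#' head(b)
#' @export
bin_series <- function(series, bin_hours = 3, coverage_floor = 0.5,
                       anchor = NULL) {
  stopifnot(inherits(series, "tag_series"), bin_hours > 0)
  s <- series$samples
  if (is.null(anchor)) {
    anchor <- as.POSIXct(trunc(series$release_time, units = "days"))
  }
  secs <- as.numeric(s$timestamp) - as.numeric(anchor)
  idx <- floor(secs / (bin_hours * 3600))
  grid <- seq.int(min(idx), max(idx))
  f <- factor(idx, levels = grid)
  n_samples <- as.integer(table(f))
  depth_sd <- as.numeric(tapply(s$depth, f, function(x)
    if (length(x) >= 2L) sd(x) else NA_real_))
  temp_mean <- as.numeric(tapply(s$ambient_temp, f, mean))
  med_int <- if (nrow(s) > 1L) median(diff(as.numeric(s$timestamp))) else
    bin_hours * 3600
  expected <- bin_hours * 3600 / med_int
  valid <- n_samples >= 2L & n_samples >= coverage_floor * expected &
    !is.na(depth_sd) & !is.na(temp_mean)
  out <- data.frame(
    fish_id = series$fish_id,
    bin = grid,
    bin_start = anchor + grid * bin_hours * 3600,
    depth_sd = depth_sd,
    temp_mean = temp_mean,
    n_samples = n_samples,
    valid = valid)
  attr(out, "bin_hours") <- bin_hours
  attr(out, "anchor") <- anchor
  attr(out, "meta") <- list(
    fish_id = series$fish_id, species = series$species,
    fork_length = series$fork_length,
    release_time = series$release_time,
    recapture_time = series$recapture_time,
    release_school = series$release_school,
    recapture_set = series$recapture_set,
    truncated = series$truncated)
  class(out) <- c("binned_series", "data.frame")
  out
}

#' Write a binned series as tidy CSV
#' @param binned A [bin_series()] result.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_binned_series <- function(binned, path) {
  out <- as.data.frame(binned)
  out$bin_start <- .format_utc(out$bin_start)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
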