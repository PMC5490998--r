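## Surface-association probability, event extraction and per-fish summary
## metrics.

#' Surface-association probability series
#'
#' Running mean of the smoothed shallow-state probability across
#' `window_bins` bins (24 h with the defaults). With the default trailing
#' alignment the window ends at the current bin, so a period of
#' surface-association is declared only after a full day of accumulated
#' shallow behaviour; the first `window_bins - 1` bins are undefined (`NA`).
#' Under sustained diel switching (12 h shallow / 12 h deep) the running
#' mean sits at 0.5; sustained shallow occupancy drives it towards 1.
#'
#' @param posteriors A [smooth_posteriors()] result (or any data.frame with
#'   `p_shallow` on a contiguous bin grid).
#' @param window_bins Window length in bins (default 8).
#' @param align `"trailing"` (default) or `"centered"` (window centred on
#'   the current bin, shifted left by `floor(window_bins / 2)` bins).
#' @return A `data.frame` of class `sa_series` with columns `fish_id`,
#'   `bin`, `bin_start`, `p_shallow`, `sa`.
#' @export
surface_association <- function(posteriors, window_bins = 8,
                                align = c("trailing", "centered")) {
  align <- match.arg(align)
  stopifnot(window_bins >= 1)
  p <- posteriors$p_shallow
  if (length(p) < window_bins) {
    stop(sprintf("series of %d bins is shorter than the %d-bin window",
                 length(p), window_bins))
  }
  sa <- as.numeric(stats::filter(p, rep(1 / window_bins, window_bins),
                                 sides = 1))
  if (align == "centered") {
    shift <- floor(window_bins / 2)
    sa <- c(sa[-seq_len(shift)], rep(NA_real_, shift))
  }
  out <- data.frame(
    fish_id = posteriors$fish_id,
    bin = posteriors$bin,
    bin_start = posteriors$bin_start,
    p_shallow = p,
    sa = sa)
  attr(out, "bin_hours") <- attr(posteriors, "bin_hours")
  attr(out, "window_bins") <- window_bins
  attr(out, "align") <- align
  attr(out, "meta") <- attr(posteriors, "meta")
  class(out) <- c("sa_series", "data.frame")
  out
}

#' Extract surface-association events
#'
#' An event is a maximal run of consecutive bins whose surface-association
#' probability strictly exceeds `threshold` (ties at the threshold do not
#' count). Runs shorter than `min_bins` are discarded. Undefined (`NA`)
#' leading bins never belong to events.
#'
#' @param sa A [surface_association()] series.
#' @param threshold Event threshold (default 0.75).
#' @param min_bins Minimum run length in bins (default 1).
#' @return A `data.frame` with one row per event: `fish_id`, `start_bin`,
#'   `end_bin` (inclusive, grid indices), `start_time`, `end_time`,
#'   `n_bins`, `duration_days`, `is_release_event` (starts within 24 h of
#'   release) and `is_recapture_event` (overlaps the final 24 h before
#'   recapture; `NA` for truncated series).
#' @export
detect_events <- function(sa, threshold = 0.75, min_bins = 1) {
  stopifnot(inherits(sa, "data.frame"), !is.null(sa$sa))
  bh <- attr(sa, "bin_hours") %||% 3
  meta <- attr(sa, "meta")
  above <- !is.na(sa$sa) & sa$sa > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_bins
  starts <- starts[keep]; ends <- ends[keep]
  start_time <- sa$bin_start[starts]
  end_time <- sa$bin_start[ends] + bh * 3600
  n_bins <- ends - starts + 1L
  is_release <- rep(NA, length(starts))
  is_recapture <- rep(NA, length(starts))
  if (!is.null(meta)) {
    if (!is.na(meta$release_time)) {
      is_release <- as.numeric(difftime(start_time, meta$release_time,
                                        units = "hours")) <= 24
    }
    if (!isTRUE(meta$truncated) && !is.na(meta$recapture_time)) {
      is_recapture <- as.numeric(difftime(meta$recapture_time, end_time,
                                          units = "hours")) < 24
    }
  }
  out <- data.frame(
    fish_id = rep(sa$fish_id[1L] %||% NA_character_, length(starts)),
    start_bin = sa$bin[starts], end_bin = sa$bin[ends],
    start_time = start_time, end_time = end_time,
    n_bins = n_bins,
    duration_days = n_bins * bh / 24,
    is_release_event = is_release,
    is_recapture_event = is_recapture)
  if (length(starts)) out$fish_id <- sa$fish_id[starts]
  out
}

#' Proportion of the series surface-associated across thresholds
#'
#' Computes, for each threshold in `seq(lo, hi, step)`, the proportion of
#' defined running-mean bins that fall inside events at that threshold.
#' Because the set of above-threshold bins can only shrink as the threshold
#' rises, the proportions are non-increasing.
#'
#' @inheritParams detect_events
#' @param lo,hi,step Sweep range (defaults 0.01 to 0.99 by 0.02).
#' @return A `data.frame` with columns `fish_id`, `threshold`, `proportion`.
#' @export
threshold_sweep <- function(sa, lo = 0.01, hi = 0.99, step = 0.02,
                            min_bins = 1) {
  if (lo >= hi) stop("`lo` must be smaller than `hi`")
  thresholds <- seq(lo, hi, by = step)
  v <- sa$sa[!is.na(sa$sa)]
  if (!length(v)) stop("no defined surface-association bins")
  prop <- vapply(thresholds, function(th) {
    above <- v > th
    if (min_bins > 1L) {
      r <- rle(above)
      r$values <- r$values & r$lengths >= min_bins
      above <- inverse.rle(r)
    }
    mean(above)
  }, numeric(1))
  data.frame(fish_id = sa$fish_id[1L], threshold = thresholds,
             proportion = prop)
}

#' Per-fish surface-association summary metrics
#'
#' Computes the summary metrics reported per individual: mean
#' surface-association probability at the start (first defined window-day),
#' end and over the whole series; the proportion of the (defined) series in
#' events, with and without release events; event counts, durations and
#' events per month-at-liberty; the mean probability over the final 24 h
#' and over each day of the final week at liberty. Recapture-window metrics
#' are `NA` for truncated series.
#'
#' @param events A [detect_events()] result for the fish.
#' @param sa The matching [surface_association()] series.
#' @param month_days Days per month-at-liberty (default 30.4375).
#' @return A one-row `data.frame` (see column names in the value).
#' @export
summarize_fish <- function(events, sa, month_days = 30.4375) {
  meta <- attr(sa, "meta")
  if (is.null(meta)) stop("sa series carries no deployment metadata")
  bh <- attr(sa, "bin_hours") %||% 3
  w <- attr(sa, "window_bins") %||% 8
  truncated <- isTRUE(meta$truncated)
  if (!truncated && is.na(meta$recapture_time)) {
    stop("missing recapture time on a non-truncated series")
  }
  end_time <- if (!is.na(meta$recapture_time)) meta$recapture_time else
    sa$bin_start[nrow(sa)] + bh * 3600
  days_at_liberty <- as.numeric(difftime(end_time, meta$release_time,
                                         units = "days"))
  def <- which(!is.na(sa$sa))
  n_def <- length(def)
  sa_def <- sa$sa[def]
  first_day <- sa_def[seq_len(min(w, n_def))]
  last_day <- sa_def[seq.int(max(1L, n_def - w + 1L), n_def)]
  ev_bins <- sum(events$n_bins)
  ev_bins_nr <- sum(events$n_bins[!(events$is_release_event %in% TRUE)])
  release_events <- events[events$is_release_event %in% TRUE, , drop = FALSE]

  final_block <- function(hours_back_hi, hours_back_lo) {
    if (truncated) return(NA_real_)
    t0 <- end_time - hours_back_hi * 3600
    t1 <- end_time - hours_back_lo * 3600
    sel <- !is.na(sa$sa) & sa$bin_start >= t0 & sa$bin_start < t1
    if (!any(sel)) return(NA_real_)
    mean(sa$sa[sel])
  }
  fw <- vapply(7:1, function(k) final_block(24 * k, 24 * (k - 1)),
               numeric(1))

  out <- data.frame(
    fish_id = meta$fish_id, species = meta$species,
    fork_length = meta$fork_length,
    truncated = truncated,
    days_at_liberty = days_at_liberty,
    n_bins_defined = n_def,
    sa_mean_start = mean(first_day),
    sa_mean_end = if (truncated) NA_real_ else mean(last_day),
    sa_mean_overall = mean(sa_def),
    prop_surface = ev_bins / n_def,
    prop_surface_excl_release = ev_bins_nr / n_def,
    n_events = nrow(events),
    events_per_month = nrow(events) / (days_at_liberty / month_days),
    first_event_days = if (nrow(events)) events$duration_days[1L] else
      NA_real_,
    last_event_days = if (nrow(events))
      events$duration_days[nrow(events)] else NA_real_,
    mean_event_days = if (nrow(events)) mean(events$duration_days) else
      NA_real_,
    median_event_days = if (nrow(events)) median(events$duration_days) else
      NA_real_,
    max_event_days = if (nrow(events)) max(events$duration_days) else
      NA_real_,
    release_event = nrow(release_events) > 0,
    release_event_days = if (nrow(release_events))
      release_events$duration_days[1L] else NA_real_,
    final24_sa_mean = final_block(24, 0))
  for (k in 1:7) out[[paste0("final_week_day", k)]] <- fw[k]
  out
}

#' Flag unusually long events (1.5 IQR rule)
#'
#' An event is an outlier when its duration exceeds Q3 + 1.5 IQR of the
#' cohort's event durations (quartiles by linear interpolation,
#' `quantile(type = 7)`). With fewer than 4 events the rule is undefined
#' and all flags are `NA` (with a warning).
#'
#' @param events Cohort-level events table (rows from [detect_events()]
#'   across fish, with `fish_id`, `duration_days`, `is_release_event`).
#' @param exclude_release If `TRUE`, release events are excluded from the
#'   quartile computation and from the flags/fraction (their flag is `NA`).
#' @return A list: `events` (input with an `is_outlier` column), `cutoff`,
#'   `outlier_fraction`, `n_outliers`, `n_events_used` and `n_fish`
#'   (number of fish contributing at least one outlier).
#' @export
flag_outliers <- function(events, exclude_release = FALSE) {
  use <- rep(TRUE, nrow(events))
  if (exclude_release) use <- !(events$is_release_event %in% TRUE)
  dur <- events$duration_days[use]
  events$is_outlier <- NA
  if (length(dur) < 4L) {
    warning("fewer than 4 events; outlier rule undefined")
    return(list(events = events, cutoff = NA_real_,
                outlier_fraction = NA_real_, n_outliers = NA_integer_,
                n_events_used = length(dur), n_fish = NA_integer_))
  }
  q <- quantile(dur, c(0.25, 0.75), type = 7, names = FALSE)
  cutoff <- q[2] + 1.5 * (q[2] - q[1])
  flag <- events$duration_days > cutoff
  flag[!use] <- NA
  events$is_outlier <- flag
  list(events = events,
       cutoff = cutoff,
       outlier_fraction = mean(flag[use]),
       n_outliers = sum(flag[use]),
       n_events_used = length(dur),
       n_fish = length(unique(events$fish_id[which(flag)])))
}
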