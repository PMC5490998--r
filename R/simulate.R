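## Synthetic tag-data generator. Emulates the statistical structure the
## analysis assumes -- diel vertical switching, sustained surface-association
## bouts, thermal stratification, data gaps, geolocation error ellipses --
## and retains full generator truth (per-bin states, bout schedule, the
## induced event schedule) for oracle tests.

#' Simulation scenario
#'
#' Parameters of the synthetic cohort. Defaults emulate the scale of
#' summaries reported for juvenile bigeye/yellowfin archival tag records:
#' warm-shallow state near 28 deg C with low diving amplitude, deep-cold
#' state near 18 deg C with high amplitude, surface-association bouts with
#' a median near 2 days at roughly 2.5 per month, and a frequent multi-day
#' post-release bout. These are emulation choices, not claims about any
#' real archive.
#'
#' @param n_fish Number of fish (default 10).
#' @param species_mix Named probabilities over species at release.
#' @param deployment_days Range (days) deployments are drawn from,
#'   uniformly, rounded to whole days.
#' @param interval_s Sampling interval in seconds (default 60).
#' @param shallow,deep Per-state emission parameters: `depth_mean` (m),
#'   `amp_mean`/`amp_sd` (between-bin diving amplitude, m),
#'   `temp_mean`/`temp_sd` (deg C).
#' @param state_corr Within-state correlation between diving amplitude and
#'   thermal habitat (default 0).
#' @param within_bin_temp_sd SD of mean-centred within-bin temperature
#'   jitter (deg C).
#' @param bouts Surface-association bout process: `rate_per_month`,
#'   log-normal duration `meanlog`/`sdlog` (days), `min_days`,
#'   `max_days`, `min_gap_days` between bouts. An optional element
#'   `fixed` (`data.frame` with `start_day`, `duration_days`) replaces the
#'   random schedule with an exact one (bouts starting before day 1 count
#'   as release bouts) -- the hook ground-truth tests use.
#' @param release_bout Post-release bout: `prob` of occurrence, normal
#'   duration `mean_days`/`sd_days`, truncated to `min_days`..`max_days`.
#' @param truncated_prob Probability a record is truncated (last
#'   `truncate_days` days lost to tag malfunction).
#' @param truncate_days Days removed from truncated records.
#' @param gaps Gap injection: `n` gaps of `hours` hours each (default
#'   none).
#' @param track Geolocation process: `step_sd` (deg per 8-h step of the
#'   bounded random walk), `ci_lon`/`ci_lat` (full 95% CI widths, deg;
#'   latitudinal error larger by default, as for equatorial light-based
#'   geolocation), `lon0`/`lat0` (release region).
#' @param t0 Release time of the first fish (UTC).
#' @param seed Master seed; per-fish streams are derived from it.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_fish = 10,
                         species_mix = c(bigeye = 0.5, yellowfin = 0.5),
                         deployment_days = c(45, 90),
                         interval_s = 60,
                         shallow = list(depth_mean = 25, amp_mean = 5,
                                        amp_sd = 1.5, temp_mean = 28,
                                        temp_sd = 0.5),
                         deep = list(depth_mean = 180, amp_mean = 40,
                                     amp_sd = 8, temp_mean = 18,
                                     temp_sd = 1),
                         state_corr = 0,
                         within_bin_temp_sd = 0.2,
                         bouts = list(rate_per_month = 2.5,
                                      meanlog = log(2), sdlog = 0.6,
                                      min_days = 1, max_days = 21,
                                      min_gap_days = 2),
                         release_bout = list(prob = 0.6, mean_days = 8,
                                             sd_days = 4, min_days = 1.5,
                                             max_days = 20),
                         truncated_prob = 0, truncate_days = 3,
                         gaps = list(n = 0, hours = 0.5),
                         track = list(step_sd = 0.12, ci_lon = 0.5,
                                      ci_lat = 1.5, lon0 = 152,
                                      lat0 = -4),
                         t0 = "2008-03-01T08:30:00",
                         seed = 1L) {
  sc <- list(n_fish = n_fish, species_mix = species_mix,
             deployment_days = deployment_days, interval_s = interval_s,
             shallow = shallow, deep = deep, state_corr = state_corr,
             within_bin_temp_sd = within_bin_temp_sd,
             bouts = bouts, release_bout = release_bout,
             truncated_prob = truncated_prob,
             truncate_days = truncate_days,
             gaps = gaps, track = track,
             t0 = .parse_utc(t0), seed = as.integer(seed))
  stopifnot(sc$n_fish >= 1, sc$interval_s >= 1,
            sc$deployment_days[1] <= sc$deployment_days[2],
            sc$bouts$min_days > 0, sc$release_bout$min_days > 0)
  class(sc) <- "sim_scenario"
  sc
}

.fish_seed <- function(scenario, fish_index, salt = 0L) {
  (scenario$seed + 104729L * as.integer(fish_index) + salt) %% 2147483647L
}

## induced event schedule from a 0/1 state sequence: trailing running mean
## by cumulative sums, strict threshold, maximal runs. Kept free of the
## events module so it can serve as its oracle.
.truth_events <- function(p_true, bins, bin_starts, window = 8,
                          threshold = 0.75, bin_hours = 3) {
  T_ <- length(p_true)
  sa <- rep(NA_real_, T_)
  if (T_ >= window) {
    cs <- c(0, cumsum(p_true))
    t <- window:T_
    sa[t] <- (cs[t + 1] - cs[t + 1 - window]) / window
  }
  above <- !is.na(sa) & sa > threshold
  ev <- list(); s <- NA_integer_
  for (t in seq_len(T_)) {
    if (above[t] && is.na(s)) s <- t
    if (!above[t] && !is.na(s)) { ev[[length(ev) + 1L]] <- c(s, t - 1L)
                                  s <- NA_integer_ }
  }
  if (!is.na(s)) ev[[length(ev) + 1L]] <- c(s, T_)
  if (!length(ev)) {
    return(data.frame(start_bin = integer(0), end_bin = integer(0),
                      n_bins = integer(0), duration_days = numeric(0)))
  }
  m <- do.call(rbind, ev)
  data.frame(start_bin = bins[m[, 1]], end_bin = bins[m[, 2]],
             n_bins = m[, 2] - m[, 1] + 1L,
             duration_days = (m[, 2] - m[, 1] + 1L) * bin_hours / 24)
}

#' Simulate one tagged fish
#'
#' Builds a per-bin true behavioural schedule -- diel switching (deep
#' 06:00-18:00 UTC, shallow otherwise) overlaid with surface-association
#' bouts that hold the shallow state continuously, optionally starting with
#' a post-release bout -- then emits depth/temperature samples at the
#' scenario's interval. Within each 3-h bin the sample SD of depth equals
#' the bin's drawn diving amplitude and the mean temperature equals the
#' bin's drawn thermal habitat exactly, so binned observations follow the
#' scenario's state distributions by construction.
#'
#' @param scenario A [sim_scenario()].
#' @param fish_index Positive integer; also offsets the release date.
#' @param seed Optional override of the derived per-fish seed.
#' @return A list with `series` (a [tag_series()]) and `truth` (per-bin
#'   states, bout schedule, induced event schedule, emission parameters).
#' @export
simulate_fish <- function(scenario, fish_index = 1,
                          seed = .fish_seed(scenario, fish_index)) {
  stopifnot(inherits(scenario, "sim_scenario"))
  withr::with_seed(seed, .simulate_fish_impl(scenario, fish_index))
}

.simulate_fish_impl <- function(scenario, fish_index) {
  sc <- scenario
  days <- round(runif(1, sc$deployment_days[1], sc$deployment_days[2]))
  release <- sc$t0 + (fish_index - 1) * 86400 +
    round(runif(1, 0, 6)) * 3600
  recapture <- release + days * 86400
  anchor <- as.POSIXct(trunc(release, units = "days"))
  bin_len <- 3 * 3600

  first_bin <- floor((as.numeric(release) - as.numeric(anchor)) / bin_len)
  last_bin <- floor((as.numeric(recapture) - 1 - as.numeric(anchor)) /
                      bin_len)
  bins <- seq.int(first_bin, last_bin)
  bin_starts <- anchor + bins * bin_len
  slot <- bins %% 8                      # 3-h slot of day; anchor = midnight
  state <- ifelse(slot %in% c(2, 3, 4, 5), "deep", "shallow")  # 06:00-18:00

  ## bout schedule, in days since release
  bout_iv <- list()                       # list of c(start_day, end_day)
  is_release_bout <- logical(0)
  if (!is.null(sc$bouts$fixed)) {
    fx <- sc$bouts$fixed
    for (k in seq_len(nrow(fx))) {
      bout_iv[[k]] <- c(fx$start_day[k], fx$start_day[k] +
                          fx$duration_days[k])
      is_release_bout <- c(is_release_bout, fx$start_day[k] < 1)
    }
  } else if (runif(1) < sc$release_bout$prob) {
    d <- min(max(rnorm(1, sc$release_bout$mean_days,
                       sc$release_bout$sd_days),
                 sc$release_bout$min_days), sc$release_bout$max_days)
    d <- min(d, days - 2)
    bout_iv[[1]] <- c(0, d)
    is_release_bout <- TRUE
  }
  n_bouts <- if (!is.null(sc$bouts$fixed)) 0L else
    rpois(1, sc$bouts$rate_per_month * days / 30.4375)
  for (k in seq_len(n_bouts)) {
    for (try in 1:50) {
      d <- min(max(rlnorm(1, sc$bouts$meanlog, sc$bouts$sdlog),
                   sc$bouts$min_days), sc$bouts$max_days)
      s <- runif(1, 1, days - d - 1)
      if (s <= 0 || s + d >= days) next
      gap_ok <- all(vapply(bout_iv, function(iv)
        s >= iv[2] + sc$bouts$min_gap_days ||
          s + d <= iv[1] - sc$bouts$min_gap_days, logical(1)))
      if (gap_ok) {
        bout_iv[[length(bout_iv) + 1L]] <- c(s, s + d)
        is_release_bout <- c(is_release_bout, FALSE)
        break
      }
    }
  }
  ## mark bout bins shallow (bin belongs to a bout when its start lies
  ## inside the bout interval)
  day_of_bin <- (as.numeric(bin_starts) - as.numeric(release)) / 86400
  for (iv in bout_iv) {
    state[day_of_bin >= iv[1] - 1e-9 & day_of_bin < iv[2] - 1e-9] <-
      "shallow"
  }

  ## per-bin emission draws (between-bin variation)
  T_ <- length(bins)
  par <- list(shallow = sc$shallow, deep = sc$deep)
  z1 <- rnorm(T_); z2 <- rnorm(T_)
  z2 <- sc$state_corr * z1 + sqrt(1 - sc$state_corr^2) * z2
  amp <- numeric(T_); tmp <- numeric(T_); dmean <- numeric(T_)
  for (stt in c("shallow", "deep")) {
    i <- state == stt
    amp[i] <- pmax(par[[stt]]$amp_mean + par[[stt]]$amp_sd * z1[i], 0.2)
    tmp[i] <- par[[stt]]$temp_mean + par[[stt]]$temp_sd * z2[i]
    dmean[i] <- par[[stt]]$depth_mean
  }

  ## raw samples: depth shaped to the exact per-bin amplitude, temperature
  ## jitter mean-centred so the bin mean is exact
  ts <- seq(as.numeric(release), as.numeric(recapture), by = sc$interval_s)
  samp_bin <- floor((ts - as.numeric(anchor)) / bin_len)
  bi <- match(samp_bin, bins)
  depth <- numeric(length(ts)); temp <- numeric(length(ts))
  for (b in seq_len(T_)) {
    j <- which(bi == b)
    n <- length(j)
    if (!n) next
    if (n >= 2) {
      z <- rnorm(n)
      z <- (z - mean(z)) / sd(z)        # exact mean 0, sample SD 1
    } else z <- 0
    depth[j] <- pmax(dmean[b] + amp[b] * z, 0)
    jit <- if (n >= 2) rnorm(n, 0, sc$within_bin_temp_sd) else 0
    temp[j] <- tmp[b] + jit - mean(jit)
  }

  ## optional gap injection and truncation
  keep <- rep(TRUE, length(ts))
  if (sc$gaps$n > 0) {
    for (k in seq_len(sc$gaps$n)) {
      g0 <- runif(1, 0.05, 0.9) * days * 86400 + as.numeric(release)
      keep[ts > g0 & ts <= g0 + sc$gaps$hours * 3600] <- FALSE
    }
  }
  truncated <- runif(1) < sc$truncated_prob
  if (truncated) {
    keep[ts > as.numeric(recapture) - sc$truncate_days * 86400] <- FALSE
  }

  species <- sample(names(sc$species_mix), 1, prob = sc$species_mix)
  series <- tag_series(
    fish_id = sprintf("SIM%03d", fish_index),
    species = species,
    fork_length = round(min(max(rnorm(1, 71, 13), 45), 110), 1),
    release_time = release, recapture_time = recapture,
    release_school = sample(c("FAD", "free", "log", "seamount"), 1,
                            prob = c(0.6, 0.2, 0.1, 0.1)),
    recapture_set = sample(c("FAD", "free", "log", "unknown"), 1,
                           prob = c(0.45, 0.1, 0.1, 0.35)),
    samples = data.frame(
      timestamp = as.POSIXct(ts[keep], origin = "1970-01-01", tz = "UTC"),
      depth = depth[keep], ambient_temp = temp[keep]),
    truncated = truncated)

  p_true <- as.numeric(state == "shallow")
  bouts_df <- if (length(bout_iv)) {
    data.frame(start_day = vapply(bout_iv, `[[`, numeric(1), 1L),
               end_day = vapply(bout_iv, `[[`, numeric(1), 2L),
               duration_days = vapply(bout_iv, function(iv) iv[2] - iv[1],
                                      numeric(1)),
               is_release = is_release_bout)
  } else {
    data.frame(start_day = numeric(0), end_day = numeric(0),
               duration_days = numeric(0), is_release = logical(0))
  }
  truth <- list(
    fish_id = series$fish_id,
    bins = bins, bin_starts = bin_starts, state = state,
    p_true = p_true,
    bouts = bouts_df,
    events = .truth_events(p_true, bins, bin_starts),
    emission = par, days = days, truncated = truncated)
  list(series = series, truth = truth)
}

#' Simulate a geolocation track for a fish
#'
#' Three light-based position estimates per deployment day (every 8 h)
#' from a bounded random walk starting at the scenario's release region,
#' with fixed axis-aligned 95% CI widths (`ci_lat` > `ci_lon` by default,
#' mirroring the large latitudinal error of equatorial light geolocation).
#'
#' @param scenario A [sim_scenario()].
#' @param fish_index Fish index (release offset and seed).
#' @param series The fish's [tag_series()] (deployment window).
#' @param seed Optional seed override.
#' @return A track `data.frame` (`fish_id`, `time`, `lon`, `lat`,
#'   `ci_lon`, `ci_lat`).
#' @export
simulate_track <- function(scenario, fish_index, series,
                           seed = .fish_seed(scenario, fish_index, 17L)) {
  stopifnot(inherits(scenario, "sim_scenario"))
  withr::with_seed(seed, {
    tr <- scenario$track
    rel <- series$release_time
    rec <- series$recapture_time
    days <- floor(as.numeric(difftime(rec, rel, units = "days")))
    times <- rel + 4 * 3600 + 8 * 3600 * (0:(3 * days - 1))
    times <- times[times <= rec]
    n <- length(times)
    lon0 <- tr$lon0 + 0.3 * (fish_index - 1)
    lat0 <- tr$lat0
    lon <- lon0 + cumsum(rnorm(n, 0, tr$step_sd))
    lat <- lat0 + cumsum(rnorm(n, 0, tr$step_sd))
    lat <- pmin(pmax(lat, lat0 - 5), lat0 + 5)
    data.frame(fish_id = series$fish_id, time = times,
               lon = lon, lat = lat,
               ci_lon = tr$ci_lon, ci_lat = tr$ci_lat)
  })
}

#' Simulate a cohort of tagged fish
#'
#' @param scenario A [sim_scenario()].
#' @param out_dir Optional directory; when given, per-fish sample CSVs, a
#'   `metadata.csv`, a `tracks.csv` and a `truth.json` bundle are written
#'   there.
#' @param tracks Whether to simulate geolocation tracks (default `TRUE`).
#' @return Invisibly, a list with `fish` (list of
#'   [simulate_fish()] results) and `tracks` (list of track data frames,
#'   or `NULL`).
#' @export
simulate_cohort <- function(scenario, out_dir = NULL, tracks = TRUE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  fish <- lapply(seq_len(scenario$n_fish), function(i)
    simulate_fish(scenario, i))
  trks <- if (tracks) {
    lapply(seq_len(scenario$n_fish), function(i)
      simulate_track(scenario, i, fish[[i]]$series))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    meta_path <- file.path(out_dir, "metadata.csv")
    if (file.exists(meta_path)) file.remove(meta_path)
    for (f in fish) {
      write_tag_series(f$series,
                       file.path(out_dir,
                                 paste0(f$series$fish_id, ".csv")),
                       meta_path)
    }
    if (!is.null(trks)) {
      write_geo_track(do.call(rbind, trks), file.path(out_dir,
                                                      "tracks.csv"))
    }
    truth <- lapply(fish, function(f) {
      tr <- f$truth
      list(fish_id = tr$fish_id, days = tr$days,
           truncated = tr$truncated,
           bouts = tr$bouts, events = tr$events,
           state = tr$state, bins = tr$bins)
    })
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         digits = NA, auto_unbox = TRUE,
                         dataframe = "columns")
  }
  invisible(list(fish = fish, tracks = trks))
}

#' Simulate a binned series directly from a two-state HMM
#'
#' Draws a state sequence from the Markov chain and bivariate-normal
#' emissions per bin -- the generative model [fit_hmm()] assumes -- for
#' parameter-recovery studies at the bin level (no raw samples involved).
#'
#' @param means 2 x 2 matrix of state means (columns `depth_sd`,
#'   `temp_mean`).
#' @param sigma List of two 2 x 2 covariance matrices.
#' @param tpm 2 x 2 transition matrix (rows sum to 1).
#' @param delta Initial state distribution (default stationary-ish
#'   `c(0.5, 0.5)`).
#' @param n_bins Number of bins.
#' @param seed Optional seed.
#' @return A list with `binned` (a `binned_series` usable by [fit_hmm()])
#'   and `states` (the true state sequence).
#' @export
simulate_hmm_bins <- function(means, sigma, tpm, delta = c(0.5, 0.5),
                              n_bins, seed = NULL) {
  run <- function() {
    states <- integer(n_bins)
    states[1] <- sample(1:2, 1, prob = delta)
    for (t in 2:n_bins) {
      states[t] <- sample(1:2, 1, prob = tpm[states[t - 1], ])
    }
    X <- matrix(0, n_bins, 2)
    ch <- lapply(sigma, chol)
    for (k in 1:2) {
      i <- states == k
      n <- sum(i)
      if (n) {
        X[i, ] <- matrix(rnorm(2 * n), n, 2) %*% ch[[k]] +
          matrix(means[k, ], n, 2, byrow = TRUE)
      }
    }
    anchor <- .parse_utc("2008-01-01T00:00:00")
    out <- data.frame(
      fish_id = "HMMSIM", bin = seq_len(n_bins) - 1L,
      bin_start = anchor + (seq_len(n_bins) - 1L) * 10800,
      depth_sd = pmax(X[, 1], 0), temp_mean = X[, 2],
      n_samples = 180L, valid = TRUE)
    attr(out, "bin_hours") <- 3
    attr(out, "anchor") <- anchor
    attr(out, "meta") <- list(fish_id = "HMMSIM", species = "other",
                              fork_length = NA_real_,
                              release_time = anchor,
                              recapture_time = anchor + n_bins * 10800,
                              release_school = "unknown",
                              recapture_set = "unknown", truncated = FALSE)
    class(out) <- c("binned_series", "data.frame")
    list(binned = out, states = states)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
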