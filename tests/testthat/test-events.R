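# Surface-association series, events, sweep, summaries, outliers, dip test.

test_that("pure diel switching gives exactly 0.5 and no events", {
  p <- rep(c(rep(1, 4), rep(0, 4)), 20)   # 12 h shallow / 12 h deep
  sa <- surface_association(make_posteriors(p))
  expect_true(all(is.na(sa$sa[1:7])))
  expect_equal(sa$sa[-(1:7)], rep(0.5, length(p) - 7))
  expect_identical(nrow(detect_events(sa, 0.75)), 0L)
})

test_that("constant shallow posterior gives sa identically 1", {
  sa <- surface_association(make_posteriors(rep(1, 40)))
  expect_equal(sa$sa[-(1:7)], rep(1, 33))
})

test_that("running mean matches an explicit sliding-window oracle", {
  set.seed(3)
  for (w in c(3, 8)) {
    p <- runif(200)
    sa <- surface_association(make_posteriors(p), window_bins = w)
    expect_lt(max(abs(sa$sa - oracle_sliding_mean(p, w)), na.rm = TRUE),
              1e-12)
    expect_identical(which(is.na(sa$sa)), seq_len(w - 1L))
  }
})

test_that("series shorter than the window is refused", {
  expect_error(surface_association(make_posteriors(rep(1, 5)),
                                   window_bins = 8), "shorter")
})

test_that("event extraction equals a brute-force linear scan", {
  set.seed(4)
  for (rep_ in 1:50) {
    v <- c(rep(NA, 7), runif(150))
    v[sample(8:157, 20)] <- 0.75          # plant exact-threshold ties
    sa <- make_sa(v)
    ev <- detect_events(sa, 0.75)
    want <- oracle_scan_events(v, 0.75)
    expect_identical(nrow(ev), nrow(want))
    if (nrow(want)) {
      expect_equal(ev$start_bin, sa$bin[want[, 1]])
      expect_equal(ev$end_bin, sa$bin[want[, 2]])
      expect_equal(ev$duration_days, (want[, 2] - want[, 1] + 1) * 3 / 24)
    }
  }
  # min-run filtering agrees too
  v <- c(rep(NA, 7), rep(c(0.9, 0.2), 20), rep(0.9, 5), 0.2)
  ev <- detect_events(make_sa(v), 0.75, min_bins = 3)
  want <- oracle_scan_events(v, 0.75, min_bins = 3)
  expect_identical(nrow(ev), nrow(want))
  expect_equal(ev$n_bins, as.integer(want[, 2] - want[, 1] + 1))
})

test_that("a day-long run above threshold is one event of one day", {
  v <- c(rep(NA, 7), rep(0.5, 20), rep(0.9, 8), rep(0.5, 20))
  ev <- detect_events(make_sa(v), 0.75)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$duration_days, 1.0)
})

test_that("hard shallow runs of a day or more always produce an event", {
  set.seed(9)
  for (rep_ in 1:20) {
    p <- as.numeric(runif(120) < 0.3)
    s0 <- sample(20:80, 1)
    p[s0:(s0 + sample(8:20, 1))] <- 1     # plant >= 24 h of shallow state
    sa <- surface_association(make_posteriors(p))
    expect_gte(nrow(detect_events(sa, 0.75)), 1L)
  }
})

test_that("threshold sweep is a step function for constant sa", {
  sa <- make_sa(rep(0.5, 60))
  sw <- threshold_sweep(sa)
  expect_equal(sw$proportion[sw$threshold < 0.5], rep(1, 25))
  expect_equal(sw$proportion[sw$threshold > 0.5], rep(0, 25))
  expect_error(threshold_sweep(sa, lo = 0.9, hi = 0.1), "smaller")
})

test_that("sweep proportions are non-increasing and match event re-runs", {
  set.seed(6)
  for (rep_ in 1:10) {
    v <- c(rep(NA, 7), pmin(pmax(cumsum(rnorm(150, 0, 0.15)) + 0.5, 0), 1))
    sa <- make_sa(v)
    sw <- threshold_sweep(sa)
    expect_true(all(diff(sw$proportion) <= 1e-12))
    n_def <- sum(!is.na(v))
    for (th in sw$threshold[c(1, 13, 25, 38, 50)]) {
      ev <- detect_events(sa, th)
      expect_equal(sw$proportion[abs(sw$threshold - th) < 1e-9],
                   sum(ev$n_bins) / n_def)
    }
  }
})

test_that("summary arithmetic: proportions and event rates", {
  # 20-day series, fully defined sa, one 2-day event -> proportion 0.1
  v <- rep(0.3, 160)
  v[41:56] <- 0.9                         # 16 bins = 2 days
  sa <- make_sa(v, recapture = as.POSIXct("2008-01-01", tz = "UTC") +
                  160 * 10800)
  ev <- detect_events(sa, 0.75)
  s <- summarize_fish(ev, sa)
  expect_equal(s$prop_surface, 0.1)
  expect_equal(s$n_events, 1L)
  expect_equal(s$first_event_days, 2.0)

  # 3 events over 45.65625 days with month_days 30.4375 -> 2 per month
  T_ <- 45.65625 * 8
  v <- rep(0.3, T_)
  v[c(41:48, 101:108, 201:208)] <- 0.9
  sa <- make_sa(v, recapture = as.POSIXct("2008-01-01", tz = "UTC") +
                  T_ * 10800)
  ev <- detect_events(sa, 0.75)
  s <- summarize_fish(ev, sa)
  expect_identical(s$n_events, 3L)
  expect_equal(s$events_per_month, 2.0, tolerance = 1e-12)
})

test_that("release events and recapture-window metrics behave", {
  # event starting at bin 2 (within 24 h of release), one near recapture
  v <- rep(0.3, 240)
  v[3:30] <- 0.9
  v[233:240] <- 0.9
  sa <- make_sa(v)
  ev <- detect_events(sa, 0.75)
  expect_identical(ev$is_release_event, c(TRUE, FALSE))
  expect_identical(ev$is_recapture_event, c(FALSE, TRUE))
  s <- summarize_fish(ev, sa)
  expect_true(s$release_event)
  expect_equal(s$release_event_days, 28 * 3 / 24)
  expect_equal(s$final24_sa_mean, 0.9)
  expect_equal(s$final_week_day7, 0.9)
  expect_equal(s$final_week_day1, 0.3)

  # truncated series: recapture-window metrics are NA, others present
  sat <- make_sa(v, truncated = TRUE)
  st <- summarize_fish(detect_events(sat, 0.75), sat)
  expect_true(is.na(st$final24_sa_mean))
  expect_true(is.na(st$sa_mean_end))
  expect_false(is.na(st$sa_mean_overall))

  # non-truncated series without recapture time is an error
  sam <- make_sa(v)
  attr(sam, "meta")$recapture_time <- as.POSIXct(NA)
  expect_error(summarize_fish(detect_events(sam, 0.75), sam),
               "recapture")
})

test_that("outlier rule: 1.5 IQR above the upper quartile", {
  ev <- data.frame(fish_id = letters[1:7],
                   duration_days = c(1, 1, 2, 2, 3, 3, 50),
                   is_release_event = FALSE)
  fl <- flag_outliers(ev)
  expect_identical(which(fl$events$is_outlier), 7L)
  expect_equal(fl$outlier_fraction, 1 / 7)
  expect_identical(fl$n_fish, 1L)

  # degenerate spread: nothing flagged
  ev$duration_days <- rep(2, 7)
  expect_identical(sum(flag_outliers(ev)$events$is_outlier), 0L)

  # under 4 events: undefined, with a warning
  expect_warning(fl <- flag_outliers(ev[1:3, ]), "fewer than 4")
  expect_true(is.na(fl$outlier_fraction))
})

test_that("outlier flags match a direct quantile-rule recomputation", {
  set.seed(8)
  dur <- rlnorm(60, log(2), 0.7)
  rel <- seq_along(dur) %in% sample(60, 10)
  ev <- data.frame(fish_id = sample(letters, 60, TRUE),
                   duration_days = dur, is_release_event = rel)
  for (excl in c(FALSE, TRUE)) {
    fl <- flag_outliers(ev, exclude_release = excl)
    use <- if (excl) !rel else rep(TRUE, 60)
    q <- quantile(dur[use], c(0.25, 0.75), type = 7, names = FALSE)
    cut <- q[2] + 1.5 * (q[2] - q[1])
    expect_equal(fl$cutoff, cut)
    expect_identical(fl$events$is_outlier[use], dur[use] > cut)
    if (excl) expect_true(all(is.na(fl$events$is_outlier[rel])))
  }
})

test_that("dip statistic matches frozen independent-oracle values", {
  # expected values computed with a linear-programming formulation of
  # 'closest unimodal cdf' (min-max over convex-then-concave cdfs)
  cases <- list(
    list(x = c(0, 1), dip = 0.25),
    list(x = c(0, 0.01, 0.99, 1), dip = 0.2474747475),
    list(x = seq(0, 1, length.out = 10), dip = 0.05),
    list(x = c(0.1, 0.2, 0.2, 0.7, 0.8, 0.9), dip = 0.1785714286),
    list(x = c(0.05, 0.1, 0.15, 0.2, 0.3, 0.5, 0.8, 1.3), dip = 0.0625),
    list(x = c(0, 0.02, 0.04, 0.5, 0.52, 0.54, 1, 1.02, 1.04),
         dip = 0.1533333333))
  for (cs in cases) {
    expect_equal(dip_stat(cs$x), cs$dip, tolerance = 1e-6)
  }
  expect_equal(dip_stat(rep(3.2, 25)), 0)
  # location/scale invariance
  set.seed(12)
  x <- rnorm(40)
  expect_equal(dip_stat(5 + 2 * x), dip_stat(x), tolerance = 1e-7)
})

test_that("dip test separates bimodal from unimodal samples", {
  set.seed(14)
  bim <- c(rnorm(50, 0, 0.05), rnorm(50, 1, 0.05))
  null100 <- dip_null(100, n_boot = 500, seed = 99)
  res <- dip_test(bim, null_dips = null100)
  expect_lt(res$p_value, 0.05)

  # null calibration: uniform samples give comfortably non-small p
  ps <- vapply(1:50, function(i) {
    withr::with_seed(1000 + i,
                     dip_test(runif(100), null_dips = null100)$p_value)
  }, numeric(1))
  expect_gt(median(ps), 0.2)

  # constant input: dip 0, p 1
  res0 <- dip_test(rep(0.4, 30))
  expect_identical(res0$dip, 0)
  expect_identical(res0$p_value, 1)
})
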