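# Synthetic tag-data generator: determinism, truth retention, recovery.

fast_scenario <- function(...) {
  # 300-second sampling keeps series small while leaving bins well covered
  sim_scenario(interval_s = 300, ...)
}

test_that("a cohort yields one series, truth and track per fish", {
  sc <- fast_scenario(n_fish = 3, deployment_days = c(31, 34), seed = 41)
  coh <- simulate_cohort(sc)
  expect_length(coh$fish, 3)
  expect_length(coh$tracks, 3)
  ids <- vapply(coh$fish, function(f) f$series$fish_id, character(1))
  expect_identical(ids, c("SIM001", "SIM002", "SIM003"))
  for (f in coh$fish) {
    expect_s3_class(f$series, "tag_series")
    expect_identical(length(f$truth$state), length(f$truth$bins))
    expect_true(screen_eligibility(f$series)$eligible)
  }
})

test_that("simulation is reproducible from the seed", {
  sc <- fast_scenario(n_fish = 1, deployment_days = c(31, 31), seed = 42)
  a <- simulate_fish(sc, 1)
  b <- simulate_fish(sc, 1)
  expect_identical(a$series$samples, b$series$samples)
  expect_identical(a$truth$events, b$truth$events)
  ta <- simulate_track(sc, 1, a$series)
  tb <- simulate_track(sc, 1, b$series)
  expect_identical(ta, tb)
})

test_that("tracks: three estimates per day, pinned when the walk is frozen", {
  sc <- fast_scenario(n_fish = 1, deployment_days = c(33, 33), seed = 43,
                      track = list(step_sd = 0, ci_lon = 0.5, ci_lat = 1.5,
                                   lon0 = 152, lat0 = -4))
  f <- simulate_fish(sc, 1)
  trk <- simulate_track(sc, 1, f$series)
  days <- floor(as.numeric(difftime(f$series$recapture_time,
                                    f$series$release_time,
                                    units = "days")))
  expect_identical(nrow(trk), as.integer(3 * days))
  expect_equal(trk$lon, rep(152, nrow(trk)))
  expect_equal(trk$lat, rep(-4, nrow(trk)))
  expect_true(all(trk$ci_lat > trk$ci_lon))
})

test_that("binned emissions reproduce the scheduled state parameters", {
  sc <- fast_scenario(n_fish = 1, deployment_days = c(35, 35), seed = 44)
  f <- simulate_fish(sc, 1)
  b <- bin_series(f$series)
  tr <- f$truth
  common <- intersect(b$bin[b$valid], tr$bins)
  st <- tr$state[match(common, tr$bins)]
  ds <- b$depth_sd[match(common, b$bin)]
  tm <- b$temp_mean[match(common, b$bin)]
  # per-bin amplitude/temperature are drawn from the state distributions
  # and imprinted exactly on the samples
  expect_equal(mean(tm[st == "shallow"]), 28, tolerance = 0.2)
  expect_equal(mean(tm[st == "deep"]), 18, tolerance = 0.4)
  expect_equal(mean(ds[st == "shallow"]), 5, tolerance = 0.5)
  expect_equal(mean(ds[st == "deep"]), 40, tolerance = 2)
  expect_gt(min(tm[st == "shallow"]), max(tm[st == "deep"]))
})

test_that("zero-noise emissions give hard posteriors matching the truth", {
  sc <- fast_scenario(
    n_fish = 1, deployment_days = c(35, 35), seed = 45,
    shallow = list(depth_mean = 25, amp_mean = 5, amp_sd = 0,
                   temp_mean = 28, temp_sd = 0),
    deep = list(depth_mean = 180, amp_mean = 40, amp_sd = 0,
                temp_mean = 18, temp_sd = 0),
    within_bin_temp_sd = 0)
  f <- simulate_fish(sc, 1)
  b <- bin_series(f$series)
  fit <- fit_hmm(b, run_config(em_restarts = 1))
  post <- smooth_posteriors(b, fit)
  common <- intersect(b$bin[b$valid], f$truth$bins)
  p <- post$p_shallow[match(common, post$bin)]
  truth <- as.numeric(f$truth$state[match(common, f$truth$bins)] ==
                        "shallow")
  expect_lt(max(abs(p - truth)), 1e-6)
})

test_that("classification accuracy exceeds 99% under clear separation", {
  sc <- fast_scenario(n_fish = 2, deployment_days = c(40, 60), seed = 46)
  coh <- simulate_cohort(sc, tracks = FALSE)
  for (f in coh$fish) {
    b <- bin_series(f$series)
    fit <- fit_hmm(b, run_config(em_restarts = 2))
    post <- smooth_posteriors(b, fit)
    common <- intersect(b$bin[b$valid], f$truth$bins)
    p <- post$p_shallow[match(common, post$bin)]
    truth <- as.numeric(f$truth$state[match(common, f$truth$bins)] ==
                          "shallow")
    acc <- mean((p > 0.5) == (truth > 0.5))
    expect_gt(acc, 0.99)
  }
})

test_that("a planted 3-day bout is recovered as one clean event", {
  sc <- fast_scenario(
    n_fish = 1, deployment_days = c(35, 35), seed = 47,
    bouts = list(fixed = data.frame(start_day = 15, duration_days = 3)),
    release_bout = list(prob = 0, mean_days = 8, sd_days = 4,
                        min_days = 1.5, max_days = 20))
  f <- simulate_fish(sc, 1)
  b <- bin_series(f$series)
  fit <- fit_hmm(b, run_config(em_restarts = 2))
  sa <- surface_association(smooth_posteriors(b, fit))
  ev <- detect_events(sa, 0.75)
  expect_identical(nrow(ev), 1L)
  expect_false(ev$is_release_event)
  # duration within the trailing-window phase tolerance of the planted bout
  expect_lt(abs(ev$duration_days - 3), 4 * 3 / 24 + 1e-9)
  # and the truth-induced schedule is matched exactly by the events module
  truth_ev <- f$truth$events
  expect_identical(nrow(truth_ev), 1L)
  post_true <- make_posteriors(f$truth$p_true)
  post_true$bin <- f$truth$bins
  post_true$bin_start <- f$truth$bin_starts
  ev_true <- detect_events(surface_association(post_true), 0.75)
  expect_equal(ev_true$start_bin, truth_ev$start_bin)
  expect_equal(ev_true$end_bin, truth_ev$end_bin)
})

test_that("planted bout durations are recovered across seeds", {
  # events detected from fitted posteriors match the truth-induced event
  # schedule to within one bin per boundary, over many generator draws
  for (s in 1:6) {
    sc <- fast_scenario(n_fish = 1, deployment_days = c(35, 45),
                        seed = 400 + s)
    f <- simulate_fish(sc, 1)
    b <- bin_series(f$series)
    fit <- fit_hmm(b, run_config(em_restarts = 2))
    sa <- surface_association(smooth_posteriors(b, fit))
    ev <- detect_events(sa, 0.75)
    truth_ev <- f$truth$events
    expect_identical(nrow(ev), nrow(truth_ev))
    if (nrow(ev)) {
      expect_true(all(abs(ev$start_bin - truth_ev$start_bin) <= 1))
      expect_true(all(abs(ev$end_bin - truth_ev$end_bin) <= 1))
    }
  }
})

test_that("outlier fraction on a planted cohort matches direct computation", {
  sc <- fast_scenario(n_fish = 6, deployment_days = c(31, 40), seed = 48)
  coh <- simulate_cohort(sc, tracks = FALSE)
  durs <- do.call(rbind, lapply(coh$fish, function(f) {
    tr <- f$truth$events
    if (nrow(tr)) data.frame(fish_id = f$truth$fish_id,
                             duration_days = tr$duration_days,
                             is_release_event = FALSE)
  }))
  fl <- flag_outliers(durs)
  q <- quantile(durs$duration_days, c(0.25, 0.75), type = 7, names = FALSE)
  want <- durs$duration_days > q[2] + 1.5 * (q[2] - q[1])
  expect_identical(fl$events$is_outlier, want)
  expect_equal(fl$outlier_fraction, mean(want))
})

test_that("gap injection produces screening exclusions", {
  sc <- fast_scenario(n_fish = 1, deployment_days = c(35, 35), seed = 49,
                      gaps = list(n = 1, hours = 3))
  f <- simulate_fish(sc, 1)
  sc_res <- screen_eligibility(f$series)
  expect_false(sc_res$eligible)
  expect_match(sc_res$reasons, "gap", all = FALSE)
})

test_that("cohorts can be written to disk and read back", {
  sc <- fast_scenario(n_fish = 2, deployment_days = c(31, 32), seed = 50)
  dir <- tempfile("cohort")
  coh <- simulate_cohort(sc, out_dir = dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "tracks.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  back <- read_tag_series(file.path(dir, "SIM001.csv"),
                          file.path(dir, "metadata.csv"))
  orig <- coh$fish[[1]]$series
  expect_identical(back$species, orig$species)
  expect_equal(back$samples$depth, orig$samples$depth, tolerance = 1e-8)
  expect_equal(as.numeric(back$samples$timestamp),
               as.numeric(orig$samples$timestamp))
  unlink(dir, recursive = TRUE)
})
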