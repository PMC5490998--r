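# surfassoc

Behavioural classification of archival-tag records from tropical tuna, for
fisheries scientists and movement ecologists studying when — and where —
juvenile bigeye and yellowfin tuna associate with the surface layer, the
behaviour that makes them vulnerable to purse-seine sets on floating
objects (FADs).

## What it computes

Each fish's depth/temperature record is reduced to a bivariate series on a
contiguous 3-hour grid: diving amplitude `s_t` (SD of depth within the
bin, m) and thermal habitat `m_t` (mean ambient temperature, °C). A
two-state hidden Markov model with bivariate-normal emissions is fitted
per individual,

```
(s_t, m_t) | z_t = k  ~  N_2(mu_k, Sigma_k),   k in {shallow, deep}
P(z_{t+1} = j | z_t = i) = A_ij,   z_1 ~ delta
```

by Baum–Welch EM with seeded restarts; the warmer state is labelled
*shallow*. Forward–backward smoothing gives the posterior
`p_t = P(z_t = shallow | all data)`, and the **surface-association
probability** is its trailing 24-hour running mean,

```
sa_t = (1/8) * sum_{u = t-7..t} p_u .
```

Diel switching (deep days, shallow nights) gives `sa_t = 0.5` exactly;
sustained shallow occupancy drives it towards 1. Maximal runs with
`sa_t > 0.75` are **surface-association events**, from which per-fish
metrics are computed (proportion of time surface-associated, events per
month-at-liberty, release/recapture-window behaviour, Tukey-rule duration
outliers, Hartigan's dip test of bimodality — the dip statistic is
implemented from its greatest-convex-minorant/least-concave-majorant
definition and LP-validated). When light-based geolocation estimates are
available, each position's 95% confidence ellipse carries its `sa` value
onto a 0.1° grid, cells averaging over all overlapping observations.

A synthetic tag-data generator with retained ground truth (true states,
bout schedule, induced event schedule) stands in for the request-only
real archives and powers the validation suite.

## Worked example

```r
library(surfassoc)

scenario <- sim_scenario(n_fish = 3, interval_s = 300, seed = 7)
input  <- file.path(tempdir(), "tags")
output <- file.path(tempdir(), "results")
simulate_cohort(scenario, out_dir = input)     # CSVs + truth bundle

res <- run_pipeline(input, output, run_config(seed = 7))
print(res$models[["SIM001"]])
#> <surf_hmm> SIM001: 2-state MVN HMM, logLik -2064.64 (8 iter)
#>   shallow state 1: depth_sd 5.0 m, temp 28.0 C
#>   deep state 2:    depth_sd 40.5 m, temp 18.1 C
#>   transition matrix:
#>        [,1]   [,2]
#> [1,] 0.8555 0.1445
#> [2,] 0.2646 0.7354

res$summaries[, c("fish_id", "days_at_liberty", "prop_surface",
                  "n_events", "events_per_month", "release_event")]
#>   fish_id days_at_liberty prop_surface n_events events_per_month release_event
#> 1  SIM001              67        0.289        5             2.27          TRUE
#> 2  SIM002              64        0.239        6             2.85          TRUE
#> 3  SIM003              88        0.170        7             2.42         FALSE
```

The fitted state means sit on the generating values (shallow ≈ 5 m
amplitude at 28 °C, deep ≈ 40 m at 18 °C); the three fish spend 17–29% of
their records surface-associated at ~2.3–2.9 events per month, and two of
the three begin with a release event — an event starting within 24 h of
tagging. The events table flags one 8.9-day event as a duration outlier
(above Q3 + 1.5 IQR of the cohort's durations):

```r
head(res$events[, c("fish_id", "start_time", "duration_days",
                    "is_release_event", "is_outlier")])
#>   fish_id          start_time duration_days is_release_event is_outlier
#> 1  SIM001 2008-03-02 09:00:00          4.00             TRUE      FALSE
#> 2  SIM001 2008-03-20 12:00:00          1.88            FALSE      FALSE
#> 3  SIM001 2008-03-25 15:00:00          1.75            FALSE      FALSE
#> 4  SIM001 2008-03-30 12:00:00          8.88            FALSE       TRUE
#> 5  SIM001 2008-05-01 15:00:00          2.62            FALSE      FALSE
#> 6  SIM002 2008-03-03 09:00:00          6.00             TRUE      FALSE
```

`output/` now holds tidy CSVs (`summary.csv`, `events.csv`, `sweep.csv`,
`exclusions.csv`, `raster.csv` — here 1354 grid cells), per-fish model
JSON under `models/`, and `run_log.json` with the seed, configuration and
EM diagnostics. A thin command-line wrapper with `run`, `simulate` and
`sweep` subcommands lives at `inst/cli/surfassoc.R`.

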