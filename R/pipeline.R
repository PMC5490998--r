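## Whole-cohort orchestration: screen -> bin -> fit -> smooth -> events ->
## summaries (-> spatial combination when tracks are present) -> tidy CSVs.

.df_for_csv <- function(df) {
  for (nm in names(df)) {
    if (inherits(df[[nm]], "POSIXct")) df[[nm]] <- .format_utc(df[[nm]])
  }
  df
}

#' Write pipeline results to a directory of tidy CSVs
#'
#' One CSV per result table (`summary.csv`, `events.csv`, `sweep.csv`,
#' `exclusions.csv`, `raster.csv` when present), fitted models as JSON
#' under `models/`, and the run log as `run_log.json`. Empty tables are
#' written with headers only.
#'
#' @param results A list with any of `summaries`, `events`, `sweeps`,
#'   `exclusions`, `raster`, `models`, `log`.
#' @param out_dir Output directory (created if needed).
#' @return A manifest `data.frame` (`file`, `rows`) of everything written.
#' @export
write_outputs <- function(results, out_dir) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  manifest <- list()
  add <- function(file, rows) {
    manifest[[length(manifest) + 1L]] <<- data.frame(file = file,
                                                     rows = rows)
  }
  tables <- list(summary.csv = results$summaries,
                 events.csv = results$events,
                 sweep.csv = results$sweeps,
                 exclusions.csv = results$exclusions)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (is.null(tb)) next
    path <- file.path(out_dir, nm)
    write.csv(.df_for_csv(tb), path, row.names = FALSE, quote = FALSE)
    add(nm, nrow(tb))
  }
  if (!is.null(results$raster)) {
    write_raster(results$raster, file.path(out_dir, "raster.csv"))
    add("raster.csv", nrow(results$raster))
  }
  if (length(results$models)) {
    dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
    for (m in results$models) {
      f <- file.path("models", paste0(m$fish_id, ".json"))
      write_hmm_json(m, file.path(out_dir, f))
      add(f, 1L)
    }
  }
  if (!is.null(results$log)) {
    jsonlite::write_json(results$log, file.path(out_dir, "run_log.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    add("run_log.json", 1L)
  }
  do.call(rbind, manifest)
}

#' Run the surface-association pipeline over a directory of tag records
#'
#' Reads `metadata.csv` plus one `<fish_id>.csv` sample file per fish from
#' `input_dir` (and `tracks.csv` if present), screens each series for
#' eligibility, and for every eligible fish fits the two-state HMM,
#' derives the surface-association series, extracts events and summary
#' metrics and the threshold sweep. Cohort-wide event-duration outliers
#' are flagged (with and without release events). When tracks are present
#' the probability raster is built. All outputs are written to `out_dir`
#' via [write_outputs()]; identical inputs, configuration and seed yield
#' identical outputs.
#'
#' @param input_dir Directory with `metadata.csv`, sample CSVs and
#'   optionally `tracks.csv`.
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @return Invisibly, a list with the result tables, fitted `models`, the
#'   `raster` (or `NULL`), the `manifest` and the run `log`.
#' @export
run_pipeline <- function(input_dir, out_dir, config = run_config()) {
  meta_path <- file.path(input_dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    stop("no metadata.csv in ", input_dir)
  }
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  if (nrow(meta) == 0L) stop("no eligible series: metadata.csv is empty")
  track_path <- file.path(input_dir, "tracks.csv")
  tracks <- if (file.exists(track_path)) read_geo_track(track_path)

  summaries <- list(); events_all <- list(); sweeps <- list()
  exclusions <- list(); models <- list(); cells_all <- list()
  diagnostics <- list(); notes <- list()
  for (i in seq_len(nrow(meta))) {
    fid <- meta$fish_id[i]
    series <- read_tag_series(file.path(input_dir, paste0(fid, ".csv")),
                              meta_path, fish_id = fid)
    sc <- screen_eligibility(series, config$min_days,
                             config$max_gap_hours)
    if (!sc$eligible) {
      exclusions[[fid]] <- data.frame(
        fish_id = fid, reason = paste(sc$reasons, collapse = "; "))
      next
    }
    binned <- bin_series(series, config$bin_hours, config$coverage_floor)
    model <- fit_hmm(binned, config, seed = config$seed + i)
    post <- smooth_posteriors(binned, model)
    sa <- surface_association(post, config$window_bins,
                              config$window_align)
    ev <- detect_events(sa, config$event_threshold, config$min_event_bins)
    summaries[[fid]] <- summarize_fish(ev, sa, config$month_days)
    events_all[[fid]] <- ev
    sweeps[[fid]] <- threshold_sweep(sa, config$sweep_lo, config$sweep_hi,
                                     config$sweep_step,
                                     config$min_event_bins)
    models[[fid]] <- model
    diagnostics[[fid]] <- list(fish_id = fid, loglik = model$loglik,
                               n_iter = model$n_iter,
                               converged = model$converged,
                               restart_used = model$restart_used,
                               n_degenerate = model$n_degenerate,
                               n_valid_bins = model$n_valid_bins)
    if (!is.null(tracks)) {
      trk <- tracks[tracks$fish_id == fid, , drop = FALSE]
      if (nrow(trk)) {
        ## estimates ahead of the first defined running-mean bin are
        ## expected; collect the notice in the log rather than warn per fish
        ell <- withCallingHandlers(
          attach_probability(trk, sa),
          warning = function(w) {
            notes[[length(notes) + 1L]] <<- paste0(fid, ": ",
                                                   conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        cells_all[[fid]] <- rasterize_ellipses(ell,
                                               config$raster_cell_deg,
                                               config$ellipse_axis)
      }
    }
  }
  if (!length(summaries)) {
    stop("no eligible series after screening (",
         length(exclusions), " excluded)")
  }
  events_df <- do.call(rbind, c(events_all, list(make.row.names = FALSE)))
  outl <- if (nrow(events_df) >= 4L) flag_outliers(events_df) else NULL
  outl_nr <- if (nrow(events_df) >= 4L)
    flag_outliers(events_df, exclude_release = TRUE) else NULL
  if (!is.null(outl)) events_df <- outl$events

  raster <- if (length(cells_all)) {
    combine_raster(do.call(rbind, cells_all), config$raster_cell_deg)
  }
  results <- list(
    summaries = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
    events = events_df,
    sweeps = do.call(rbind, c(sweeps, list(make.row.names = FALSE))),
    exclusions = if (length(exclusions)) {
      do.call(rbind, c(exclusions, list(make.row.names = FALSE)))
    } else {
      data.frame(fish_id = character(0), reason = character(0))
    },
    models = models,
    raster = raster,
    log = list(
      seed = config$seed,
      config = unclass(config),
      n_fish = nrow(meta),
      n_eligible = length(summaries),
      n_excluded = length(exclusions),
      outliers = if (!is.null(outl)) list(
        cutoff_days = outl$cutoff, fraction = outl$outlier_fraction,
        n_outliers = outl$n_outliers, n_fish = outl$n_fish),
      outliers_excl_release = if (!is.null(outl_nr)) list(
        cutoff_days = outl_nr$cutoff,
        fraction = outl_nr$outlier_fraction,
        n_outliers = outl_nr$n_outliers, n_fish = outl_nr$n_fish),
      notes = unlist(notes),
      em_diagnostics = unname(diagnostics)))
  results$manifest <- write_outputs(results, out_dir)
  invisible(results)
}
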