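## Domain object: per-fish archival tag record (sensor samples + deployment
## metadata). Plain S3 list; samples kept as a data.frame.

.species_levels <- c("bigeye", "yellowfin", "other")
.release_school_levels <- c("FAD", "log", "free", "megafauna", "seamount",
                            "unknown")
.recapture_set_levels <- c("FAD", "log", "free", "unknown")

.parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    return(as.POSIXct(format(x, tz = "UTC"), tz = "UTC"))
  }
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%d"))
  out
}

.format_utc <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Construct a validated tag record series
#'
#' @param fish_id Identifier string.
#' @param species One of `"bigeye"`, `"yellowfin"`, `"other"`.
#' @param fork_length Fork length at release, cm.
#' @param release_time,recapture_time Deployment window (UTC `POSIXct` or
#'   ISO-8601 strings). `recapture_time` may be `NA` for truncated series.
#' @param release_school School association at release (`"FAD"`, `"log"`,
#'   `"free"`, `"megafauna"`, `"seamount"`, `"unknown"`).
#' @param recapture_set Purse-seine set type at recapture (`"FAD"`, `"log"`,
#'   `"free"`, `"unknown"`).
#' @param samples `data.frame` with columns `timestamp` (UTC), `depth` (m,
#'   non-negative), `ambient_temp` (deg C) and optionally `internal_temp`,
#'   `light`. Timestamps must be strictly increasing.
#' @param truncated Logical; `TRUE` when the record ends before recapture
#'   (tag malfunction). Truncated series are excluded from recapture-window
#'   metrics only.
#'
#' @return An object of class `tag_series`.
#' @export
tag_series <- function(fish_id, species = "other", fork_length = NA_real_,
                       release_time, recapture_time = NA,
                       release_school = "unknown", recapture_set = "unknown",
                       samples, truncated = FALSE) {
  stopifnot(is.character(fish_id), length(fish_id) == 1L, nzchar(fish_id))
  species <- match.arg(species, .species_levels)
  release_school <- match.arg(release_school, .release_school_levels)
  recapture_set <- match.arg(recapture_set, .recapture_set_levels)
  release_time <- .parse_utc(release_time)
  recapture_time <- if (length(recapture_time) == 1L && is.na(recapture_time))
    as.POSIXct(NA) else .parse_utc(recapture_time)

  need <- c("timestamp", "depth", "ambient_temp")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("schema error: samples missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(samples) == 0L) stop("empty sample series for fish ", fish_id)
  samples$timestamp <- .parse_utc(samples$timestamp)
  if (anyNA(samples$timestamp)) {
    stop("unparseable timestamp at line ",
         which(is.na(samples$timestamp))[1L] + 1L)
  }
  dt <- diff(as.numeric(samples$timestamp))
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L] + 1L
    stop(sprintf("timestamps not strictly increasing at line %d (sample %d)",
                 bad + 1L, bad))
  }
  if (any(samples$depth < 0, na.rm = TRUE)) {
    stop("negative depth at sample ", which(samples$depth < 0)[1L])
  }
  if (length(dt)) {
    med <- median(dt)
    if (med < 10 || med > 300) {
      warning(sprintf("median sampling interval %.1f s outside 10-300 s", med))
    }
  }
  if (!is.na(release_time) &&
      as.numeric(difftime(samples$timestamp[1L], release_time,
                          units = "hours")) < -1) {
    warning("first sample precedes release_time by more than 1 h")
  }
  if (!truncated && !is.na(recapture_time) &&
      recapture_time < samples$timestamp[nrow(samples)]) {
    warning("recapture_time precedes last sample on a non-truncated series")
  }
  for (opt in c("internal_temp", "light")) {
    if (is.null(samples[[opt]])) samples[[opt]] <- NA_real_
  }
  structure(
    list(fish_id = fish_id, species = species, fork_length = fork_length,
         release_time = release_time, recapture_time = recapture_time,
         release_school = release_school, recapture_set = recapture_set,
         truncated = isTRUE(truncated),
         samples = samples[, c("timestamp", "depth", "ambient_temp",
                               "internal_temp", "light")]),
    class = "tag_series")
}

#' @export
print.tag_series <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<tag_series> %s (%s, FL %s cm)\n", x$fish_id, x$species,
              format(x$fork_length)))
  cat(sprintf("  release %s (%s school), recapture %s (%s set)%s\n",
              .format_utc(x$release_time), x$release_school,
              if (is.na(x$recapture_time)) "NA" else
                .format_utc(x$recapture_time),
              x$recapture_set,
              if (x$truncated) " [truncated]" else ""))
  cat(sprintf("  %d samples, %s to %s\n", n,
              .format_utc(x$samples$timestamp[1L]),
              .format_utc(x$samples$timestamp[n])))
  invisible(x)
}

#' Read a tag record series from CSV
#'
#' Sample files are UTF-8 CSVs with a header and columns `timestamp`
#' (ISO-8601, UTC), `depth` (m), `ambient_temp` (deg C) and optional
#' `internal_temp`, `light`; '.' is the decimal mark. The metadata file has
#' one row per fish with columns `fish_id`, `species`, `fork_length`,
#' `release_time`, `recapture_time`, `release_school`, `recapture_set`,
#' `truncated`.
#'
#' @param path Path to the per-fish sample CSV.
#' @param metadata_path Path to the deployment metadata CSV.
#' @param fish_id Fish to select from the metadata; defaults to the sample
#'   file's base name.
#' @return A validated [tag_series()].
#' @seealso [write_tag_series()]
#' @export
read_tag_series <- function(path, metadata_path,
                            fish_id = sub("\\.csv$", "", basename(path))) {
  if (!file.exists(path)) stop("no such sample file: ", path)
  if (!file.exists(metadata_path)) {
    stop("no such metadata file: ", metadata_path)
  }
  samples <- read.csv(path, stringsAsFactors = FALSE)
  meta <- read.csv(metadata_path, stringsAsFactors = FALSE)
  need <- c("fish_id", "species", "fork_length", "release_time",
            "recapture_time", "release_school", "recapture_set", "truncated")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("schema error: metadata missing column(s): ",
         paste(miss, collapse = ", "))
  }
  row <- meta[meta$fish_id == fish_id, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop(sprintf("metadata has %d rows for fish_id '%s' (need exactly 1)",
                 nrow(row), fish_id))
  }
  rec <- row$recapture_time
  tag_series(
    fish_id = as.character(row$fish_id), species = row$species,
    fork_length = as.numeric(row$fork_length),
    release_time = row$release_time,
    recapture_time = if (is.na(rec) || !nzchar(rec)) NA else rec,
    release_school = row$release_school, recapture_set = row$recapture_set,
    samples = samples, truncated = as.logical(row$truncated))
}

#' Write a tag record series to CSV
#'
#' Writes the sample table to `path` and appends (or creates) the fish's row
#' in `metadata_path`. Numeric sensor values are written with 10 decimal
#' places, the documented round-trip precision.
#'
#' @inheritParams read_tag_series
#' @param series A [tag_series()].
#' @return Invisibly, `c(path, metadata_path)`.
#' @export
write_tag_series <- function(series, path, metadata_path) {
  stopifnot(inherits(series, "tag_series"))
  s <- series$samples
  out <- data.frame(
    timestamp = .format_utc(s$timestamp),
    depth = sprintf("%.10f", s$depth),
    ambient_temp = sprintf("%.10f", s$ambient_temp),
    internal_temp = ifelse(is.na(s$internal_temp), "",
                           sprintf("%.10f", s$internal_temp)),
    light = ifelse(is.na(s$light), "", sprintf("%.10f", s$light)))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  mrow <- data.frame(
    fish_id = series$fish_id, species = series$species,
    fork_length = series$fork_length,
    release_time = .format_utc(series$release_time),
    recapture_time = if (is.na(series$recapture_time)) "" else
      .format_utc(series$recapture_time),
    release_school = series$release_school,
    recapture_set = series$recapture_set,
    truncated = series$truncated)
  if (file.exists(metadata_path)) {
    meta <- read.csv(metadata_path, stringsAsFactors = FALSE,
                     colClasses = "character")
    meta <- meta[meta$fish_id != series$fish_id, , drop = FALSE]
    mrow[] <- lapply(mrow, as.character)
    meta <- rbind(meta, mrow)
  } else {
    meta <- mrow
  }
  write.csv(meta, metadata_path, row.names = FALSE, quote = FALSE)
  invisible(c(path, metadata_path))
}
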