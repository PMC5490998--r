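## Combining geolocation confidence ellipses with surface-association
## probabilities on a 0.1 degree grid. Grid cells are registered with edges
## at multiples of the cell size from the 0 meridian / equator; longitudes
## are normalized to [0, 360) so the grid is continuous across the
## antimeridian.

#' Read a geolocation track from CSV
#'
#' Expected columns: `fish_id`, `time` (ISO-8601 UTC), `lon`, `lat`
#' (degrees), `ci_lon`, `ci_lat` (full 95% CI widths in degrees, > 0).
#'
#' @param path CSV path.
#' @return A `data.frame` with parsed times.
#' @export
read_geo_track <- function(path) {
  if (!file.exists(path)) stop("no such track file: ", path)
  trk <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "time", "lon", "lat", "ci_lon", "ci_lat")
  miss <- setdiff(need, names(trk))
  if (length(miss)) {
    stop("schema error: track missing column(s): ",
         paste(miss, collapse = ", "))
  }
  trk$time <- .parse_utc(trk$time)
  if (any(trk$ci_lon <= 0 | trk$ci_lat <= 0)) {
    stop("confidence interval widths must be positive")
  }
  trk
}

#' Write a geolocation track to CSV
#' @param track Track `data.frame`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_geo_track <- function(track, path) {
  out <- track
  out$time <- .format_utc(out$time)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach surface-association probabilities to position estimates
#'
#' Each geolocation estimate is paired with the surface-association value
#' of the temporally nearest defined bin (bin midpoints; an estimate
#' exactly equidistant between two bins takes the earlier bin). Estimates
#' lying outside the defined span by more than half a bin are dropped with
#' a warning.
#'
#' @param track A [read_geo_track()] style `data.frame` for one fish.
#' @param sa The fish's [surface_association()] series.
#' @return The track with an `sa` column (class `probability_ellipses`).
#' @export
attach_probability <- function(track, sa) {
  bh <- attr(sa, "bin_hours") %||% 3
  def <- !is.na(sa$sa)
  if (!any(def)) stop("no defined surface-association bins")
  mids <- as.numeric(sa$bin_start[def]) + bh * 1800
  vals <- sa$sa[def]
  tt <- as.numeric(track$time)
  if (max(tt) < min(mids) - bh * 1800 || min(tt) > max(mids) + bh * 1800) {
    stop("track and surface-association series do not overlap in time")
  }
  keep <- tt >= min(mids) - bh * 1800 & tt <= max(mids) + bh * 1800
  if (any(!keep)) {
    warning(sprintf(
      "dropping %d estimate(s) outside the surface-association span",
      sum(!keep)))
  }
  out <- track[keep, , drop = FALSE]
  idx <- vapply(as.numeric(out$time), function(t)
    which.min(abs(mids - t)), integer(1))     # ties: earlier bin (first min)
  out$sa <- vals[idx]
  class(out) <- c("probability_ellipses", "data.frame")
  attr(out, "bin_hours") <- bh
  out
}

## grid helpers: cell index from coordinate, cell center from index
.cell_index <- function(coord, cell_deg) as.integer(floor(coord / cell_deg))
.cell_center <- function(index, cell_deg) (index + 0.5) * cell_deg

#' Rasterize probability ellipses onto the analysis grid
#'
#' Each estimate becomes an axis-aligned ellipse centred on (`lon`, `lat`)
#' whose semi-axes derive from the 95% CI widths (`axis = "full"`: CI width
#' is the full axis, semi-axis = width / 2; `"half"`: CI width already is
#' the semi-axis). A grid cell belongs to the ellipse when its centre lies
#' inside or on the ellipse; an ellipse smaller than a cell still claims
#' the cell containing its centre. Every claimed cell inherits the
#' ellipse's surface-association probability unchanged.
#'
#' @param ellipses An [attach_probability()] result (needs `lon`, `lat`,
#'   `ci_lon`, `ci_lat`, `sa`).
#' @param cell_deg Cell size in degrees (default 0.1).
#' @param axis `"full"` (default) or `"half"`; see above.
#' @return A `data.frame` with one row per (ellipse, cell): `ellipse_id`,
#'   `cell_ix`, `cell_iy`, `lon`, `lat` (cell centres), `sa`.
#' @export
rasterize_ellipses <- function(ellipses, cell_deg = 0.1,
                               axis = c("full", "half")) {
  axis <- match.arg(axis)
  stopifnot(nrow(ellipses) >= 1)
  half <- if (axis == "full") 0.5 else 1
  nx <- as.integer(round(360 / cell_deg))
  res <- vector("list", nrow(ellipses))
  for (e in seq_len(nrow(ellipses))) {
    lon0 <- ellipses$lon[e] %% 360
    lat0 <- ellipses$lat[e]
    a <- ellipses$ci_lon[e] * half
    b <- ellipses$ci_lat[e] * half
    ix <- .cell_index(lon0 - a, cell_deg):.cell_index(lon0 + a, cell_deg)
    iy <- .cell_index(lat0 - b, cell_deg):.cell_index(lat0 + b, cell_deg)
    g <- expand.grid(ix = ix, iy = iy)
    cx <- .cell_center(g$ix, cell_deg)
    cy <- .cell_center(g$iy, cell_deg)
    inside <- ((cx - lon0) / a)^2 + ((cy - lat0) / b)^2 <= 1
    g <- g[inside, , drop = FALSE]
    if (nrow(g) == 0L) {                 # degenerate: claim the centre cell
      g <- data.frame(ix = .cell_index(lon0, cell_deg),
                      iy = .cell_index(lat0, cell_deg))
    }
    res[[e]] <- data.frame(
      ellipse_id = e,
      cell_ix = g$ix %% nx,              # wrap across the antimeridian
      cell_iy = g$iy,
      sa = ellipses$sa[e])
  }
  out <- do.call(rbind, res)
  out$lon <- .cell_center(out$cell_ix, cell_deg)
  out$lat <- .cell_center(out$cell_iy, cell_deg)
  attr(out, "cell_deg") <- cell_deg
  out
}

#' Combine rasterized ellipses into a probability raster
#'
#' Per map cell, the mean surface-association probability over every
#' (ellipse, cell) observation touching it: equal weight per observation,
#' regardless of which fish contributed, with observation counts retained
#' so low-support cells can be masked downstream.
#'
#' @param cells Rasterized cells from [rasterize_ellipses()] (rows may come
#'   from many fish; simply `rbind` them).
#' @param cell_deg Cell size in degrees (default taken from `cells`).
#' @return A `data.frame` of class `probability_raster` with columns
#'   `cell_ix`, `cell_iy`, `lon`, `lat`, `mean_probability`, `n_obs`.
#' @export
combine_raster <- function(cells, cell_deg = attr(cells, "cell_deg") %||%
                             0.1) {
  stopifnot(nrow(cells) >= 1)
  key <- paste(cells$cell_ix, cells$cell_iy, sep = ":")
  sums <- rowsum(cells$sa, key)
  cnts <- rowsum(rep(1, nrow(cells)), key)
  parts <- strsplit(rownames(sums), ":", fixed = TRUE)
  ix <- as.integer(vapply(parts, `[[`, character(1), 1L))
  iy <- as.integer(vapply(parts, `[[`, character(1), 2L))
  out <- data.frame(
    cell_ix = ix, cell_iy = iy,
    lon = .cell_center(ix, cell_deg),
    lat = .cell_center(iy, cell_deg),
    mean_probability = as.numeric(sums) / as.numeric(cnts),
    n_obs = as.integer(cnts))
  out <- out[order(out$cell_ix, out$cell_iy), ]
  rownames(out) <- NULL
  attr(out, "cell_deg") <- cell_deg
  class(out) <- c("probability_raster", "data.frame")
  out
}

#' Write a probability raster as gridded CSV
#' @param raster A [combine_raster()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_raster <- function(raster, path) {
  write.csv(raster[, c("lon", "lat", "mean_probability", "n_obs")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
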