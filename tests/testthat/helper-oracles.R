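# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's own code paths (loops and direct arithmetic instead
# of filter/rle/forward-backward) so agreement is evidence, not tautology.

# hand-built binned series on a 3-h grid starting at midnight UTC
make_binned <- function(depth_sd, temp_mean, valid = NULL,
                        fish_id = "FIX", release = "2008-01-01T00:00:00",
                        truncated = FALSE, recapture = NULL) {
  T_ <- length(depth_sd)
  anchor <- as.POSIXct(release, tz = "UTC",
                       format = "%Y-%m-%dT%H:%M:%S")
  if (is.null(valid)) valid <- rep(TRUE, T_)
  if (is.null(recapture)) recapture <- anchor + T_ * 10800
  out <- data.frame(
    fish_id = fish_id, bin = seq_len(T_) - 1L,
    bin_start = anchor + (seq_len(T_) - 1L) * 10800,
    depth_sd = depth_sd, temp_mean = temp_mean,
    n_samples = 180L, valid = valid)
  attr(out, "bin_hours") <- 3
  attr(out, "anchor") <- anchor
  attr(out, "meta") <- list(fish_id = fish_id, species = "other",
                            fork_length = 70,
                            release_time = anchor,
                            recapture_time = recapture,
                            release_school = "unknown",
                            recapture_set = "unknown",
                            truncated = truncated)
  class(out) <- c("binned_series", "data.frame")
  out
}

# hand-built state-posterior series (bypasses the HMM)
make_posteriors <- function(p_shallow, ...) {
  b <- make_binned(rep(5, length(p_shallow)), rep(28, length(p_shallow)),
                   ...)
  out <- data.frame(fish_id = b$fish_id, bin = b$bin,
                    bin_start = b$bin_start,
                    p_shallow = p_shallow, valid = b$valid)
  attr(out, "bin_hours") <- 3
  attr(out, "meta") <- attr(b, "meta")
  class(out) <- c("state_posteriors", "data.frame")
  out
}

# hand-built surface-association series with every bin defined
make_sa <- function(sa_values, ...) {
  p <- make_posteriors(rep(0.5, length(sa_values)), ...)
  out <- data.frame(fish_id = p$fish_id, bin = p$bin,
                    bin_start = p$bin_start,
                    p_shallow = p$p_shallow, sa = sa_values)
  attr(out, "bin_hours") <- 3
  attr(out, "window_bins") <- 8
  attr(out, "align") <- "trailing"
  attr(out, "meta") <- attr(p, "meta")
  class(out) <- c("sa_series", "data.frame")
  out
}

# trailing sliding mean by an explicit loop
oracle_sliding_mean <- function(p, w) {
  T_ <- length(p)
  out <- rep(NA_real_, T_)
  for (t in seq_len(T_)) {
    if (t >= w) out[t] <- sum(p[(t - w + 1):t]) / w
  }
  out
}

# maximal above-threshold runs by an explicit linear scan
oracle_scan_events <- function(sa, threshold, min_bins = 1) {
  above <- !is.na(sa) & sa > threshold
  runs <- list()
  start <- NA_integer_
  for (t in seq_along(above)) {
    if (above[t] && is.na(start)) start <- t
    if (!above[t] && !is.na(start)) {
      runs[[length(runs) + 1L]] <- c(start, t - 1L)
      start <- NA_integer_
    }
  }
  if (!is.na(start)) runs[[length(runs) + 1L]] <- c(start, length(above))
  if (length(runs)) {
    m <- do.call(rbind, runs)
    m <- m[m[, 2] - m[, 1] + 1L >= min_bins, , drop = FALSE]
    m
  } else {
    matrix(integer(0), 0, 2)
  }
}

# smoothed HMM marginals by exhaustive enumeration over all 2^T paths
oracle_enum_posteriors <- function(X, valid, means, sigma, tpm, delta) {
  T_ <- nrow(X)
  dens <- function(x, mu, S) {
    d <- x - mu
    Si <- solve(S)
    exp(-0.5 * (d %*% Si %*% d)) / (2 * pi * sqrt(det(S)))
  }
  emis <- matrix(1, T_, 2)
  for (t in seq_len(T_)) {
    if (valid[t]) {
      for (k in 1:2) emis[t, k] <- dens(X[t, ], means[k, ], sigma[[k]])
    }
  }
  paths <- as.matrix(expand.grid(rep(list(1:2), T_)))
  w <- numeric(nrow(paths))
  for (i in seq_len(nrow(paths))) {
    s <- paths[i, ]
    pw <- delta[s[1]] * emis[1, s[1]]
    for (t in seq_len(T_ - 1)) {
      pw <- pw * tpm[s[t], s[t + 1]] * emis[t + 1, s[t + 1]]
    }
    w[i] <- pw
  }
  gamma <- matrix(0, T_, 2)
  for (t in seq_len(T_)) {
    for (k in 1:2) gamma[t, k] <- sum(w[paths[, t] == k])
  }
  gamma / rowSums(gamma)
}

# cells whose centre lies inside an axis-aligned ellipse, by scanning a
# generous index box point by point
oracle_ellipse_cells <- function(lon, lat, a, b, cell) {
  lon <- lon %% 360
  pad <- 2L
  ix0 <- floor((lon - a) / cell) - pad; ix1 <- floor((lon + a) / cell) + pad
  iy0 <- floor((lat - b) / cell) - pad; iy1 <- floor((lat + b) / cell) + pad
  hits <- list()
  for (ix in ix0:ix1) {
    for (iy in iy0:iy1) {
      cx <- (ix + 0.5) * cell
      cy <- (iy + 0.5) * cell
      if (((cx - lon) / a)^2 + ((cy - lat) / b)^2 <= 1) {
        hits[[length(hits) + 1L]] <- c(ix, iy)
      }
    }
  }
  if (!length(hits)) return(matrix(integer(0), 0, 2))
  m <- do.call(rbind, hits)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# a small generative model with well-separated states, used across tests
oracle_true_model <- function() {
  list(means = rbind(c(5, 28), c(40, 18)),
       sigma = list(diag(c(1.5^2, 0.5^2)), diag(c(8^2, 1^2))),
       tpm = rbind(c(0.92, 0.08), c(0.05, 0.95)),
       delta = c(0.5, 0.5))
}
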