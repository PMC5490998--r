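## Two-state multivariate-normal hidden Markov model on the binned
## (diving amplitude, thermal habitat) series: Baum-Welch EM with seeded
## restarts, scaled forward-backward smoothing, missing bins marginalized.

.COV_EIG_FLOOR <- 1e-6

## log density of rows of X under a bivariate normal (analytic 2x2 inverse)
.mvn_logdens <- function(X, mu, sigma) {
  a <- sigma[1, 1]; b <- sigma[1, 2]; d <- sigma[2, 2]
  det <- a * d - b * b
  x1 <- X[, 1] - mu[1]; x2 <- X[, 2] - mu[2]
  q <- (d * x1 * x1 - 2 * b * x1 * x2 + a * x2 * x2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

.floor_cov <- function(sigma) {
  sigma <- (sigma + t(sigma)) / 2
  e <- eigen(sigma, symmetric = TRUE)
  v <- pmax(e$values, .COV_EIG_FLOOR)
  e$vectors %*% (v * t(e$vectors))
}

## log emission matrix (T x 2); invalid bins contribute log-likelihood 0
## (emission density 1), the standard censored-HMM marginalization
.log_emissions <- function(X, valid, means, sigma) {
  T_ <- nrow(X)
  logB <- matrix(0, T_, 2)
  if (any(valid)) {
    Xv <- X[valid, , drop = FALSE]
    for (k in 1:2) {
      logB[valid, k] <- .mvn_logdens(Xv, means[k, ], sigma[[k]])
    }
  }
  logB
}

## scaled forward-backward. Returns smoothed marginals `gamma` (T x 2),
## expected transition counts `xi_sum` (2 x 2) and the log-likelihood.
.forward_backward <- function(logB, tpm, delta) {
  T_ <- nrow(logB)
  m <- pmax(logB[, 1], logB[, 2])
  b <- pmax(exp(logB - m), 1e-280)         # row-rescaled emission densities;
                                           # floor avoids exact-zero underflow
  alpha <- matrix(0, T_, 2)
  cvec <- numeric(T_)
  a <- delta * b[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  if (T_ > 1) {
    for (t in 2:T_) {
      a <- (alpha[t - 1, ] %*% tpm) * b[t, ]
      cvec[t] <- sum(a)
      alpha[t, ] <- a / cvec[t]
    }
  }
  ## beta rows are renormalized by their maximum each step; any per-row
  ## scale cancels in the row-normalized gamma and per-step-normalized xi,
  ## and it keeps degenerate models (near-zero path support) finite
  beta <- matrix(0, T_, 2)
  beta[T_, ] <- 1
  xi_sum <- matrix(0, 2, 2)
  if (T_ > 1) {
    for (t in (T_ - 1):1) {
      bb <- b[t + 1, ] * beta[t + 1, ]
      xi_t <- tpm * outer(alpha[t, ], bb)
      s <- sum(xi_t)
      if (s > 0) xi_sum <- xi_sum + xi_t / s
      bt <- tpm %*% bb
      beta[t, ] <- pmax(bt / max(bt), 1e-280)
    }
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, xi_sum = xi_sum,
       loglik = sum(log(cvec)) + sum(m))
}

## one Baum-Welch run from a given initialization
.em_run <- function(X, valid, init, max_iter, tol) {
  means <- init$means; sigma <- init$sigma
  tpm <- init$tpm; delta <- init$delta
  ll_old <- -Inf
  ll_hist <- numeric(0)
  degenerate <- FALSE
  fb <- NULL
  for (iter in seq_len(max_iter)) {
    logB <- .log_emissions(X, valid, means, sigma)
    fb <- .forward_backward(logB, tpm, delta)
    ll <- fb$loglik
    if (!is.finite(ll)) { degenerate <- TRUE; break }
    ll_hist <- c(ll_hist, ll)
    gamma <- fb$gamma
    delta <- gamma[1, ]
    rs <- rowSums(fb$xi_sum)
    if (all(rs > 0)) tpm <- fb$xi_sum / rs
    gv <- gamma[valid, , drop = FALSE]
    Xv <- X[valid, , drop = FALSE]
    w <- colSums(gv)
    if (any(w < 1.5)) { degenerate <- TRUE; break }   # state collapse
    for (k in 1:2) {
      mu <- colSums(gv[, k] * Xv) / w[k]
      xc <- sweep(Xv, 2, mu)
      S <- crossprod(xc * sqrt(gv[, k] / w[k]), xc * sqrt(gv[, k] / w[k]))
      means[k, ] <- mu
      sigma[[k]] <- .floor_cov(S)
    }
    if (iter > 1 && (ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(means = means, sigma = sigma, tpm = tpm, delta = delta,
       loglik = if (length(ll_hist)) ll_hist[length(ll_hist)] else -Inf,
       ll_hist = ll_hist, n_iter = length(ll_hist),
       converged = length(ll_hist) < max_iter && !degenerate,
       degenerate = degenerate)
}

## moment initialization from a temperature-quantile split, optionally
## perturbed (restarts > 1)
.em_init <- function(X, valid, perturb = FALSE) {
  Xv <- X[valid, , drop = FALSE]
  ## median split on thermal habitat, by rank so both groups stay populated
  ## even when temperatures are heavily tied
  warm <- rank(Xv[, 2], ties.method = "first") > nrow(Xv) / 2
  grp <- list(Xv[warm, , drop = FALSE], Xv[!warm, , drop = FALSE])
  means <- rbind(colMeans(grp[[1]]), colMeans(grp[[2]]))
  sigma <- lapply(grp, function(g) .floor_cov(cov(g)))
  tpm <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  delta <- c(0.5, 0.5)
  if (perturb) {
    sds <- apply(Xv, 2, sd)
    means <- means + matrix(rnorm(4, 0, 0.25 * pmax(sds, 1e-3)),
                            2, 2, byrow = TRUE)
    p <- runif(2, 0.7, 0.95)
    tpm <- rbind(c(p[1], 1 - p[1]), c(1 - p[2], p[2]))
    delta <- runif(2, 0.25, 0.75)
    delta <- delta / sum(delta)
  }
  list(means = means, sigma = sigma, tpm = tpm, delta = delta)
}

#' Fit a two-state multivariate-normal HMM to a binned series
#'
#' Baum-Welch EM on the bivariate observations (diving amplitude, thermal
#' habitat). Invalid bins are marginalized (emission likelihood 1) so the
#' 3-hour grid stays contiguous. The first initialization splits bins at the
#' median thermal habitat and takes group moments; remaining restarts are
#' seeded random perturbations. The restart with the best log-likelihood
#' wins. States carry no intrinsic order; [label_shallow_state()] assigns
#' the warm-shallow label.
#'
#' @param binned A [bin_series()] result with at least
#'   `config$min_fit_bins` valid bins.
#' @param config A [run_config()].
#' @param seed Seed for the random restarts; defaults to `config$seed`.
#' @return An object of class `surf_hmm`: state means (2 x 2 matrix, rows =
#'   states), covariances (`sigma`, list of 2), transition matrix `tpm`,
#'   initial distribution `delta`, `shallow_state`, `loglik`, the
#'   log-likelihood trace `ll_hist` of the winning run, and convergence
#'   diagnostics.
#' @examples
#' sc <- sim_scenario(n_fish = 1, deployment_days = c(40, 40))
#' fish <- simulate_fish(sc, 1)
#' b <- bin_series(fish$series)
#' m <- fit_hmm(b, run_config(em_restarts = 2))
#' m$means
#' @export
fit_hmm <- function(binned, config = run_config(), seed = config$seed) {
  stopifnot(inherits(binned, "binned_series"))
  X <- cbind(depth_sd = binned$depth_sd, temp_mean = binned$temp_mean)
  if (isTRUE(config$log_depth_sd)) X[, 1] <- log1p(X[, 1])
  valid <- binned$valid & !is.na(X[, 1]) & !is.na(X[, 2])
  X[!valid, ] <- 0                         # never read; keeps arithmetic finite
  if (sum(valid) < config$min_fit_bins) {
    stop(sprintf("only %d valid bins; need >= %d to fit the HMM",
                 sum(valid), config$min_fit_bins))
  }
  runs <- vector("list", config$em_restarts)
  for (r in seq_len(config$em_restarts)) {
    init <- if (r == 1L) {
      .em_init(X, valid, perturb = FALSE)
    } else {
      withr::with_seed(config_restart_seed(seed, r),
                       .em_init(X, valid, perturb = TRUE))
    }
    runs[[r]] <- .em_run(X, valid, init, config$em_max_iter, config$em_tol)
  }
  ok <- !vapply(runs, `[[`, logical(1), "degenerate")
  if (!any(ok)) {
    stop("all EM restarts degenerate (state collapse); ",
         "log-likelihoods: ",
         paste(sprintf("%.3f", vapply(runs, `[[`, numeric(1), "loglik")),
               collapse = ", "))
  }
  best <- which.max(ifelse(ok, vapply(runs, `[[`, numeric(1), "loglik"),
                           -Inf))
  fit <- runs[[best]]
  colnames(fit$means) <- c("depth_sd", "temp_mean")
  rownames(fit$means) <- c("state1", "state2")
  model <- structure(
    list(means = fit$means, sigma = fit$sigma, tpm = fit$tpm,
         delta = fit$delta, shallow_state = NA_integer_,
         loglik = fit$loglik, ll_hist = fit$ll_hist, n_iter = fit$n_iter,
         converged = fit$converged, restart_used = best,
         n_restarts = config$em_restarts,
         n_degenerate = sum(!ok), n_valid_bins = sum(valid),
         log_depth_sd = isTRUE(config$log_depth_sd),
         fish_id = attr(binned, "meta")$fish_id),
    class = "surf_hmm")
  model$shallow_state <- label_shallow_state(model)
  model
}

## deterministic per-restart seed stream, kept below 2^31
config_restart_seed <- function(seed, r) {
  (as.integer(seed) + 7919L * (r - 1L)) %% 2147483647L
}

#' Label the warm-shallow state of a fitted HMM
#'
#' The shallow state is the one with the larger mean thermal habitat
#' ("relatively warm and shallow"). If the two temperature means are within
#' `temp_tol` degrees the state with the smaller mean diving amplitude is
#' chosen instead. An exact tie on both criteria is an error: the fit needs
#' inspection.
#'
#' @param model A `surf_hmm`.
#' @param temp_tol Temperature tie tolerance in deg C (default 0.1).
#' @return The shallow state index (1 or 2).
#' @export
label_shallow_state <- function(model, temp_tol = 0.1) {
  tm <- model$means[, "temp_mean"]
  ds <- model$means[, "depth_sd"]
  if (abs(tm[1] - tm[2]) > temp_tol) {
    return(unname(which.max(tm)))
  }
  if (ds[1] != ds[2]) {
    return(unname(which.min(ds)))
  }
  if (tm[1] != tm[2]) return(unname(which.max(tm)))
  stop("cannot label shallow state: identical state means")
}

#' Smoothed shallow-state probabilities
#'
#' Runs the forward-backward recursions with the fitted parameters and
#' returns, per bin, the probability of the warm-shallow state given the
#' whole observation sequence. Invalid bins receive marginalized (smoothed)
#' probabilities; the recursions are scaled so chains of 1e4+ bins do not
#' underflow.
#'
#' @param binned The [bin_series()] result the model was fitted to.
#' @param model A fitted `surf_hmm`.
#' @return A `data.frame` of class `state_posteriors` with columns
#'   `fish_id`, `bin`, `bin_start`, `p_shallow`, `valid`, carrying the
#'   binned series' attributes.
#' @export
smooth_posteriors <- function(binned, model) {
  stopifnot(inherits(binned, "binned_series"), inherits(model, "surf_hmm"))
  X <- cbind(binned$depth_sd, binned$temp_mean)
  if (isTRUE(model$log_depth_sd)) X[, 1] <- log1p(X[, 1])
  valid <- binned$valid & !is.na(X[, 1]) & !is.na(X[, 2])
  X[!valid, ] <- 0
  logB <- .log_emissions(X, valid, model$means, model$sigma)
  fb <- .forward_backward(logB, model$tpm, model$delta)
  out <- data.frame(
    fish_id = binned$fish_id,
    bin = binned$bin,
    bin_start = binned$bin_start,
    p_shallow = fb$gamma[, model$shallow_state],
    valid = valid)
  attr(out, "bin_hours") <- attr(binned, "bin_hours")
  attr(out, "meta") <- attr(binned, "meta")
  class(out) <- c("state_posteriors", "data.frame")
  out
}

#' @export
print.surf_hmm <- function(x, ...) {
  cat(sprintf("<surf_hmm> %s: 2-state MVN HMM, logLik %.2f (%d iter%s)\n",
              x$fish_id %||% "?", x$loglik, x$n_iter,
              if (x$converged) "" else ", not converged"))
  sh <- x$shallow_state
  cat(sprintf("  shallow state %d: depth_sd %.1f m, temp %.1f C\n",
              sh, x$means[sh, 1], x$means[sh, 2]))
  cat(sprintf("  deep state %d:    depth_sd %.1f m, temp %.1f C\n",
              3 - sh, x$means[3 - sh, 1], x$means[3 - sh, 2]))
  cat("  transition matrix:\n")
  print(round(x$tpm, 4))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a fitted HMM to JSON
#'
#' @param model A `surf_hmm`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hmm_json <- function(model, path) {
  obj <- list(
    fish_id = model$fish_id,
    means = model$means,
    sigma = lapply(model$sigma, unclass),
    tpm = model$tpm, delta = model$delta,
    shallow_state = model$shallow_state,
    loglik = model$loglik, n_iter = model$n_iter,
    converged = model$converged,
    restart_used = model$restart_used, n_restarts = model$n_restarts,
    n_degenerate = model$n_degenerate,
    n_valid_bins = model$n_valid_bins,
    log_depth_sd = model$log_depth_sd)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a serialized HMM back from JSON
#' @param path Path written by [write_hmm_json()].
#' @return A `surf_hmm`.
#' @export
read_hmm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rowmat <- function(m) do.call(rbind, lapply(m, function(r)
    as.numeric(unlist(r))))
  model <- structure(
    list(means = `dimnames<-`(rowmat(obj$means),
                              list(c("state1", "state2"),
                                   c("depth_sd", "temp_mean"))),
         sigma = lapply(obj$sigma, rowmat),
         tpm = rowmat(obj$tpm),
         delta = as.numeric(obj$delta),
         shallow_state = as.integer(obj$shallow_state),
         loglik = obj$loglik, ll_hist = NULL, n_iter = obj$n_iter,
         converged = obj$converged, restart_used = obj$restart_used,
         n_restarts = obj$n_restarts, n_degenerate = obj$n_degenerate,
         n_valid_bins = obj$n_valid_bins,
         log_depth_sd = isTRUE(obj$log_depth_sd),
         fish_id = obj$fish_id),
    class = "surf_hmm")
  model
}
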