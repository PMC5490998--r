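## Hartigan's dip statistic: the sup-norm distance between the empirical
## CDF and the closest unimodal CDF (convex below the mode, concave above,
## the greatest-convex-minorant / least-concave-majorant geometry).
##
## Computed by bisection on the tube half-width d: F_n is within d of some
## unimodal G iff a piecewise-linear path with a unimodal slope sequence
## fits inside the staircase tube [F_n - d, F_n + d]. Feasibility is
## decided by an O(n^2) chord-envelope sweep from each side plus a modal
## junction condition (connector slope must dominate both arrival slopes).

## one-sided sweep: minimal reachable value A_j and minimal arrival slope
## S_j of a convex path through the tube [l, u] at points x
.dip_sweep <- function(x, l, u) {
  m <- length(x)
  rowmax <- function(mat) mat[cbind(seq_len(m),
                                    max.col(mat, ties.method = "first"))]
  dx <- outer(x, x, "-")                 # dx[j, i] = x_j - x_i
  lower <- row(dx) > col(dx)             # i < j
  ch <- (outer(l, u, "-")) / dx          # chord (l_j - u_i)/(x_j - x_i)
  ch[!lower] <- -Inf
  cc <- rowmax(ch)                       # forced slope into j
  cpos <- pmax(cc, 0); cpos[1] <- 0
  line <- outer(rep(1, m), l) + outer(rep(1, m), cpos) * dx  # [j, i']
  line[!lower] <- -Inf
  A <- pmax(l, rowmax(line))
  prefix_ok <- cumsum(A > u + 1e-12) == 0
  C <- cummax(pmax(cc, -Inf))
  ar <- (outer(A, u, "-")) / dx
  ar[!lower] <- -Inf
  S <- pmax(0, pmax(C, rowmax(ar)))
  S[1] <- 0
  list(A = A, S = S, ok = prefix_ok)
}

## feasibility of |F_n - G| <= d for some unimodal cdf G; ux unique sorted
## values, flo/fhi the empirical cdf just below / at each value
.dip_feasible <- function(ux, flo, fhi, d) {
  m <- length(ux)
  l <- pmax(fhi - d, 0)
  u <- pmin(flo + d, 1)
  if (any(l > u + 1e-15)) return(FALSE)
  if (m == 1L) return(TRUE)
  fwd <- .dip_sweep(ux, l, u)
  ## concave side, mirrored: reflect positions and values
  bwd <- .dip_sweep(-rev(ux), 1 - rev(u), 1 - rev(l))
  B <- 1 - rev(bwd$A)                    # max reachable value from the right
  R <- rev(bwd$S)                        # min departure slope at j
  suffix_ok <- rev(bwd$ok)
  if (fwd$ok[m] || suffix_ok[1]) return(TRUE)  # pure convex / pure concave
  j <- seq_len(m - 1)
  lhs <- B[j + 1] - fwd$A[j]
  rhs <- (ux[j + 1] - ux[j]) * pmax(fwd$S[j], R[j + 1])
  any(fwd$ok[j] & suffix_ok[j + 1] & lhs >= rhs - 1e-12)
}

#' Hartigan's dip statistic
#'
#' The maximum distance between the empirical CDF of `x` and the closest
#' unimodal CDF. 0 is returned for constant input; the smallest attainable
#' value for n distinct points is 1/(2n), the largest 0.25.
#'
#' @param x Numeric vector.
#' @param tol Bisection tolerance on the statistic (default 1e-9).
#' @return The dip statistic (a single number in [0, 0.25]).
#' @examples
#' dip_stat(c(0, 1))            # 0.25: two points are maximally bimodal
#' dip_stat(rep(1, 10))         # 0: constant data
#' @export
dip_stat <- function(x, tol = 1e-9) {
  x <- sort(as.numeric(x[!is.na(x)]))
  n <- length(x)
  if (n < 2L || x[1] == x[n]) return(0)
  ux <- unique(x)
  cnt <- tabulate(match(x, ux))
  cum <- cumsum(cnt)
  flo <- (cum - cnt) / n
  fhi <- cum / n
  dlo <- 1 / (2 * n)
  if (.dip_feasible(ux, flo, fhi, dlo)) return(dlo)
  dhi <- 0.25
  if (!.dip_feasible(ux, flo, fhi, dhi)) dhi <- 0.5
  while (dhi - dlo > tol) {
    mid <- (dlo + dhi) / 2
    if (.dip_feasible(ux, flo, fhi, mid)) dhi <- mid else dlo <- mid
  }
  dhi
}

#' Null distribution of the dip statistic
#'
#' Dip statistics of `n_boot` uniform(0, 1) samples of size `n`, the
#' standard reference distribution for the dip test. Computing the table
#' once and passing it to [dip_test()] amortizes the bootstrap across
#' repeated tests at the same sample size.
#'
#' @param n Sample size.
#' @param n_boot Number of bootstrap samples (default 2000).
#' @param seed Optional seed.
#' @return Numeric vector of `n_boot` dip statistics.
#' @export
dip_null <- function(n, n_boot = 2000, seed = NULL) {
  draw <- function() vapply(seq_len(n_boot),
                            function(i) dip_stat(runif(n)), numeric(1))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Dip test of unimodality
#'
#' Tests the null hypothesis that the values are drawn from a unimodal
#' distribution. The p-value is the fraction of uniform(0, 1) bootstrap
#' samples of the same size whose dip statistic is at least the observed
#' one.
#'
#' @param values Numeric vector (at least 4 non-missing values for a
#'   meaningful test).
#' @param n_boot Bootstrap samples (default 2000); ignored when
#'   `null_dips` is given.
#' @param seed Optional seed for the bootstrap.
#' @param null_dips Optional precomputed [dip_null()] table for
#'   `length(values)`.
#' @return A list with `dip`, `p_value`, `n` and `n_boot`.
#' @examples
#' dip_test(c(rnorm(50, 0, 0.1), rnorm(50, 5, 0.1)), n_boot = 200,
#'          seed = 1)$p_value  # strongly bimodal: small p
#' @export
dip_test <- function(values, n_boot = 2000, seed = NULL, null_dips = NULL) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 4L) warning("dip test on fewer than 4 values")
  d <- dip_stat(values)
  if (d == 0) {
    return(list(dip = 0, p_value = 1, n = n,
                n_boot = length(null_dips) %||% n_boot))
  }
  if (is.null(null_dips)) null_dips <- dip_null(n, n_boot, seed)
  list(dip = d, p_value = mean(null_dips >= d), n = n,
       n_boot = length(null_dips))
}
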