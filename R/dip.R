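# Hartigan & Hartigan dip statistic.
#
# The dip of an empirical CDF F_n is the smallest sup-norm distance between
# F_n and any unimodal CDF. It is computed by the classical iterative
# greatest-convex-minorant / least-concave-majorant algorithm: the candidate
# modal interval is shrunk while tracking the largest deviation of F_n from
# the convex fit to its left and the concave fit to its right; outside the
# modal interval a unimodal CDF can split a deviation of size d into d/2 by
# running midway between F_n and its convex (concave) hull.
#
# Conventions: the GCM is fitted to the lower staircase corners
# (x_i, (i-1)/n) and the LCM to the upper corners (x_i, i/n); all deviations
# are halved at the end. Validated against a brute-force linear-programming
# minimization over piecewise-linear unimodal CDFs.

# Greatest convex minorant touch points of (xs, ys) as an index vector
# (increasing); ys evaluated at all points via linear interpolation.
.gcm_fit <- function(xs, ys) {
  n <- length(xs)
  idx <- c(1L)
  for (j in 2:n) {
    while (length(idx) >= 2) {
      a <- idx[length(idx) - 1L]; b <- idx[length(idx)]
      # drop b if it lies above chord a--j
      if ((ys[b] - ys[a]) * (xs[j] - xs[a]) >=
          (ys[j] - ys[a]) * (xs[b] - xs[a])) {
        idx <- idx[-length(idx)]
      } else break
    }
    idx <- c(idx, j)
  }
  idx
}

.lcm_fit <- function(xs, ys) {
  n <- length(xs)
  idx <- c(1L)
  for (j in 2:n) {
    while (length(idx) >= 2) {
      a <- idx[length(idx) - 1L]; b <- idx[length(idx)]
      if ((ys[b] - ys[a]) * (xs[j] - xs[a]) <=
          (ys[j] - ys[a]) * (xs[b] - xs[a])) {
        idx <- idx[-length(idx)]
      } else break
    }
    idx <- c(idx, j)
  }
  idx
}

# Interpolate fit (touch indices `tp` into xs/ys) at positions `at` (indices).
.fit_interp <- function(xs, ys, tp, at) {
  approx(xs[tp], ys[tp], xout = xs[at], ties = "ordered")$y
}

#' Hartigan's dip statistic
#'
#' The maximum distance between the empirical CDF of `x` and the closest
#' unimodal CDF, computed by the greatest-convex-minorant /
#' least-concave-majorant algorithm. Larger values indicate multimodality;
#' the minimum attainable value is `1/(2n)`.
#'
#' @param x Numeric vector with at least 4 finite values, not all identical.
#' @return The dip statistic (scalar in `[1/(2n), 0.25]`).
#' @export
dip_stat <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("dip requires at least 4 finite values")
  if (max(x) == min(x)) stop("dip undefined for constant data")
  tabulated <- table(x)
  xs <- as.numeric(names(tabulated))        # unique sorted values
  P <- cumsum(as.integer(tabulated)) / n
  k <- length(xs)
  lo_y <- c(0, P[-k])            # GCM corners: F(u_i^-)
  hi_y <- P                      # LCM corners: F(u_i)
  lo <- 1L; hi <- k
  D <- 0
  repeat {
    idx <- lo:hi
    gcm <- idx[.gcm_fit(xs[idx], lo_y[idx])]
    lcm <- idx[.lcm_fit(xs[idx], hi_y[idx])]
    # largest gap between the LCM curve and the GCM curve on [lo, hi],
    # checked at the corners of both fits
    g_at_l <- .fit_interp(xs, lo_y, gcm, lcm)
    l_at_g <- .fit_interp(xs, hi_y, lcm, gcm)
    gap_l <- hi_y[lcm] - g_at_l      # lcm corner above gcm curve
    gap_g <- l_at_g - lo_y[gcm]      # lcm curve above gcm corner
    d <- max(gap_l, gap_g)
    if (d <= D) break
    # modal-interval candidates: tightest [gcm corner, lcm corner] bracket
    # around the argmax
    if (max(gap_g) >= max(gap_l)) {
      j <- gcm[which.max(gap_g)]
      new_lo <- j
      new_hi <- min(lcm[lcm >= j])
    } else {
      j <- lcm[which.max(gap_l)]
      new_hi <- j
      new_lo <- max(gcm[gcm <= j])
    }
    # deviations of F from the convex fit left of the modal interval and
    # from the concave fit right of it
    # The candidate mode may sit exactly at the interval boundary, where a
    # unimodal CDF is allowed to jump; the boundary point's own atom is
    # therefore not charged against the outside fits.
    d_left <- 0
    seg <- gcm[gcm <= new_lo]
    if (length(seg) >= 2) {
      at <- seg[1]:seg[length(seg)]
      fitv <- .fit_interp(xs, lo_y, seg, at)
      dev <- hi_y[at] - fitv
      dev[at == new_lo] <- 0
      d_left <- max(dev, 0)
    }
    d_right <- 0
    seg <- lcm[lcm >= new_hi]
    if (length(seg) >= 2) {
      at <- seg[1]:seg[length(seg)]
      fitv <- .fit_interp(xs, hi_y, seg, at)
      dev <- fitv - lo_y[at]
      dev[at == new_hi] <- 0
      d_right <- max(dev, 0)
    }
    D <- max(D, d_left, d_right)
    if (new_lo == lo && new_hi == hi) break
    lo <- new_lo; hi <- new_hi
    if (hi - lo < 1) break
  }
  max(D / 2, 1 / (2 * n))
}

.dip_null_cache <- new.env(parent = emptyenv())

#' Dip test of unimodality
#'
#' Tests the null of unimodality with Hartigan's dip statistic. The p value
#' is the fraction of `n_boot` seeded uniform(0,1) samples of the same size
#' whose dip is at least the observed one (the null distribution depends
#' only on sample size and is cached per `(n, n_boot, seed)`).
#'
#' @param values Numeric vector (>= 4 finite, non-constant values; otherwise
#'   an error — callers route constant input to the degenerate rule).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Bootstrap seed.
#' @return List with `D` (statistic) and `p`.
#' @export
dip_test <- function(values, n_boot = 1000, seed = 1) {
  values <- values[is.finite(values)]
  if (length(values) < 4) stop("dip test requires at least 4 finite values")
  if (max(values) == min(values)) stop("dip test undefined for constant data")
  D <- dip_stat(values)
  key <- sprintf("n%d_b%d_s%d", length(values), n_boot, as.integer(seed))
  if (is.null(.dip_null_cache[[key]])) {
    .dip_null_cache[[key]] <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) dip_stat(runif(length(values))),
             numeric(1))
    })
  }
  null <- .dip_null_cache[[key]]
  list(D = D, p = mean(null >= D))
}
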