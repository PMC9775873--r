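# Internal numeric helpers shared across the pipeline.

#' Consistency constant for the scaled median absolute deviation
#'
#' Returns the factor that makes the median absolute deviation a consistent
#' estimator of the standard deviation under normality, `1 / qnorm(3/4)`
#' (approximately 1.4826). This is the scaling used by [reject_outliers_mad()].
#'
#' @return A single numeric value.
#' @export
#' @examples
#' mad_scale_constant()
mad_scale_constant <- function() {
  1 / stats::qnorm(0.75)
}

#' Scaled median absolute deviation
#'
#' `scaled_mad(x)` is `mad_scale_constant() * median(|x - median(x)|)`,
#' a robust estimate of spread used by the moving-window outlier rejector.
#' `NA` values are dropped.
#'
#' @param x Numeric vector.
#' @return A single numeric value (`NA` if `x` has no finite values).
#' @export
scaled_mad <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  stats::mad(x, constant = mad_scale_constant())
}

# Indices of strict-or-plateau local maxima of x. A plateau reports its first
# index. Endpoints are never maxima.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # collapse zero slopes to the sign of the next nonzero slope so plateaus work
  s <- sign(d)
  nz <- s != 0
  if (!any(nz)) return(integer(0))
  s_filled <- s
  # propagate the following nonzero sign backwards across zeros
  idx_nz <- which(nz)
  s_filled[!nz] <- s[idx_nz[findInterval(which(!nz), idx_nz) + 1L]]
  s_filled[is.na(s_filled)] <- -1  # trailing plateau: treat as descending
  which(diff(s_filled) == -2) + 1L
}

# Prominence of peaks at indices `peaks` within series x (classic definition:
# height above the higher of the two key saddles bounding the peak).
peak_prominence <- function(x, peaks) {
  if (length(peaks) == 0L) return(numeric(0))
  n <- length(x)
  vapply(peaks, function(p) {
    h <- x[p]
    # walk left until a sample higher than h (or the edge); track the minimum
    left_min <- h
    i <- p - 1L
    while (i >= 1L && x[i] <= h) {
      if (x[i] < left_min) left_min <- x[i]
      i <- i - 1L
    }
    right_min <- h
    i <- p + 1L
    while (i <= n && x[i] <= h) {
      if (x[i] < right_min) right_min <- x[i]
      i <- i + 1L
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

# Enforce a minimum index distance between peaks, keeping higher peaks first.
prune_peaks_min_distance <- function(peaks, heights, min_dist) {
  if (length(peaks) <= 1L) return(peaks)
  ord <- order(heights, decreasing = TRUE)
  keep <- logical(length(peaks))
  taken <- integer(0)
  for (j in ord) {
    p <- peaks[j]
    if (length(taken) == 0L || all(abs(taken - p) >= min_dist)) {
      keep[j] <- TRUE
      taken <- c(taken, p)
    }
  }
  sort(peaks[keep])
}

# Trapezoidal integral of series y (on a uniform 1/fs grid, sample i at time
# (i-1)/fs) between fractional sample positions a and b (1-based, can be
# non-integer). Linear interpolation at the fractional endpoints.
trapz_between <- function(y, a, b, fs) {
  if (b <= a) return(0)
  ia <- ceiling(a)
  ib <- floor(b)
  interp <- function(p) {
    i0 <- floor(p)
    fr <- p - i0
    if (fr == 0) y[i0] else (1 - fr) * y[i0] + fr * y[i0 + 1L]
  }
  total <- 0
  if (ib >= ia) {
    if (ib > ia) {
      yy <- y[ia:ib]
      total <- sum(yy[-length(yy)] + yy[-1L]) / 2
    }
    # partial edges
    if (a < ia) total <- total + (ia - a) * (interp(a) + y[ia]) / 2
    if (b > ib) total <- total + (b - ib) * (y[ib] + interp(b)) / 2
  } else {
    # both endpoints inside one sample interval
    total <- (b - a) * (interp(a) + interp(b)) / 2
  }
  total / fs
}

# Linear interpolation of y (uniform grid, sample i at (i-1)/fs) at time t
# relative to the grid origin.
sample_at_time <- function(y, t, fs) {
  p <- t * fs + 1
  p <- min(max(p, 1), length(y))
  i0 <- floor(p)
  fr <- p - i0
  if (fr == 0) y[i0] else (1 - fr) * y[i0] + fr * y[min(i0 + 1L, length(y))]
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
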