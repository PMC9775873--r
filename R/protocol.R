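# LBNP protocol construction and the reference compensatory reserve metric.

#' Build a ramped LBNP chamber-pressure protocol
#'
#' Constructs the piecewise-linear chamber-pressure time course of a ramped
#' lower-body negative pressure (LBNP) session: a resting baseline at ambient
#' pressure, a depressurization ramp at `down_rate` to the maximal negative
#' pressure `pmax`, and -- when `up_rate` is given -- a repressurization ramp
#' back to ambient followed by a recovery period. Pressures are stored as
#' nonnegative magnitudes of the (negative) chamber pressure, so 0 means
#' ambient and `pmax` the deepest suction applied.
#'
#' @param down_rate Depressurization rate, mmHg/min (positive; typically 3, 6
#'   or 9).
#' @param up_rate Repressurization rate, mmHg/min, or `NULL` for a
#'   depressurization-only session that ends at `pmax`.
#' @param pmax Magnitude of the maximal negative chamber pressure, mmHg, in
#'   (0, 100].
#' @param baseline_duration Baseline phase duration, seconds (default 300).
#' @param recovery_duration Recovery phase duration, seconds (default 600);
#'   only present when `up_rate` is given.
#' @param sample_interval Spacing of the returned trace samples, seconds.
#'
#' @return A data frame of class `lbnp_trace` with columns `time_s`,
#'   `pressure_mmhg` (magnitude, >= 0) and `phase` (one of `"baseline"`,
#'   `"depressurization"`, `"repressurization"`, `"recovery"`), and attributes
#'   `pmax`, `down_rate`, `up_rate`.
#' @export
#' @examples
#' tr <- build_protocol(down_rate = 6, up_rate = 6, pmax = 60)
#' range(tr$pressure_mmhg)
build_protocol <- function(down_rate, up_rate = NULL, pmax,
                           baseline_duration = 300,
                           recovery_duration = 600,
                           sample_interval = 1) {
  if (!is.numeric(down_rate) || length(down_rate) != 1L || down_rate <= 0)
    stop_invalid("`down_rate` must be a single positive rate in mmHg/min (got %s)",
                 format(down_rate))
  if (!is.null(up_rate) && (!is.numeric(up_rate) || length(up_rate) != 1L || up_rate <= 0))
    stop_invalid("`up_rate` must be NULL or a single positive rate in mmHg/min")
  if (!is.numeric(pmax) || length(pmax) != 1L || pmax <= 0 || pmax > 100)
    stop_invalid("`pmax` must lie in (0, 100] mmHg (got %s)", format(pmax))
  if (baseline_duration < 0 || recovery_duration < 0 || sample_interval <= 0)
    stop_invalid("durations must be nonnegative and `sample_interval` positive")

  down_per_s <- down_rate / 60
  t_down <- pmax / down_per_s
  t1 <- baseline_duration
  t2 <- t1 + t_down
  if (is.null(up_rate)) {
    t_end <- t2
  } else {
    up_per_s <- up_rate / 60
    t_up <- pmax / up_per_s
    t3 <- t2 + t_up
    t_end <- t3 + recovery_duration
  }

  times <- seq(0, t_end, by = sample_interval)
  # make sure every phase breakpoint is on the grid so the trace is exactly
  # piecewise linear
  brk <- c(t1, t2, if (!is.null(up_rate)) t3, t_end)
  times <- sort(unique(c(times, brk)))

  p <- numeric(length(times))
  phase <- character(length(times))
  in_base <- times < t1
  phase[in_base] <- "baseline"
  in_down <- !in_base & times <= t2
  phase[in_down] <- "depressurization"
  p[in_down] <- pmin((times[in_down] - t1) * down_per_s, pmax)
  if (!is.null(up_rate)) {
    in_up <- times > t2 & times <= t3
    phase[in_up] <- "repressurization"
    p[in_up] <- pmax(pmax - (times[in_up] - t2) * up_per_s, 0)
    in_rec <- times > t3
    phase[in_rec] <- "recovery"
  }
  # guard against floating-point overshoot at the ramp apex
  p[which.max(p)] <- pmax

  out <- data.frame(time_s = times, pressure_mmhg = p, phase = phase,
                    stringsAsFactors = FALSE)
  attr(out, "pmax") <- pmax
  attr(out, "down_rate") <- down_rate
  attr(out, "up_rate") <- if (is.null(up_rate)) NA_real_ else up_rate
  class(out) <- c("lbnp_trace", "data.frame")
  out
}

#' Reference compensatory reserve from chamber pressure
#'
#' The reference CRM at time t is `(1 - P(t)/Pmax) * 100` percent, where P is
#' the magnitude of the negative chamber pressure and Pmax the maximum
#' pressure sustained in the session. It is 100% at ambient pressure
#' (normovolemia) and 0% at `Pmax` (decompensation).
#'
#' @param trace An `lbnp_trace` from [build_protocol()], or a numeric vector
#'   of pressure magnitudes.
#' @param pmax Maximum sustained pressure magnitude, mmHg. Defaults to the
#'   trace's own `pmax` attribute (per-session maximum).
#' @return Numeric vector of CRM percentages in \[0, 100\], one per trace
#'   sample.
#' @export
#' @examples
#' compute_reference_crm(c(0, 30, 45, 60), pmax = 60)
compute_reference_crm <- function(trace, pmax = NULL) {
  p <- if (is.data.frame(trace)) trace$pressure_mmhg else trace
  if (is.null(pmax)) pmax <- attr(trace, "pmax")
  if (is.null(pmax) || !is.numeric(pmax) || pmax <= 0)
    stop_invalid("`pmax` must be a positive pressure magnitude in mmHg")
  if (any(p < 0)) stop_invalid("pressure magnitudes must be nonnegative")
  if (any(p > pmax + 1e-9))
    stop_invalid("pressure magnitude exceeds pmax (%.3f > %.3f): truth inconsistency",
                 max(p), pmax)
  (1 - p / pmax) * 100
}

# CRM value(s) at arbitrary session time(s), by linear interpolation of the
# protocol trace (rule 2: clamped at the ends).
crm_at_time <- function(trace, t) {
  crm <- compute_reference_crm(trace)
  stats::approx(trace$time_s, crm, xout = t, rule = 2)$y
}

# Phase label at arbitrary session time(s): the phase of the trace sample
# whose interval contains t (right edge owns the sample).
phase_at_time <- function(trace, t) {
  i <- findInterval(t, trace$time_s, rightmost.closed = TRUE)
  i[i < 1L] <- 1L
  trace$phase[i]
}
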