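#' Pesticide application regime
#'
#' Describes how pesticide-induced mortality is scheduled over the growing
#' season. Four modes are supported: `"none"` (untreated control),
#' `"pulse"` (1-day applications at fixed intervals, first application at
#' the start of the season), `"threshold"` (1-day applications triggered
#' whenever the pest density at a monitoring time strictly exceeds a
#' threshold) and `"continuous"` (constant mortality, e.g. systemic
#' pesticides or treated seed).
#'
#' @param mode One of `"none"`, `"pulse"`, `"threshold"`, `"continuous"`.
#' @param p Pest mortality while the pesticide acts (1/day).
#' @param q Enemy mortality relative to the pest (ratio).
#' @param s Alternative-prey mortality relative to the pest (ratio; food
#'   web model only).
#' @param interval Days between pulse applications (pulse mode).
#' @param pulse_duration Days a pulse acts (default 1).
#' @param monitor_interval Days between density checks (threshold mode).
#' @param threshold_density Pest density that triggers a spray (200/m2 for
#'   the basic model; 0.5 for the food web model).
#' @param season_length Season length in days.
#' @return An object of class `"pesticide_regime"`.
#' @examples
#' pesticide_regime("pulse", p = 1, q = 0.5, interval = 14)
#' @export
pesticide_regime <- function(mode = c("none", "pulse", "threshold", "continuous"),
                             p = 0, q = 0, s = 0,
                             interval = 14, pulse_duration = 1,
                             monitor_interval = 6, threshold_density = 200,
                             season_length = 100) {
  mode <- match.arg(mode)
  if (p < 0 || q < 0 || s < 0) stop("p, q and s must be >= 0")
  if (pulse_duration < 0) stop("pulse_duration must be >= 0")
  if (mode == "pulse" && interval < pulse_duration)
    stop("interval must be >= pulse_duration")
  if (monitor_interval <= 0) stop("monitor_interval must be > 0")
  if (threshold_density <= 0) stop("threshold_density must be > 0")
  if (season_length <= 0) stop("season_length must be > 0")
  structure(list(mode = mode, p = p, q = q, s = s, interval = interval,
                 pulse_duration = pulse_duration,
                 monitor_interval = monitor_interval,
                 threshold_density = threshold_density,
                 season_length = season_length),
            class = "pesticide_regime")
}

#' @export
print.pesticide_regime <- function(x, ...) {
  cat("Pesticide regime:", x$mode, "\n")
  cat(sprintf("  p = %g/day, q = %g, s = %g\n", x$p, x$q, x$s))
  if (x$mode == "pulse")
    cat(sprintf("  every %g days for %g day(s)\n", x$interval, x$pulse_duration))
  if (x$mode == "threshold")
    cat(sprintf("  monitor every %g days, threshold %g\n",
                x$monitor_interval, x$threshold_density))
  cat(sprintf("  season %g days\n", x$season_length))
  invisible(x)
}

new_windows <- function(start = numeric(0), end = numeric(0),
                        cause = character(0)) {
  data.frame(start = start, end = end, cause = cause,
             stringsAsFactors = FALSE)
}

#' Scheduled application windows for a pulsed regime
#'
#' Pulses start at `t = 0` and recur every `interval` days; each acts for
#' `pulse_duration` days over the half-open window `[start, start + d)`.
#' Windows whose start lies inside the season are kept, truncated at the
#' season end if necessary.
#'
#' @param regime A [pesticide_regime()] with `mode = "pulse"`.
#' @return A data frame of application windows with columns `start`, `end`
#'   and `cause`.
#' @examples
#' r <- pesticide_regime("pulse", p = 1, interval = 14, season_length = 100)
#' build_pulse_schedule(r)  # 8 windows: starts 0, 14, ..., 98
#' @export
build_pulse_schedule <- function(regime) {
  if (regime$mode != "pulse") stop("regime mode must be 'pulse'")
  if (regime$interval < regime$pulse_duration)
    stop("interval must be >= pulse_duration")
  starts <- seq(0, regime$season_length, by = regime$interval)
  starts <- starts[starts < regime$season_length]
  ends <- pmin(starts + regime$pulse_duration, regime$season_length)
  keep <- ends > starts
  new_windows(starts[keep], ends[keep], rep("scheduled", sum(keep)))
}

#' Convert an application frequency to an application interval
#'
#' Maps a frequency `f` in `[0, 1]` ("none" at 0 to "daily" at 1) to a
#' pulse interval `T = season_length * (1 - f)` days, clamped to
#' `[1, season_length]`. The mapping reproduces the anchor that a
#' frequency of 0.86 in a 100-day season corresponds to an application
#' every 14 days. `f = 0` means no application at all (`Inf`).
#'
#' @param f Application frequency in `[0, 1]`.
#' @param season_length Season length in days.
#' @return Interval in days (`Inf` for `f = 0`).
#' @examples
#' frequency_to_interval(0.86, 100)  # 14
#' @export
frequency_to_interval <- function(f, season_length = 100) {
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]")
  ifelse(f == 0, Inf, pmin(pmax(season_length * (1 - f), 1), season_length))
}

#' Spray decision at a monitoring time of a threshold regime
#'
#' At each monitoring time (multiples of `monitor_interval`, starting at
#' `t = 0`) the pest density is assessed; a 1-day spray starting at the
#' monitoring time is triggered if, and only if, the density strictly
#' exceeds `threshold_density` ("surpassed" read as strict, so ties do not
#' trigger). Monitoring continues every `monitor_interval` days whether or
#' not earlier sprays occurred.
#'
#' @param traj_so_far A `trajectory` (see [simulate_season()]) covering
#'   `t_check`, or a single pest density.
#' @param regime A [pesticide_regime()] with `mode = "threshold"`.
#' @param t_check The monitoring time (days).
#' @return A one-row window data frame (`cause = "threshold-triggered"`)
#'   if a spray is triggered, otherwise a zero-row window data frame.
#' @export
threshold_controller <- function(traj_so_far, regime, t_check) {
  dens <- if (is.numeric(traj_so_far) && length(traj_so_far) == 1L) {
    traj_so_far
  } else {
    v <- attr(traj_so_far, "pest_variable")
    if (is.null(v)) v <- if ("N" %in% names(traj_so_far)) "N" else "N1"
    i <- which.min(abs(traj_so_far$time - t_check))
    traj_so_far[[v]][i]
  }
  if (dens > regime$threshold_density) {
    new_windows(t_check, min(t_check + regime$pulse_duration,
                             regime$season_length), "threshold-triggered")
  } else {
    new_windows()
  }
}

#' Mortality acting at a given time under realized application windows
#'
#' @param t Time in days, within `[0, season_length]`.
#' @param windows Realized application windows (data frame with `start`,
#'   `end`); half-open: `t` in `[start, end)` is active.
#' @param regime The governing [pesticide_regime()].
#' @return A [mortality_input()] with `p_now = regime$p` if `t` lies in an
#'   active window or the mode is continuous, else `p_now = 0`.
#' @export
mortality_at <- function(t, windows, regime) {
  active <- regime$mode == "continuous" ||
    (nrow(windows) > 0 && any(windows$start <= t & t < windows$end))
  mortality_input(p_now = if (active) regime$p else 0,
                  q = regime$q, s = regime$s)
}
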