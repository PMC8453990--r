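# Season-long integration under a pesticide regime, plus the summary
# diagnostics: time averages, cumulative averages, crossover generation,
# resurgence intervals and predator extinction.

rhs_for <- function(params) {
  if (inherits(params, "rm_params")) {
    function(t, y, parms) {
      N <- y[1]; P <- y[2]
      dN <- parms$r * N * (1 - N / parms$K) -
        parms$a * N * P / (N + parms$D) - parms$p_now * N
      dP <- parms$a * parms$c * N * P / (N + parms$D) -
        parms$m * P - parms$p_now * parms$q * P
      list(c(dN, dP))
    }
  } else {
    function(t, y, parms) {
      R <- y[1]; N1 <- y[2]; N2 <- y[3]; P <- y[4]
      w <- parms$omega
      den <- w * N1 + (1 - w) * N2 + parms$N0
      fR1 <- R / (R + parms$R01)
      fR2 <- R / (R + parms$R02)
      dR <- R * (1 - R / parms$K) -
        parms$xN1 * parms$yN1 * fR1 * N1 - parms$xN2 * parms$yN2 * fR2 * N2
      dN1 <- -parms$xN1 * N1 * (1 - parms$yN1 * fR1) -
        w * parms$xP * parms$yP * N1 * P / den - parms$p_now * N1
      dN2 <- -parms$xN2 * N2 * (1 - parms$yN2 * fR2) -
        (1 - w) * parms$xP * parms$yP * N2 * P / den -
        parms$p_now * parms$s * N2
      dP <- -parms$xP * P *
        (1 - (w * parms$yP * N1 + (1 - w) * parms$yP * N2) / den) -
        parms$p_now * parms$q * P
      list(c(dR, dN1, dN2, dP))
    }
  }
}

# Integrate one segment with constant mortality; returns matrix on the grid.
integrate_segment <- function(rhs, y, t0, t1, parms, output_step, rel_tol,
                              abs_tol) {
  grid <- seq(ceiling(t0 / output_step), floor(t1 / output_step)) * output_step
  tt <- sort(unique(c(t0, grid[grid > t0 & grid < t1], t1)))
  sol <- deSolve::lsoda(y, tt, rhs, parms, rtol = rel_tol, atol = abs_tol)
  if (attr(sol, "istate")[1] < 0)
    stop("solver failure in [", t0, ", ", t1, "]; last good state: ",
         paste(signif(sol[nrow(sol), -1], 6), collapse = ", "))
  sol
}

#' Simulate a season of pest-enemy dynamics under a pesticide regime
#'
#' Integrates the basic predator-prey model or the food web model over the
#' season with event-split integration: the solver is stopped and
#' restarted at every application-window boundary (and at monitoring times
#' for threshold regimes), so 1-day mortality pulses act exactly over
#' their windows while the dynamics continue. Densities are reported on a
#' regular output grid; components below `1e-12` are clamped to 0 at
#' output time.
#'
#' @param params An [rm_params()] or [foodweb_params()] object.
#' @param regime A [pesticide_regime()].
#' @param initial_state Named state vector; defaults to
#'   [default_initial_state()].
#' @param season_length Season length in days (default: the regime's).
#' @param output_step Output grid step in days (default 0.05, resolving a
#'   1-day pulse by 20 points).
#' @param rel_tol,abs_tol Solver tolerances.
#' @return A `trajectory`: a data frame with column `time` and one column
#'   per state variable, with attributes `windows` (realized application
#'   windows), `regime`, `params`, `pest_variable`, `predator_variable`.
#' @examples
#' ctrl <- simulate_season(rm_params(), pesticide_regime("none"))
#' trt <- simulate_season(rm_params(),
#'   pesticide_regime("pulse", p = 1, q = 0.5, interval = 14))
#' crossover_generation(trt, ctrl)
#' @export
simulate_season <- function(params, regime,
                            initial_state = default_initial_state(params),
                            season_length = regime$season_length,
                            output_step = 0.05,
                            rel_tol = 1e-8, abs_tol = 1e-10) {
  stopifnot(inherits(params, "model_params"),
            inherits(regime, "pesticide_regime"))
  if (output_step > 0.1) stop("output_step must be <= 0.1")
  vars <- if (inherits(params, "rm_params")) c("N", "P")
          else c("R", "N1", "N2", "P")
  check_state(initial_state, vars)
  y0 <- initial_state[vars]
  rhs <- rhs_for(params)
  parms <- unclass(params)
  parms$q <- regime$q; parms$s <- regime$s

  windows <- switch(regime$mode,
    none = new_windows(),
    pulse = {
      w <- build_pulse_schedule(regime)
      w[w$start < season_length, , drop = FALSE]
    },
    continuous = new_windows(0, season_length, "continuous"),
    threshold = NULL)  # built on the fly below

  if (regime$mode != "threshold") {
    bks <- sort(unique(c(0, season_length,
                         windows$start[windows$start < season_length],
                         pmin(windows$end, season_length))))
    out <- NULL; y <- y0
    for (i in seq_len(length(bks) - 1)) {
      t0 <- bks[i]; t1 <- bks[i + 1]
      parms$p_now <- mortality_at(t0, windows, regime)$p_now
      sol <- integrate_segment(rhs, y, t0, t1, parms, output_step,
                               rel_tol, abs_tol)
      y <- as.numeric(sol[nrow(sol), -1])
      out <- rbind(out, sol[if (i == 1) seq_len(nrow(sol)) else -1, ,
                            drop = FALSE])
    }
  } else {
    monitor <- seq(0, season_length, by = regime$monitor_interval)
    windows <- new_windows()
    out <- NULL; y <- y0; t <- 0
    pest_idx <- which(vars == pest_variable(params))
    while (t < season_length) {
      # spray decision at the monitoring time t
      w <- threshold_controller(y[pest_idx], regime, t)
      if (nrow(w) > 0) windows <- rbind(windows, w)
      t_next <- min(monitor[monitor > t], season_length)
      bks <- sort(unique(c(t, t_next,
                           windows$end[windows$end > t & windows$end < t_next])))
      for (i in seq_len(length(bks) - 1)) {
        parms$p_now <- mortality_at(bks[i], windows, regime)$p_now
        sol <- integrate_segment(rhs, y, bks[i], bks[i + 1], parms,
                                 output_step, rel_tol, abs_tol)
        y <- as.numeric(sol[nrow(sol), -1])
        out <- rbind(out, sol[if (is.null(out)) seq_len(nrow(sol)) else -1, ,
                              drop = FALSE])
      }
      t <- t_next
    }
  }

  states <- out[, -1, drop = FALSE]
  if (any(states < -1e-9))
    stop("negative density excursion beyond -1e-9; tighten solver tolerances")
  states[states < 1e-12] <- 0
  traj <- data.frame(time = out[, 1], states)
  names(traj) <- c("time", vars)
  structure(traj,
            windows = windows, regime = regime, params = params,
            pest_variable = pest_variable(params),
            predator_variable = predator_variable(params),
            class = c("trajectory", "data.frame"))
}

#' Realized application windows of a trajectory
#' @param traj A `trajectory`.
#' @return Data frame with columns `start`, `end`, `cause`.
#' @export
application_windows <- function(traj) attr(traj, "windows")

traj_var <- function(traj, variable) {
  if (is.null(variable)) variable <- attr(traj, "pest_variable")
  if (!variable %in% names(traj)) stop("no state variable '", variable, "'")
  variable
}

gen_time <- function(traj) attr(traj, "params")$generation_time

#' Time-averaged density over a window
#'
#' Trapezoidal time integral of a state variable divided by the window
#' length.
#'
#' @param traj A `trajectory`.
#' @param variable State variable name; defaults to the pest variable.
#' @param window Time window `c(t0, t1)` in days; defaults to the whole
#'   trajectory span.
#' @return Average density over the window.
#' @export
time_average <- function(traj, variable = NULL, window = NULL) {
  variable <- traj_var(traj, variable)
  t <- traj$time; x <- traj[[variable]]
  if (is.null(window)) window <- range(t)
  if (window[2] <= window[1]) stop("empty averaging window")
  keep <- t >= window[1] & t <= window[2]
  t <- t[keep]; x <- x[keep]
  sum(diff(t) * (head(x, -1) + tail(x, -1)) / 2) / (t[length(t)] - t[1])
}

#' Cumulative-average series of a state variable
#'
#' Returns `A(t) = (1/t) \int_0^t x(s) ds` on the output grid (trapezoidal
#' rule), with `A(0) = x(0)` as the limiting value.
#'
#' @inheritParams time_average
#' @return Data frame with columns `time` and `cumavg`.
#' @export
cumulative_average <- function(traj, variable = NULL) {
  variable <- traj_var(traj, variable)
  t <- traj$time; x <- traj[[variable]]
  ci <- c(0, cumsum(diff(t) * (head(x, -1) + tail(x, -1)) / 2))
  avg <- ci / (t - t[1])
  avg[1] <- x[1]
  data.frame(time = t, cumavg = avg)
}

#' Crossover generation of treated vs control cumulative averages
#'
#' The first time (expressed in pest generations) at which the cumulative
#' average pest density of the treated arm reaches or exceeds that of the
#' untreated control, linearly interpolated between grid points. Times
#' before 0.1 generations are ignored because both arms share initial
#' conditions and the cumulative average is indeterminate as `t -> 0`.
#'
#' @param treated,control `trajectory` objects on the same grid.
#' @return Crossing time in pest generations; `NA` if the treated
#'   cumulative average never reaches the control's. If the two arms are
#'   numerically identical the degenerate value 0 is returned with
#'   attribute `tie = TRUE`.
#' @export
crossover_generation <- function(treated, control) {
  if (!isTRUE(all.equal(treated$time, control$time)))
    stop("treated and control trajectories must share the output grid")
  gt <- gen_time(treated)
  at <- cumulative_average(treated)$cumavg
  ac <- cumulative_average(control,
                           variable = attr(treated, "pest_variable"))$cumavg
  d <- at - ac
  keep <- treated$time > 0.1 * gt
  if (max(abs(d[keep])) == 0) return(structure(0, tie = TRUE))
  idx <- which(keep & d >= 0)
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1]
  if (i == 1 || d[i] == d[i - 1]) return(treated$time[i] / gt)
  t0 <- treated$time[i - 1]; t1 <- treated$time[i]
  (t0 - d[i - 1] * (t1 - t0) / (d[i] - d[i - 1])) / gt
}

#' Resurgence intervals of a treated arm relative to its control
#'
#' Maximal time intervals during which the instantaneous treated pest
#' density exceeds the control density. Because the treated curve is
#' spiked by the 1-day mortality pulses, times inside active application
#' windows are excluded from the comparison and gaps shorter than one
#' application interval are merged, so the intervals describe the
#' envelope of the treated curve rather than its within-spray dips.
#'
#' @param treated,control `trajectory` objects on the same grid.
#' @param merge_gap Gap length (days) below which adjacent intervals are
#'   merged; defaults to the treated regime's application interval.
#' @return Data frame with columns `start` and `end` in pest generations;
#'   an interval reaching the season end is open-ended.
#' @export
resurgence_intervals <- function(treated, control, merge_gap = NULL) {
  if (!isTRUE(all.equal(treated$time, control$time)))
    stop("treated and control trajectories must share the output grid")
  gt <- gen_time(treated)
  regime <- attr(treated, "regime")
  if (is.null(merge_gap))
    merge_gap <- if (!is.null(regime) && is.finite(regime$interval))
      regime$interval else 14
  v <- attr(treated, "pest_variable")
  t <- treated$time
  w <- application_windows(treated)
  inwin <- rep(FALSE, length(t))
  for (i in seq_len(nrow(w)))
    inwin <- inwin | (t >= w$start[i] & t < w$end[i])
  tt <- t[!inwin]
  above <- (treated[[v]] > control[[v]])[!inwin]
  if (!any(above)) return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  iv <- data.frame(start = tt[starts[r$values]], end = tt[ends[r$values]])
  if (nrow(iv) > 1) {
    merged <- iv[1, ]
    for (i in 2:nrow(iv)) {
      if (iv$start[i] - merged$end[nrow(merged)] < merge_gap)
        merged$end[nrow(merged)] <- iv$end[i]
      else merged <- rbind(merged, iv[i, ])
    }
    iv <- merged
  }
  data.frame(start = iv$start / gt, end = iv$end / gt)
}

#' Is the predator extinct at the end of the season?
#'
#' The predator is classified as extinct when its mean density over the
#' final pest generation falls below `1e-3` (model units; /m2 for the
#' basic model) -- small enough to be unreachable in persistent runs,
#' large enough to absorb numerical dust.
#'
#' @param traj A `trajectory`.
#' @param floor Extinction floor (default `1e-3`).
#' @return Logical flag.
#' @export
is_predator_extinct <- function(traj, floor = 1e-3) {
  gt <- gen_time(traj)
  t_end <- max(traj$time)
  time_average(traj, attr(traj, "predator_variable"),
               c(t_end - gt, t_end)) < floor
}

#' Season summary of a treated/control pair
#'
#' Computes the season-long time-averaged densities, cumulative-average
#' series, crossover generation, resurgence intervals and the predator
#' extinction flag for a treated trajectory, optionally against an
#' untreated control.
#'
#' @param treated A `trajectory`.
#' @param control Optional control `trajectory` on the same grid.
#' @return An object of class `"season_summary"`: a list with elements
#'   `avg` (named vector of season averages), `cumavg` (data frame),
#'   `crossover_gen`, `resurgence` (data frame in generations),
#'   `predator_extinct` and `extinction_floor`.
#' @export
season_summary <- function(treated, control = NULL) {
  vars <- setdiff(names(treated), "time")
  avg <- vapply(vars, function(v) time_average(treated, v), numeric(1))
  cum <- cumulative_average(treated)
  out <- list(
    avg = avg,
    cumavg = cum,
    crossover_gen = if (!is.null(control))
      crossover_generation(treated, control) else NA_real_,
    resurgence = if (!is.null(control))
      resurgence_intervals(treated, control) else NULL,
    predator_extinct = is_predator_extinct(treated),
    extinction_floor = 1e-3)
  structure(out, class = "season_summary")
}

#' @export
print.season_summary <- function(x, ...) {
  cat("Season summary\n  averages:\n")
  print(round(x$avg, 4))
  if (!is.na(x$crossover_gen))
    cat("  crossover at", round(x$crossover_gen, 3), "generations\n")
  if (!is.null(x$resurgence) && nrow(x$resurgence) > 0) {
    cat("  resurgence intervals (generations):\n")
    print(round(x$resurgence, 3))
  }
  cat("  predator extinct:", x$predator_extinct, "\n")
  invisible(x)
}

#' Write a trajectory and its application windows to CSV
#'
#' @param traj A `trajectory`.
#' @param path Path for the trajectory CSV (columns: `time`, one per state
#'   variable). The realized application windows are written alongside to
#'   `<path base>_windows.csv` (columns `start`, `end`, `cause`).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  wpath <- sub("(\\.csv)?$", "_windows.csv", path)
  utils::write.csv(application_windows(traj), wpath, row.names = FALSE)
  invisible(path)
}
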