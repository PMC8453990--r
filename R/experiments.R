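# Parameter sweeps over pesticide mortality, application frequency,
# threshold-triggered and continuous regimes, alternative-prey
# sensitivity, and initial pest-enemy ratios. Sweeps emit tidy
# long-format data frames (one row per grid cell) so figure reproduction
# is a pure plotting step; each grid carries a single no-pesticide
# reference computed once.

sweep_cell <- function(params, regime, initial_state, output_step = 0.05) {
  traj <- simulate_season(params, regime, initial_state,
                          output_step = output_step)
  sprays <- nrow(application_windows(traj))
  c(avg_pest = time_average(traj, pest_variable(params)),
    avg_predator = time_average(traj, predator_variable(params)),
    predator_extinct = as.numeric(is_predator_extinct(traj)),
    sprays = sprays)
}

sweep_reference <- function(params, initial_state, season_length = 100,
                            output_step = 0.05) {
  ctrl <- simulate_season(params, pesticide_regime("none",
                                                   season_length = season_length),
                          initial_state, output_step = output_step)
  c(avg_pest = time_average(ctrl, pest_variable(params)),
    avg_predator = time_average(ctrl, predator_variable(params)))
}

finish_sweep <- function(rows, ref, swept) {
  out <- do.call(rbind, rows)
  structure(as.data.frame(out), reference = ref, swept = swept,
            class = c("sweep_grid", "data.frame"))
}

#' No-pesticide reference of a sweep grid
#' @param grid A sweep result.
#' @return Named vector with `avg_pest` and `avg_predator` of the
#'   untreated reference run.
#' @export
sweep_reference_value <- function(grid) attr(grid, "reference")

#' Sweep pulsed pesticide mortality
#'
#' Average pest and predator densities over five pest generations for
#' 1-day pulse applications every `interval` days, on a grid of pest
#' mortality `p` crossed with relative enemy mortality `q`.
#'
#' @param params A `model_params` object.
#' @param q_levels Relative enemy mortalities (default 0, 0.5, 1, 1.5, 2).
#' @param p_grid Pest mortalities in `[0, 3]` (default step 0.1).
#' @param interval Days between pulses (default 14).
#' @param initial_state Initial densities (model defaults).
#' @param season_length Season length in days.
#' @param output_step Output grid step (days).
#' @return A `sweep_grid` data frame with columns `p`, `q`, `avg_pest`,
#'   `avg_predator`, `predator_extinct`, `sprays`; the no-pesticide
#'   reference is in [sweep_reference_value()].
#' @export
sweep_pulse_p <- function(params, q_levels = c(0, 0.5, 1, 1.5, 2),
                          p_grid = seq(0, 3, by = 0.1), interval = 14,
                          initial_state = default_initial_state(params),
                          season_length = 100, output_step = 0.05) {
  ref <- sweep_reference(params, initial_state, season_length, output_step)
  rows <- list()
  for (q in q_levels) for (p in p_grid) {
    reg <- pesticide_regime(if (p == 0) "none" else "pulse", p = p, q = q,
                            interval = interval,
                            season_length = season_length)
    rows[[length(rows) + 1]] <-
      c(p = p, q = q, sweep_cell(params, reg, initial_state, output_step))
  }
  finish_sweep(rows, ref, "p")
}

#' Sweep pesticide application frequency
#'
#' As [sweep_pulse_p()] but at fixed pest mortality `p`, varying the
#' application frequency from none (0) to daily (1) via
#' [frequency_to_interval()].
#'
#' @inheritParams sweep_pulse_p
#' @param f_grid Frequencies in `[0, 1]` (default step 0.02).
#' @param p Pest mortality while a pulse acts (default 1/day).
#' @return A `sweep_grid` with columns `f`, `q` and the cell summaries.
#' @export
sweep_frequency <- function(params, q_levels = c(0, 0.5, 1, 1.5, 2),
                            f_grid = seq(0, 1, by = 0.02), p = 1,
                            initial_state = default_initial_state(params),
                            season_length = 100, output_step = 0.05) {
  ref <- sweep_reference(params, initial_state, season_length, output_step)
  rows <- list()
  for (q in q_levels) for (f in f_grid) {
    if (f == 0) {
      reg <- pesticide_regime("none", season_length = season_length)
    } else {
      reg <- pesticide_regime("pulse", p = p, q = q,
                              interval = frequency_to_interval(f, season_length),
                              season_length = season_length)
    }
    rows[[length(rows) + 1]] <-
      c(f = f, q = q, sweep_cell(params, reg, initial_state, output_step))
  }
  finish_sweep(rows, ref, "f")
}

#' Sweep pesticide mortality under threshold-triggered application
#'
#' Sprays are applied for 1 day whenever the pest density at a 6-day
#' monitoring time exceeds the threshold (200/m2 for the basic model, 0.5
#' for the food web model). Spray counts per cell are recorded.
#'
#' @inheritParams sweep_pulse_p
#' @param threshold_density Triggering density; defaults to 200 for the
#'   basic model and 0.5 for the food web model.
#' @param monitor_interval Days between density checks (default 6).
#' @return A `sweep_grid` with columns `p`, `q` and the cell summaries
#'   (including `sprays`).
#' @export
sweep_threshold <- function(params, q_levels = c(0, 0.5, 1, 1.5, 2),
                            p_grid = seq(0, 3, by = 0.1),
                            threshold_density = if (inherits(params, "rm_params")) 200 else 0.5,
                            monitor_interval = 6,
                            initial_state = default_initial_state(params),
                            season_length = 100, output_step = 0.05) {
  ref <- sweep_reference(params, initial_state, season_length, output_step)
  rows <- list()
  for (q in q_levels) for (p in p_grid) {
    reg <- pesticide_regime("threshold", p = p, q = q,
                            monitor_interval = monitor_interval,
                            threshold_density = threshold_density,
                            season_length = season_length)
    rows[[length(rows) + 1]] <-
      c(p = p, q = q, sweep_cell(params, reg, initial_state, output_step))
  }
  finish_sweep(rows, ref, "p")
}

#' Sweep continuous (systemic) pesticide mortality
#'
#' Pesticide acts as a constant mortality over the whole season,
#' representing systemic compounds or treated seed; `p` is swept over
#' `[0, 0.3]`.
#'
#' @inheritParams sweep_pulse_p
#' @param p_grid Pest mortalities in `[0, 0.3]` (default step 0.01).
#' @return A `sweep_grid` with columns `p`, `q` and the cell summaries.
#' @export
sweep_continuous <- function(params, q_levels = c(0, 0.5, 1, 1.5, 2),
                             p_grid = seq(0, 0.3, by = 0.01),
                             initial_state = default_initial_state(params),
                             season_length = 100, output_step = 0.05) {
  ref <- sweep_reference(params, initial_state, season_length, output_step)
  rows <- list()
  for (q in q_levels) for (p in p_grid) {
    reg <- pesticide_regime(if (p == 0) "none" else "continuous", p = p,
                            q = q, season_length = season_length)
    rows[[length(rows) + 1]] <-
      c(p = p, q = q, sweep_cell(params, reg, initial_state, output_step))
  }
  finish_sweep(rows, ref, "p")
}

#' Sweep alternative-prey pesticide sensitivity in the food web model
#'
#' Runs the food web model with the alternative prey present
#' (`N2(0) = 0.2`) over a grid of `(p or f, q, s)` for one of the four
#' application regimes, where `s` scales the pesticide-induced mortality
#' of the alternative prey relative to the pest.
#'
#' @param params A [foodweb_params()] object.
#' @param s_levels Alternative-prey relative mortalities (default 0, 0.5, 1).
#' @param regime_mode One of `"pulse"`, `"frequency"`, `"threshold"`,
#'   `"continuous"`.
#' @param q_levels Relative enemy mortalities.
#' @param grid Grid for the swept axis: `p` values (pulse/threshold:
#'   `[0, 3]`; continuous: `[0, 0.3]`) or frequencies (frequency mode).
#' @param p Pest mortality for the frequency mode (default 1/day).
#' @inheritParams sweep_pulse_p
#' @return A `sweep_grid` with columns `s`, `q`, the swept axis and the
#'   cell summaries.
#' @export
sweep_alt_prey <- function(params, s_levels = c(0, 0.5, 1),
                           regime_mode = c("pulse", "frequency", "threshold",
                                           "continuous"),
                           q_levels = c(0, 0.5, 1, 1.5, 2),
                           grid = NULL, p = 1,
                           season_length = 100, output_step = 0.05) {
  if (!inherits(params, "foodweb_params"))
    stop("sweep_alt_prey requires the food web model")
  regime_mode <- match.arg(regime_mode)
  if (is.null(grid))
    grid <- switch(regime_mode,
                   pulse = , threshold = seq(0, 3, by = 0.1),
                   frequency = seq(0, 1, by = 0.02),
                   continuous = seq(0, 0.3, by = 0.01))
  init <- default_initial_state(params, alt_prey = TRUE)
  ref <- sweep_reference(params, init, season_length, output_step)
  rows <- list()
  for (s in s_levels) for (q in q_levels) for (g in grid) {
    reg <- switch(regime_mode,
      pulse = pesticide_regime(if (g == 0) "none" else "pulse", p = g, q = q,
                               s = s, interval = 14,
                               season_length = season_length),
      frequency = if (g == 0)
        pesticide_regime("none", season_length = season_length)
      else pesticide_regime("pulse", p = p, q = q, s = s,
                            interval = frequency_to_interval(g, season_length),
                            season_length = season_length),
      threshold = pesticide_regime("threshold", p = g, q = q, s = s,
                                   threshold_density = 0.5,
                                   season_length = season_length),
      continuous = pesticide_regime(if (g == 0) "none" else "continuous",
                                    p = g, q = q, s = s,
                                    season_length = season_length))
    row <- c(s = s, q = q, g, sweep_cell(params, reg, init, output_step))
    names(row)[3] <- if (regime_mode == "frequency") "f" else "p"
    rows[[length(rows) + 1]] <- row
  }
  finish_sweep(rows, ref, if (regime_mode == "frequency") "f" else "p")
}

#' Sweep initial pest-enemy ratios under continuous application
#'
#' Varies the initial predator density relative to the pest while keeping
#' the default initial pest density, under constant (continuous)
#' pesticide application, to probe the sensitivity of season summaries to
#' starting conditions.
#'
#' @param params A `model_params` object.
#' @param ratio_grid Initial enemy:pest density ratios.
#' @param p_grid Continuous pest mortalities.
#' @param q Relative enemy mortality (default 0.5).
#' @inheritParams sweep_pulse_p
#' @return A `sweep_grid` with columns `ratio`, `p` and the cell
#'   summaries.
#' @export
sweep_initial_conditions <- function(params,
                                     ratio_grid = c(0.05, 0.2, 1),
                                     p_grid = seq(0, 0.3, by = 0.05),
                                     q = 0.5,
                                     season_length = 100,
                                     output_step = 0.05) {
  base <- default_initial_state(params)
  pv <- pest_variable(params)
  ref <- sweep_reference(params, base, season_length, output_step)
  rows <- list()
  for (ratio in ratio_grid) for (p in p_grid) {
    init <- base
    init[predator_variable(params)] <- ratio * base[[pv]]
    reg <- pesticide_regime(if (p == 0) "none" else "continuous", p = p,
                            q = q, season_length = season_length)
    rows[[length(rows) + 1]] <-
      c(ratio = ratio, p = p, sweep_cell(params, reg, init, output_step))
  }
  finish_sweep(rows, ref, "p")
}

#' Largest pesticide mortality at which the predator persists
#'
#' Scans `p` over a grid (default step 0.1 on `[0, 3]`) under the given
#' regime mode and reports the largest grid value for which the predator
#' is not classified extinct at the end of the season (mean density over
#' the final generation >= 1e-3).
#'
#' @param params A `model_params` object.
#' @param q Relative enemy mortality.
#' @param regime_mode `"pulse"`, `"threshold"`, `"continuous"` or
#'   `"none"`.
#' @param p_grid Mortality grid (default `seq(0, 3, 0.1)`).
#' @param interval Pulse interval (pulse mode).
#' @inheritParams sweep_pulse_p
#' @return The largest persisting `p`; `Inf` for `mode = "none"` (the
#'   pesticide never acts, so no extinction at any nominal `p`).
#' @export
find_extinction_threshold <- function(params, q = 0.5,
                                      regime_mode = c("pulse", "threshold",
                                                      "continuous", "none"),
                                      p_grid = seq(0, 3, by = 0.1),
                                      interval = 14,
                                      initial_state = default_initial_state(params),
                                      season_length = 100,
                                      output_step = 0.05) {
  regime_mode <- match.arg(regime_mode)
  if (regime_mode == "none") return(Inf)
  persisting <- -Inf
  for (p in sort(p_grid)) {
    reg <- switch(regime_mode,
      pulse = pesticide_regime(if (p == 0) "none" else "pulse", p = p, q = q,
                               interval = interval,
                               season_length = season_length),
      threshold = pesticide_regime("threshold", p = p, q = q,
        threshold_density = if (inherits(params, "rm_params")) 200 else 0.5,
        season_length = season_length),
      continuous = pesticide_regime(if (p == 0) "none" else "continuous",
                                    p = p, q = q,
                                    season_length = season_length))
    traj <- simulate_season(params, reg, initial_state,
                            output_step = output_step)
    if (!is_predator_extinct(traj)) persisting <- p
  }
  persisting
}
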