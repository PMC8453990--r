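# Synthetic inputs for the meta-analytic pipeline: mechanistic "virtual
# field trials" built on the simulator, and a purely parametric
# effect-size generator with known truth for recovery and coverage tests.

#' Design of a virtual field trial
#'
#' A paired pesticide/control experiment run on one of the simulation
#' models: both arms share the biology and initial conditions (enemies
#' absent is encoded as a predator-free start in both arms), the treated
#' arm gets the pesticide regime, and plot-level observations are the
#' deterministic densities times iid lognormal noise with unit mean and
#' the stated coefficient of variation.
#'
#' @param params A `model_params` object.
#' @param regime The treated arm's [pesticide_regime()].
#' @param enemies_present If `FALSE` the predator initial density is 0 in
#'   both arms.
#' @param n_plots Replicate plots per arm (>= 2).
#' @param sampling_times Sampling times in pest generations (default every
#'   0.5 from 0.5 to 5, mirroring repeated-measures field series).
#' @param cv Coefficient of variation of the multiplicative lognormal
#'   observation noise (default 0.3, typical field-count dispersion).
#' @param kind `"timepoint"` for repeated measures, `"seasonal_average"`
#'   for a single season-average record.
#' @param enemy_presence Moderator label (`"local"`, `"regional"`,
#'   `"none"`); defaults to `"local"` when enemies are present, else
#'   `"none"`.
#' @param application Moderator label (`"once"`, `"regular"`,
#'   `"threshold"`, `"seed"`); defaults from the regime mode (pulse ->
#'   `"regular"`, or `"once"` for a single pulse; threshold ->
#'   `"threshold"`; continuous -> `"seed"`).
#' @param seed Integer seed making the trial reproducible.
#' @return An object of class `"trial_design"`.
#' @export
trial_design <- function(params, regime, enemies_present = TRUE,
                         n_plots = 4,
                         sampling_times = seq(0.5, 5, by = 0.5),
                         cv = 0.3,
                         kind = c("timepoint", "seasonal_average"),
                         enemy_presence = NULL, application = NULL,
                         seed = 1L) {
  kind <- match.arg(kind)
  if (n_plots < 2) stop("n_plots must be >= 2")
  if (cv < 0) stop("cv must be >= 0")
  if (is.null(enemy_presence))
    enemy_presence <- if (enemies_present) "local" else "none"
  if (is.null(application))
    application <- switch(regime$mode,
      pulse = if (regime$interval >= regime$season_length) "once" else "regular",
      threshold = "threshold",
      continuous = "seed",
      none = "none")
  structure(list(params = params, regime = regime,
                 enemies_present = enemies_present, n_plots = n_plots,
                 sampling_times = sampling_times, cv = cv, kind = kind,
                 enemy_presence = enemy_presence, application = application,
                 seed = as.integer(seed)),
            class = "trial_design")
}

#' Simulate a virtual field trial
#'
#' Runs the deterministic control (no pesticide) and treated simulations
#' of the design, samples pest densities at the design's sampling times
#' (or the season average), and turns plot-level noisy observations into
#' trial records (arm means, SDs and sample sizes with moderator labels).
#' Deterministic given the design's seed.
#'
#' @param design A [trial_design()].
#' @return A data frame of trial records with columns `series`, `time`
#'   (pest generations), `mean_c`, `sd_c`, `n_c`, `mean_t`, `sd_t`,
#'   `n_t`, `enemy_presence`, `application`, `kind`, `duration`
#'   (generations of the experiment).
#' @export
simulate_trial <- function(design) {
  params <- design$params
  regime <- design$regime
  init <- default_initial_state(params)
  if (!design$enemies_present) init[predator_variable(params)] <- 0
  season <- regime$season_length
  gt <- params$generation_time
  if (any(design$sampling_times * gt > season))
    stop("sampling time beyond the season")
  ctrl <- simulate_season(params, pesticide_regime("none",
                                                   season_length = season),
                          init)
  trt <- simulate_season(params, regime, init)
  pv <- pest_variable(params)
  sigma <- sqrt(log(1 + design$cv^2))
  noisy_arm <- function(dens) {
    obs <- dens * stats::rlnorm(design$n_plots, meanlog = -sigma^2 / 2,
                                sdlog = sigma)
    c(mean = mean(obs), sd = stats::sd(obs))
  }
  set.seed(design$seed)
  if (design$kind == "timepoint") {
    recs <- lapply(design$sampling_times, function(tg) {
      i <- which.min(abs(ctrl$time - tg * gt))
      ac <- noisy_arm(ctrl[[pv]][i])
      at <- noisy_arm(trt[[pv]][i])
      data.frame(time = tg, mean_c = ac[["mean"]], sd_c = ac[["sd"]],
                 n_c = design$n_plots, mean_t = at[["mean"]],
                 sd_t = at[["sd"]], n_t = design$n_plots)
    })
    out <- do.call(rbind, recs)
  } else {
    ac <- noisy_arm(time_average(ctrl, pv))
    at <- noisy_arm(time_average(trt, pv))
    out <- data.frame(time = season / gt / 2, mean_c = ac[["mean"]],
                      sd_c = ac[["sd"]], n_c = design$n_plots,
                      mean_t = at[["mean"]], sd_t = at[["sd"]],
                      n_t = design$n_plots)
  }
  out$enemy_presence <- design$enemy_presence
  out$application <- design$application
  out$kind <- design$kind
  out$duration <- season / gt
  out
}

#' Assemble a meta-analysis dataset from a collection of trial designs
#'
#' Simulates each design (with per-design seeds derived from `seed`),
#' assigns study and series identifiers, and appends Hedges g effect
#' sizes, producing the documented meta-dataset schema ready for
#' [fit_meta()] or [write_meta_dataset()].
#'
#' @param designs List of [trial_design()] objects (possibly with mixed
#'   moderators).
#' @param seed Integer master seed; design i runs with `seed + i`.
#' @return Data frame with columns `study`, `series`, `time`, arm
#'   summaries, moderators, `g` and `v`. An empty design list yields an
#'   empty data frame with the full schema.
#' @export
build_meta_dataset <- function(designs, seed = 1L) {
  schema <- data.frame(study = integer(0), series = integer(0),
                       time = numeric(0), mean_c = numeric(0),
                       sd_c = numeric(0), n_c = integer(0),
                       mean_t = numeric(0), sd_t = numeric(0),
                       n_t = integer(0), enemy_presence = character(0),
                       application = character(0), kind = character(0),
                       duration = numeric(0), g = numeric(0),
                       v = numeric(0))
  if (length(designs) == 0) return(schema)
  rows <- lapply(seq_along(designs), function(i) {
    d <- designs[[i]]
    d$seed <- as.integer(seed) + i
    rec <- simulate_trial(d)
    cbind(study = i, series = i, rec)
  })
  effect_sizes(do.call(rbind, rows))
}

#' Write / read the meta-dataset CSV schema
#'
#' One row per trial record; the header is the documented schema of
#' [build_meta_dataset()].
#'
#' @param dataset A meta-dataset data frame.
#' @param path CSV file path.
#' @return `path` (write) or the data frame (read).
#' @export
write_meta_dataset <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_meta_dataset
#' @export
read_meta_dataset <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Truth object for the parametric effect-size generator
#'
#' @param beta Named true coefficient vector; the first element is the
#'   intercept, remaining elements are moderator effects matched by
#'   column name to the generated design.
#' @param tau2 True between-cluster variance (random intercept).
#' @param tau2_series True series-level serial variance (CAR term).
#' @param rho Serial decay rate: correlation `exp(-rho * dt)` between
#'   effects `dt` apart within one series.
#' @param v_range Range from which within-study sampling variances are
#'   drawn uniformly.
#' @param n_clusters Number of clusters (studies/series).
#' @param cluster_size Effects per cluster; with `times` given, the
#'   cluster is a time series at those times.
#' @param times Optional vector of observation times (generations) for
#'   serial structure; length defines `cluster_size`.
#' @return An object of class `"generator_truth"`.
#' @export
generator_truth <- function(beta = c(intercept = 0, x = -0.8),
                            tau2 = 0.1, tau2_series = 0, rho = 0,
                            v_range = c(0.05, 0.2),
                            n_clusters = 200, cluster_size = 2,
                            times = NULL) {
  if (tau2 < 0 || tau2_series < 0) stop("tau2 components must be >= 0")
  if (rho < 0) stop("rho must be >= 0")
  if (!is.null(times)) cluster_size <- length(times)
  structure(list(beta = beta, tau2 = tau2, tau2_series = tau2_series,
                 rho = rho, v_range = v_range, n_clusters = n_clusters,
                 cluster_size = cluster_size, times = times),
            class = "generator_truth")
}

#' Generate parametric effect sizes with known truth
#'
#' Draws `g_i = x_i' beta + u_cluster + w_series(t_i) + e_i` with
#' `u ~ N(0, tau2)`, `w` a Gaussian serial process with covariance
#' `tau2_series * exp(-rho * dt)` within each cluster's series, and
#' `e_i ~ N(0, v_i)` with `v_i` drawn uniformly from `v_range`. The
#' binary moderator `x` is assigned to alternate clusters so the design
#' is balanced. Used as the calibration oracle for the meta-regression:
#' the returned table carries its truth as an attribute.
#'
#' @param truth A [generator_truth()].
#' @param seed Integer seed.
#' @return Data frame with columns `cluster`, `series`, `time`, `x`,
#'   `g`, `v`; attribute `truth` is the generating truth.
#' @export
parametric_effects <- function(truth, seed = 1L) {
  set.seed(as.integer(seed))
  K <- truth$n_clusters; m <- truth$cluster_size
  x_cl <- rep_len(c(0, 1), K)
  tt <- if (is.null(truth$times)) rep(0, m) else truth$times
  Ccor <- exp(-truth$rho * abs(outer(tt, tt, "-")))
  Cchol <- chol(truth$tau2_series * Ccor + diag(1e-12, m))
  rows <- lapply(seq_len(K), function(k) {
    u <- stats::rnorm(1, 0, sqrt(truth$tau2))
    w <- if (truth$tau2_series > 0)
      as.numeric(crossprod(Cchol, stats::rnorm(m))) else numeric(m)
    v <- stats::runif(m, truth$v_range[1], truth$v_range[2])
    mu <- truth$beta[1] + truth$beta[2] * x_cl[k]
    g <- mu + u + w + stats::rnorm(m, 0, sqrt(v))
    data.frame(cluster = k, series = k, time = tt, x = x_cl[k], g = g, v = v)
  })
  structure(do.call(rbind, rows), truth = truth)
}
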