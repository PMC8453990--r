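test_that("predator-free pest growth saturates at carrying capacity", {
  traj <- simulate_season(rm_params(), pesticide_regime("none"),
                          initial_state = c(N = 50, P = 0))
  expect_equal(tail(traj$N, 1), 1000, tolerance = 1e-3)
  expect_true(all(traj$P == 0))
})

test_that("continuous mortality converges to the closed-form equilibria", {
  p <- rm_params()
  long <- pesticide_regime("continuous", p = 0.05, q = 0.5,
                           season_length = 2000)
  traj <- simulate_season(p, long)
  expect_equal(tail(traj$N, 1), rm_pest_equilibrium(p, 0.05, 0.5),
               tolerance = 1e-3)
  expect_equal(tail(traj$P, 1), rm_predator_equilibrium(p, 0.05, 0.5),
               tolerance = 1e-3)
})

test_that("pulses carve 1-day exponential dips into the treated pest curve", {
  ctrl <- rm_control(); trt <- rm_treated()
  i1 <- which.min(abs(trt$time - 1))
  # during the first day growth is slow relative to p = 1/day
  expect_equal(trt$N[i1], exp(-1) * ctrl$N[i1], tolerance = 0.05)
})

test_that("time_average and cumulative_average obey closed forms", {
  ctrl <- rm_control()
  # constant and ramp oracles on a synthetic trajectory
  fake <- ctrl
  fake$N <- rep(7, nrow(fake))
  expect_equal(time_average(fake, "N"), 7)
  expect_equal(cumulative_average(fake, "N")$cumavg, rep(7, nrow(fake)))
  fake$N <- fake$time
  expect_equal(time_average(fake, "N"), 50)
  ca <- cumulative_average(fake, "N")
  expect_equal(ca$cumavg[-1], fake$time[-1] / 2, tolerance = 1e-12)
  expect_error(time_average(ctrl, "N", c(5, 5)), "empty")
  # season average equals the cumulative average at season end
  expect_equal(time_average(ctrl, "N"),
               tail(cumulative_average(ctrl, "N")$cumavg, 1))
})

test_that("crossover is found once and flags ties", {
  ctrl <- rm_control(); trt <- rm_treated()
  x <- crossover_generation(trt, ctrl)
  expect_gt(x, 0.1)
  expect_lt(x, 5)
  # treated cumavg genuinely below control before, above after
  expect_lt(time_average(trt, "N", c(0, 20)), time_average(ctrl, "N", c(0, 20)))
  expect_gt(time_average(trt, "N"), time_average(ctrl, "N"))
  tie <- crossover_generation(ctrl, ctrl)
  expect_equal(as.numeric(tie), 0)
  expect_true(attr(tie, "tie"))
  expect_error(crossover_generation(trt, trt[1:100, ]), "grid")
})

test_that("resurgence intervals are empty for identical arms and ordered", {
  ctrl <- rm_control(); trt <- rm_treated()
  expect_equal(nrow(resurgence_intervals(ctrl, ctrl)), 0)
  iv <- resurgence_intervals(trt, ctrl)
  expect_true(all(iv$start < iv$end))
  expect_true(all(iv$start >= 0 & iv$end <= 5))
  if (nrow(iv) > 1) expect_true(all(diff(iv$start) > 0))
})

test_that("predator extinction flag tracks the final-generation mean", {
  expect_true(is_predator_extinct(
    simulate_season(rm_params(), pesticide_regime("none"),
                    initial_state = c(N = 50, P = 0))))
  expect_false(is_predator_extinct(rm_control()))
  # far beyond the persistence range of the pulsed regime
  hot <- simulate_season(rm_params(),
                         pesticide_regime("pulse", p = 3, q = 0.5,
                                          interval = 14))
  expect_true(is_predator_extinct(hot))
})

test_that("simulation is deterministic and robust to tolerance tightening", {
  a <- simulate_season(rm_params(), standard_pulse_regime())
  b <- simulate_season(rm_params(), standard_pulse_regime())
  expect_identical(a$N, b$N)
  expect_identical(a$P, b$P)
  ctrl <- rm_control()
  tight_t <- simulate_season(rm_params(), standard_pulse_regime(),
                             rel_tol = 1e-9)
  tight_c <- simulate_season(rm_params(), pesticide_regime("none"),
                             rel_tol = 1e-9)
  expect_lt(abs(crossover_generation(tight_t, tight_c) -
                crossover_generation(rm_treated(), ctrl)), 0.02)
})

test_that("back-to-back pulses equal the continuous regime", {
  tiled <- simulate_season(rm_params(),
    pesticide_regime("pulse", p = 0.1, q = 0.5, interval = 1,
                     pulse_duration = 1))
  cont <- simulate_season(rm_params(),
    pesticide_regime("continuous", p = 0.1, q = 0.5))
  expect_equal(tiled$N, cont$N, tolerance = 1e-6)
  expect_equal(tiled$P, cont$P, tolerance = 1e-6)
})

test_that("selective continuous pesticide leaves the long-run pest average at the untreated equilibrium", {
  p <- rm_params()
  traj <- simulate_season(p, pesticide_regime("continuous", p = 0.05, q = 0,
                                              season_length = 2000))
  expect_equal(time_average(traj, "N", c(1500, 2000)),
               rm_pest_equilibrium(p, 0, 0), tolerance = 1e-3)
})

test_that("food-web exchange symmetry holds along whole trajectories", {
  fw <- foodweb_params(xN1 = 0.2, xN2 = 0.2, yN1 = 2.01, yN2 = 2.01,
                       R01 = 0.16129, R02 = 0.16129, omega = 0.5)
  traj <- simulate_season(fw,
    pesticide_regime("pulse", p = 1, q = 0.5, s = 1, interval = 14),
    initial_state = c(R = 0.1, N1 = 0.2, N2 = 0.2, P = 0.1))
  expect_equal(traj$N1, traj$N2, tolerance = 1e-6)
})

test_that("threshold runs record triggered windows and season summaries print", {
  th <- simulate_season(rm_params(),
    pesticide_regime("threshold", p = 1, q = 0.5, threshold_density = 200))
  w <- application_windows(th)
  expect_gt(nrow(w), 0)
  expect_true(all(w$cause == "threshold-triggered"))
  expect_true(all(w$start %% 6 == 0))  # sprays start at monitoring times
  s <- season_summary(rm_treated(), rm_control())
  expect_equal(s$avg[["N"]], time_average(rm_treated(), "N"))
  expect_false(s$predator_extinct)
  expect_output(print(s), "Season summary")
})

test_that("trajectories round-trip to CSV with their windows", {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, sub("\\.csv$", "_windows.csv", path))))
  write_trajectory(rm_treated(), path)
  back <- read.csv(path)
  expect_equal(back$N, rm_treated()$N)
  w <- read.csv(sub("\\.csv$", "_windows.csv", path))
  expect_equal(nrow(w), 8)
})
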