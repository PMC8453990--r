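# Small grids keep the sweeps fast; the structural claims do not depend
# on grid resolution.

test_that("pulsed-p sweep: reference cells, enemy-sparing selectivity, resurgence", {
  g <- sweep_pulse_p(rm_params(), q_levels = c(0, 0.5),
                     p_grid = c(0, 0.5, 1))
  ref <- sweep_reference_value(g)
  # p = 0 column equals the untreated reference for every q
  expect_equal(g$avg_pest[g$p == 0], rep(ref[["avg_pest"]], 2))
  # fully selective pesticide (q = 0) never raises the season average
  expect_true(all(g$avg_pest[g$q == 0] <= ref[["avg_pest"]] + 1e-8))
  # enemy mortality q = 0.5 produces resurgence above the reference
  expect_gt(g$avg_pest[g$q == 0.5 & g$p == 1], ref[["avg_pest"]])
  # average pest density nondecreasing in q at fixed p (persistence region)
  expect_gte(g$avg_pest[g$q == 0.5 & g$p == 0.5],
             g$avg_pest[g$q == 0 & g$p == 0.5])
})

test_that("frequency sweep agrees with the pulsed sweep at the 14-day anchor", {
  p <- rm_params()
  gf <- sweep_frequency(p, q_levels = 0.5, f_grid = c(0, 0.86))
  gp <- sweep_pulse_p(p, q_levels = 0.5, p_grid = c(0, 1))
  # f = 0 equals the reference
  expect_equal(gf$avg_pest[gf$f == 0],
               sweep_reference_value(gf)[["avg_pest"]])
  # f = 0.86 is the same regime as (p = 1, interval = 14)
  expect_equal(gf$avg_pest[gf$f == 0.86], gp$avg_pest[gp$p == 1],
               tolerance = 1e-10)
  # daily application with very enemy-toxic pesticide: predator lost and
  # pest pushed below the reference
  gd <- sweep_frequency(p, q_levels = 2, f_grid = 1)
  expect_equal(gd$predator_extinct, 1)
  expect_lt(gd$avg_pest, sweep_reference_value(gd)[["avg_pest"]])
})

test_that("threshold sweep counts sprays and peaks below the pulsed peak", {
  p <- rm_params()
  pg <- seq(0, 3, by = 0.5)
  gt <- sweep_threshold(p, q_levels = 0.5, p_grid = pg)
  gp <- sweep_pulse_p(p, q_levels = 0.5, p_grid = pg)
  # p = 0: sprays may fire but change nothing (equal to within the
  # solver tolerance across the restart pattern)
  expect_equal(gt$avg_pest[gt$p == 0],
               sweep_reference_value(gt)[["avg_pest"]], tolerance = 1e-6)
  expect_gt(gt$sprays[gt$p == 0], 0)
  # resurgence peaks at lower mortality than under fixed-calendar pulses
  expect_lt(pg[which.max(gt$avg_pest)], pg[which.max(gp$avg_pest)])
})

test_that("continuous sweep: selective long-run neutrality and extinction at q = 2", {
  p <- rm_params()
  g <- sweep_continuous(p, q_levels = c(0, 2), p_grid = c(0, 0.1, 0.3))
  ref <- sweep_reference_value(g)
  expect_equal(g$avg_pest[g$p == 0], rep(ref[["avg_pest"]], 2))
  expect_equal(g$predator_extinct[g$q == 2 & g$p == 0.3], 1)
})

test_that("alternative prey buffers enemies when it escapes the pesticide", {
  fw <- foodweb_params()
  g <- sweep_alt_prey(fw, s_levels = c(0, 1), regime_mode = "pulse",
                      q_levels = 0.5, grid = c(0, 0.5))
  # the p = 0 plane is identical across s
  expect_equal(g$avg_pest[g$p == 0 & g$s == 0],
               g$avg_pest[g$p == 0 & g$s == 1])
  # unsprayed alternative prey keeps pest densities lower than when it is
  # hit as hard as the pest
  expect_lt(g$avg_pest[g$s == 0 & g$p == 0.5],
            g$avg_pest[g$s == 1 & g$p == 0.5])
  # both grids agree directionally with the no-alternative-prey system:
  # resurgence with s = 1 at low p, none with s = 0
  ref <- sweep_reference_value(g)[["avg_pest"]]
  expect_gt(g$avg_pest[g$s == 1 & g$p == 0.5], ref)
  expect_lt(g$avg_pest[g$s == 0 & g$p == 0.5], ref)
})

test_that("initial pest-enemy ratios barely move the basic model's summaries", {
  p <- rm_params()
  g <- sweep_initial_conditions(p, ratio_grid = c(0.05, 0.2, 1),
                                p_grid = c(0, 0.1), q = 0.5)
  for (pp in unique(g$p)) {
    cells <- g$avg_pest[g$p == pp]
    expect_lt(max(cells) / min(cells), 2)
  }
  # enemy mortality raises pest densities at low p for every start
  for (r in unique(g$ratio))
    expect_gt(g$avg_pest[g$ratio == r & g$p == 0.1],
              g$avg_pest[g$ratio == r & g$p == 0])
})

test_that("without predators the pest average declines monotonically in p", {
  p <- rm_params()
  init0 <- c(N = 50, P = 0)
  avgs <- sapply(c(0.5, 1, 2), function(pp)
    time_average(simulate_season(p,
      pesticide_regime("pulse", p = pp, q = 0.5, interval = 14), init0)))
  expect_true(all(diff(avgs) < 0))
})

test_that("grid cells are independent: recomputing one reproduces its value", {
  p <- rm_params()
  g <- sweep_pulse_p(p, q_levels = 0.5, p_grid = c(0.5, 1))
  cell <- simulate_season(p, standard_pulse_regime())
  expect_equal(g$avg_pest[g$p == 1], time_average(cell, "N"))
})

test_that("extinction threshold scanning respects ordering in q", {
  p <- rm_params()
  # no regime, no extinction at any nominal p
  expect_identical(find_extinction_threshold(p, regime_mode = "none"), Inf)
  # heavier enemy kill brings extinction earlier
  coarse <- seq(0, 3, by = 0.5)
  t_q5 <- find_extinction_threshold(p, q = 5, p_grid = coarse)
  t_q05 <- find_extinction_threshold(p, q = 0.5, p_grid = coarse)
  expect_lt(t_q5, t_q05)
  expect_lt(t_q5, 1.9)
})
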