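# Shared fixtures. Trajectories for the standard treated/control pair
# (1-day pulses every 14 days, p = 1/day, q = 0.5) are computed once per
# test run and cached, since several files summarize the same runs.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_cache)) assign(name, build(), .fixture_cache)
  get(name, .fixture_cache)
}

standard_pulse_regime <- function(q = 0.5)
  pesticide_regime("pulse", p = 1, q = q, interval = 14)

rm_control <- function() fixture("rm_control", function()
  simulate_season(rm_params(), pesticide_regime("none")))

rm_treated <- function() fixture("rm_treated", function()
  simulate_season(rm_params(), standard_pulse_regime()))

fw_control <- function() fixture("fw_control", function()
  simulate_season(foodweb_params(), pesticide_regime("none")))

fw_treated <- function() fixture("fw_treated", function()
  simulate_season(foodweb_params(), standard_pulse_regime()))
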