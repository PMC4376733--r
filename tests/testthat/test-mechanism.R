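test_that("activation steepness evaluates the window endpoints", {
  win <- list(lower = -51, upper = -50)
  # frozen independent evaluation of the Kd sigmoid at both bounds
  expect_equal(activation_steepness(channel_spec("Kd"), win),
               0.00308195, tolerance = 1e-4)
  # zero-width window
  expect_equal(activation_steepness(channel_spec("Kd"),
                                    list(lower = -50, upper = -50)), 0)
  # KCa uses the supplied fixed calcium
  s15 <- activation_steepness(channel_spec("KCa"), win, ca = 15)
  s1 <- activation_steepness(channel_spec("KCa"), win, ca = 1)
  expect_gt(s15, s1)
  expect_error(activation_steepness(channel_spec("leak"), win), "passive")
})

test_that("the voltage window needs at least two tonic levels", {
  expect_error(dynamic_voltage_window(baseline_config(), levels = 0,
                                      duration = 4000, transient = 1000),
               "tonic")
})

test_that("coupling and uncoupling rewrite the KCa activation as configured", {
  cfg <- baseline_config()
  # identity coefficient: identical dynamics
  tr1 <- simulate_neuron(cfg, duration = 1500, transient = 0)
  tr2 <- simulate_neuron(set_coupling(cfg, 1), duration = 1500,
                         transient = 0)
  expect_identical(tr1$V, tr2$V)
  # a stronger coupling recruits more K current and slows firing
  tr3 <- simulate_neuron(set_coupling(cfg, 2), duration = 5000,
                         transient = 1500)
  tr0 <- simulate_neuron(cfg, duration = 5000, transient = 1500)
  expect_lt(length(detect_spikes(tr3)$times),
            length(detect_spikes(tr0)$times))
  # uncoupled state pins the calcium factor: the KCa gate no longer
  # follows calcium transients
  un <- uncouple_kca(cfg, 15)
  expect_equal(un$kca_fixed_ca, 15)
  st <- initial_state(un, -65)
  expect_equal(st$m$KCa,
               eval_gating(channel_spec("KCa"), -65, Ca = 15)$m_inf)
  expect_error(uncouple_kca(cfg, -1))
  expect_error(set_coupling(cfg, 0))
})

test_that("current-voltage loops reproduce closed-form passive loops", {
  cfg <- baseline_config()
  loop <- iv_loop(cfg, "leak", drive = 0, transient = 1000)
  expect_length(loop$V, 16000)
  # ohmic line through the leak reversal
  expect_equal(loop$I, 0.04 * (loop$V + 50), tolerance = 1e-10)
  # a zero-conductance channel has a flat loop
  loop2 <- iv_loop(cfg, "CaT", drive = 0, transient = 1000)
  expect_true(all(loop2$I == 0))
  # the loop's voltage range is the trace's voltage range
  expect_equal(range(loop$V), range(loop2$V))
  # occupancy companion normalizes
  expect_equal(sum(loop$occupancy$percent), 100, tolerance = 1e-9)
})

test_that("rate matching inverts the f-I curve", {
  cfg <- baseline_config()
  short <- list(duration = 5000, transient = 1500)
  target <- 15
  drive <- match_firing_rate(cfg, target, bounds = c(0, 2),
                             duration = short$duration,
                             transient = short$transient)
  expect_within(as.numeric(drive), 0, 2)
  expect_lt(abs(attr(drive, "rate") - target) / target, 0.011)
  # dense-grid inverse lookup agrees
  grid <- seq(0, 2, length.out = 21)
  rates <- vapply(grid, function(a) {
    tr <- simulate_neuron(cfg, tonic_current(a), short$duration,
                          short$transient)
    interval_rate(detect_spikes(tr))
  }, numeric(1))
  inv <- stats::approx(rates, grid, xout = target)$y
  expect_lt(abs(as.numeric(drive) - inv), 0.1)
  expect_error(match_firing_rate(cfg, 500, bounds = c(0, 2),
                                 duration = 3000, transient = 1000),
               "not bracketed")
})

test_that("per-spike average currents pair rates with channel currents", {
  cfg <- baseline_config()
  tab <- current_per_ap_curve(cfg, "KCa", levels = c(0.5, 1, 1.5, 2),
                              duration = 6000, transient = 2000)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$current > 0))      # outward at E = -80
  expect_true(all(diff(tab$rate) > 0))
  # zero-conductance channel carries nothing at any rate
  tab0 <- current_per_ap_curve(cfg, "CaT", levels = c(1, 1.5, 2),
                               duration = 6000, transient = 2000)
  expect_true(all(tab0$current == 0))
  # leak current sign is set by the mean driving force
  tabl <- current_per_ap_curve(cfg, "leak", levels = c(1.5, 2),
                               duration = 6000, transient = 2000)
  expect_true(all(is.finite(tabl$current)))
  expect_error(current_per_ap_curve(cfg, "KCa", levels = 0,
                                    duration = 3200, transient = 2000),
               "spikes")
})

test_that("shifting the h activation moves its half-voltage into the window", {
  cfg <- shift_h_activation(baseline_config(), -50)
  expect_equal(eval_gating(cfg$specs$h, -50)$m_inf, 0.5)
  # other channels untouched
  expect_identical(cfg$specs$Na, channel_spec("Na"))
  # the shifted channel conducts far more around the firing window,
  # so the same conductance now slows the ramp to threshold
  tr0 <- simulate_neuron(with_h <- baseline_config(), duration = 5000,
                         transient = 1500)
  cfg_big <- cfg
  cfg_big$gbar[["h"]] <- 0.5
  tr1 <- simulate_neuron(cfg_big, duration = 5000, transient = 1500)
  expect_false(identical(tr0$V, tr1$V))
})
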