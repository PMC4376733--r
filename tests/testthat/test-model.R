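test_that("channel currents follow the conductance equation", {
  cfg <- baseline_config()
  st <- initial_state(cfg, -50)
  # leak reverses at -50 mV
  expect_equal(channel_current("leak", cfg, st), 0)
  # zero-conductance channels carry no current
  expect_equal(channel_current("CaT", cfg, st), 0)
  expect_equal(channel_current("e", cfg, st), 0)
  # hand-evaluated delayed-rectifier current at m = 0.5, V = -30
  st2 <- initial_state(cfg, -30)
  st2$m$Kd <- 0.5
  expect_equal(channel_current("Kd", cfg, st2), 125 * 0.5^4 * (-30 + 80))
  expect_equal(channel_current("Kd", cfg, st2), 390.625)
})

test_that("calcium reversal follows the Nernst equation", {
  cc <- calcium_config()
  expect_equal(calcium_reversal(cc$ca_out, cc), 0)
  # frozen independent evaluation at baseline calcium (z = 2, ln)
  expect_equal(calcium_reversal(0.05, cc), 146.954746, tolerance = 1e-6)
  # halving the intracellular concentration raises the reversal
  expect_gt(calcium_reversal(0.025, cc), calcium_reversal(0.05, cc))
  expect_error(calcium_reversal(0, cc), "positive")
  # log10 convention at z = 1 agrees with the direct formula
  cc10 <- calcium_config(z = 1, log_base = "log10")
  expect_equal(calcium_reversal(0.05, cc10),
               1000 * 8.3145 * 310 / 96485 * log10(60000) / log(10) * log(10),
               tolerance = 1e-6)
})

test_that("initial state puts every gate at steady state", {
  cfg <- baseline_config()
  st <- initial_state(cfg, -25.5)
  expect_equal(st$m$Na, 0.5)
  st2 <- initial_state(cfg, -65)
  expect_equal(st2$m$Na, eval_gating(cfg$specs$Na, -65)$m_inf)
  gates <- unlist(c(st2$m, st2$h))
  expect_true(all(gates >= 0 & gates <= 1))
  expect_equal(st2$ca, 0.05)
})

test_that("state derivative vanishes at a passive fixed point", {
  gb <- c(Na = 0, CaS = 0, CaT = 0, A = 0, KCa = 0, Kd = 0, h = 0,
          leak = 0, e = 0, i = 0)
  cfg <- neuron_config(gbar = gb)
  d <- state_derivative(initial_state(cfg, -55), cfg, 0)
  expect_equal(d$dV, 0)
  expect_equal(unlist(d$dm), unlist(d$dm) * 0)  # gates at steady state
  # leak-only: derivative at the leak reversal is zero
  cfg2 <- neuron_config(gbar = c(gb, leak = NULL))
  cfg2$gbar[["leak"]] <- 0.04
  d2 <- state_derivative(initial_state(cfg2, -50), cfg2, 0)
  expect_equal(d2$dV, 0)
})

test_that("leak-only membrane relaxes with the RC time constant", {
  gb <- c(Na = 0, CaS = 0, CaT = 0, A = 0, KCa = 0, Kd = 0, h = 0,
          e = 0, i = 0)
  cfg <- neuron_config(gbar = gb)   # leak stays at 0.04 mS/cm2
  tr <- simulate_neuron(cfg, duration = 200, transient = 0, V0 = -70)
  tau <- cfg$cm / cfg$gbar[["leak"]]   # 15 ms
  expected <- -50 + (-70 + 50) * exp(-tr$time / tau)
  expect_lt(max(abs(tr$V - expected)), 1e-3)
  expect_equal(tail(tr$V, 1), -50, tolerance = 1e-5)
})

test_that("compiled and R derivatives describe the same dynamics", {
  cfg <- baseline_config()
  st <- initial_state(cfg, -65)
  nm <- names(neurogain:::state_vector(st))
  rfun <- function(t, y, p) {
    s <- neuron_state(y[[1]],
                      m = list(Na = y[[2]], CaS = y[[4]], CaT = y[[6]],
                               A = y[[8]], KCa = y[[10]], Kd = y[[11]],
                               h = y[[12]]),
                      h = list(Na = y[[3]], CaS = y[[5]], CaT = y[[7]],
                               A = y[[9]]),
                      ca = y[[13]])
    d <- state_derivative(s, cfg, 0)
    list(c(d$dV, d$dm$Na, d$dh$Na, d$dm$CaS, d$dh$CaS, d$dm$CaT,
           d$dh$CaT, d$dm$A, d$dh$A, d$dm$KCa, d$dm$Kd, d$dm$h, d$dca))
  }
  y0 <- neurogain:::state_vector(st)
  names(y0) <- nm
  times <- seq(0, 200, 0.25)
  solR <- deSolve::lsoda(y0, times, rfun, NULL, rtol = 1e-8, atol = 1e-10)
  trC <- simulate_neuron(cfg, duration = 200, transient = 0,
                         rtol = 1e-8, atol = 1e-10)
  # the 200 ms segment includes a full action potential
  expect_gt(max(trC$V), 0)
  expect_lt(max(abs(solR[, 2] - trC$V)), 0.01)
})

test_that("passive channels at zero conductance leave the trace untouched", {
  cfg <- baseline_config()
  expect_equal(cfg$gbar[["e"]], 0)
  expect_equal(cfg$gbar[["i"]], 0)
  tr1 <- simulate_neuron(cfg, duration = 1500, transient = 0)
  cfg2 <- neuron_config(erev = c(e = -10, i = -85))  # reversals moot at g=0
  tr2 <- simulate_neuron(cfg2, duration = 1500, transient = 0)
  expect_identical(tr1$V, tr2$V)
})

test_that("configuration constructor validates its inputs", {
  expect_error(neuron_config(gbar = c(Na = -1)), "Na")
  expect_error(neuron_config(gbar = c(Nax = 1)), "unknown")
  expect_error(neuron_config(erev = c(CaS = 100)), "CaS")
  expect_error(neuron_config(cm = 0))
  expect_error(neuron_config(kca_fixed_ca = -1), "positive")
})
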