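test_that("steady-state activations hit their half-voltages and frozen values", {
  # half-activation at the tabulated half-voltages
  expect_equal(eval_gating(channel_spec("Na"), -25.5)$m_inf, 0.5)
  expect_equal(eval_gating(channel_spec("h"), -75)$m_inf, 0.5)
  # direct evaluation of the printed Kd sigmoid at -50 mV
  expect_equal(eval_gating(channel_spec("Kd"), -50)$m_inf,
               0.0393575198, tolerance = 1e-8)
  # KCa at calcium half-saturation and saturating depolarization
  expect_equal(eval_gating(channel_spec("KCa"), 100, Ca = 3)$m_inf,
               0.5, tolerance = 1e-4)
})

test_that("gating evaluation enforces its preconditions", {
  expect_error(eval_gating(channel_spec("leak"), -50), "passive")
  expect_error(eval_gating(channel_spec("KCa"), -50), "Ca")
  expect_error(eval_gating(channel_spec("Na"), NaN), "finite")
  expect_error(eval_gating(channel_spec("KCa"), -50, Ca = -1), "positive")
})

test_that("gating quantities are bounded and positive over the voltage range", {
  V <- seq(-120, 60, by = 1)
  for (n in c("Na", "CaS", "CaT", "A", "KCa", "Kd", "h")) {
    g <- eval_gating(channel_spec(n), V,
                     Ca = if (n == "KCa") 15 else NULL)
    expect_true(all(g$m_inf >= 0 & g$m_inf <= 1), info = n)
    expect_true(all(g$h_inf >= 0 & g$h_inf <= 1), info = n)
    expect_true(all(g$tau_m > 0), info = n)
    expect_true(all(is.na(g$tau_h) | g$tau_h > 0), info = n)
  }
})

test_that("activation and inactivation curves are monotone in voltage", {
  V <- seq(-120, 60, by = 1)
  for (n in c("Na", "CaS", "CaT", "A", "Kd", "KCa")) {
    g <- eval_gating(channel_spec(n), V, Ca = if (n == "KCa") 15 else NULL)
    expect_true(all(diff(g$m_inf) > 0), info = paste(n, "m_inf increasing"))
  }
  expect_true(all(diff(eval_gating(channel_spec("h"), V)$m_inf) < 0))
  for (n in c("Na", "CaS", "CaT", "A")) {
    g <- eval_gating(channel_spec(n), V)
    expect_true(all(diff(g$h_inf) < 0), info = paste(n, "h_inf decreasing"))
  }
})

test_that("gate counts and inactivation structure follow the kinetics table", {
  rho <- c(Na = 3, CaS = 3, CaT = 3, A = 3, KCa = 4, Kd = 4, h = 1)
  for (n in names(rho)) {
    sp <- channel_spec(n)
    expect_identical(sp$rho, as.integer(rho[[n]]), info = n)
  }
  for (n in c("KCa", "Kd", "h"))
    expect_null(channel_spec(n)$inact, info = n)
  for (n in c("leak", "e", "i")) {
    sp <- channel_spec(n)
    expect_identical(sp$rho, 0L)
    expect_null(sp$act)
    expect_null(sp$inact)
  }
})

test_that("activation shift moves the half-voltage and nothing else", {
  h50 <- shift_activation(channel_spec("h"), -50)
  expect_equal(eval_gating(h50, -50)$m_inf, 0.5)
  # evaluation away from the new half-voltage, frozen independent value
  expect_equal(eval_gating(h50, -75)$m_inf, 0.98949616, tolerance = 1e-7)
  # shift to the original half-voltage is the identity
  expect_identical(shift_activation(channel_spec("h"), -75),
                   channel_spec("h"))
  # slope at the half-voltage is preserved under the shift
  eps <- 1e-4
  d0 <- diff(eval_gating(channel_spec("h"), c(-75 - eps, -75 + eps))$m_inf)
  d1 <- diff(eval_gating(h50, c(-50 - eps, -50 + eps))$m_inf)
  expect_equal(d0, d1, tolerance = 1e-10)
  # time constant untouched
  expect_equal(eval_gating(h50, -60)$tau_m,
               eval_gating(channel_spec("h"), -60)$tau_m)
  expect_error(shift_activation(channel_spec("leak"), -50), "sigmoid")
})

test_that("availability curves match independent evaluation and are nonnegative", {
  V <- seq(-80, 0, by = 5)
  for (n in c("Na", "A", "Kd")) {
    av <- availability_curve(channel_spec(n), V)
    expect_true(all(av >= 0), info = n)
  }
  # A-type at -60 mV: frozen product of the four tabulated expressions
  expect_equal(availability_curve(channel_spec("A"), -60),
               1.23326913e-05, tolerance = 1e-7)
  # without inactivation the curve reduces to m_inf / tau_m
  g <- eval_gating(channel_spec("Kd"), V)
  expect_equal(availability_curve(channel_spec("Kd"), V),
               g$m_inf / g$tau_m)
  expect_error(availability_curve(channel_spec("Kd"), numeric(0)), "empty")
})
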