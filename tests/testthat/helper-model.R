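# Shared fixtures. Expensive baseline simulations are computed once per
# test run and reused.

.fixtures <- new.env(parent = emptyenv())

baseline_config <- function() neuron_config()

# full-length baseline run (12 s, 2 s transient), shared by several tests
baseline_trace <- function() {
  if (is.null(.fixtures$baseline)) {
    .fixtures$baseline <- simulate_neuron(baseline_config(),
                                          duration = 12000,
                                          transient = 2000)
  }
  .fixtures$baseline
}

# shorter baseline run for structural checks
short_trace <- function() {
  if (is.null(.fixtures$short)) {
    .fixtures$short <- simulate_neuron(baseline_config(),
                                       duration = 4000, transient = 1000)
  }
  .fixtures$short
}

# build a synthetic trace object from a plain voltage series so spike
# and occupancy metrics can be tested against constructed waveforms
synthetic_trace <- function(V, dt = 0.25, transient = 0) {
  n <- length(V)
  structure(list(time = seq(0, by = dt, length.out = n), V = V,
                 ca = rep(1, n),
                 currents = matrix(0, n, 10,
                                   dimnames = list(NULL,
                                     c("Na", "CaS", "CaT", "A", "KCa",
                                       "Kd", "h", "leak", "e", "i"))),
                 i_stim = rep(0, n),
                 gates = NULL, config = NULL, stimulus = zero_stimulus(),
                 transient = transient),
            class = "neuron_trace")
}

# synthetic tuning curve from explicit points
synthetic_curve <- function(input, rate, kind = "tonic") {
  structure(data.frame(input = input, level = input, rate = rate,
                       pattern = "tonic"),
            kind = kind, config = NULL,
            class = c("tuning_curve", "data.frame"))
}

expect_within <- function(value, lo, hi) {
  expect_gte(value, lo)
  expect_lte(value, hi)
}
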