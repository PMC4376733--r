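test_that("spike detection counts constructed threshold crossings", {
  flat <- synthetic_trace(rep(-50, 4001))
  expect_length(detect_spikes(flat)$times, 0)
  # three separated triangular excursions above threshold
  tri <- rep(-60, 4000)
  for (c0 in c(500, 2000, 3500)) {
    tri[(c0 - 40):(c0 + 40)] <- -60 + 70 * (1 - abs(-40:40) / 40)
  }
  sp <- detect_spikes(synthetic_trace(tri))
  expect_length(sp$times, 3)
  # crossings closer than min_isi merge
  dbl <- rep(-60, 2000)
  dbl[500:504] <- 20
  dbl[508:512] <- 20   # 1 ms later
  expect_length(detect_spikes(synthetic_trace(dbl), min_isi = 4)$times, 1)
  expect_length(detect_spikes(synthetic_trace(dbl), min_isi = 0.5)$times, 2)
})

test_that("firing rate is count over window and matches the ISI identity", {
  sp <- structure(list(times = seq(100, 1900, by = 200),
                       window = c(0, 2000)), class = "spike_train")
  expect_equal(firing_rate(sp), 10 / 2)   # 10 spikes / 2000 ms = 5 Hz
  empty <- structure(list(times = numeric(0), window = c(0, 1000)),
                     class = "spike_train")
  expect_equal(firing_rate(empty), 0)
  # for a perfectly regular train the interval estimate agrees to within
  # one-spike edge error
  expect_equal(interval_rate(sp), 1000 / 200)
  expect_lt(abs(interval_rate(sp) - firing_rate(sp)),
            1000 / diff(sp$window))
})

test_that("firing patterns classify by ISI variability", {
  reg <- structure(list(times = seq(0, 2000, by = 100),
                        window = c(0, 2000)), class = "spike_train")
  expect_equal(classify_pattern(reg), "tonic")
  empty <- structure(list(times = numeric(0), window = c(0, 1000)),
                     class = "spike_train")
  expect_equal(classify_pattern(empty), "silent")
  # alternating 10/200 ms intervals: CV far above the tonic cutoff
  alt <- structure(list(times = cumsum(rep(c(10, 200), 10)),
                        window = c(0, 2200)), class = "spike_train")
  isi <- diff(alt$times)
  expect_gt(stats::sd(isi) / mean(isi), 0.1)
  expect_equal(classify_pattern(alt), "non-tonic")
})

test_that("voltage occupancy is a normalized time histogram", {
  const <- synthetic_trace(rep(-60.5, 1000))
  occ <- voltage_occupancy(const)
  expect_equal(sum(occ$percent), 100, tolerance = 1e-9)
  expect_equal(max(occ$percent), 100)
  # linear ramp across two equal bins splits evenly
  ramp <- synthetic_trace(seq(-60.999, -59.001, length.out = 2000))
  occ2 <- voltage_occupancy(ramp)
  top2 <- sort(occ2$percent, decreasing = TRUE)[1:2]
  expect_equal(top2[1], 50, tolerance = 0.2)
  expect_equal(top2[2], 50, tolerance = 0.2)
  # refinement never changes the total
  expect_equal(sum(voltage_occupancy(baseline_trace(), 0.25)$percent), 100)
  expect_equal(sum(voltage_occupancy(baseline_trace(), 2)$percent), 100)
})

test_that("trace means reduce to time averages", {
  expect_equal(mean_voltage(synthetic_trace(rep(-60, 100))), -60)
  sq <- synthetic_trace(rep(c(-70, -30), 500))
  expect_equal(mean_voltage(sq), -50)
  expect_equal(mean_calcium(synthetic_trace(rep(-60, 100))), 1)
})

test_that("spike counts are threshold-invariant for full-height spikes", {
  tr <- baseline_trace()
  counts <- vapply(c(-20, -15, -10, -5, 0),
                   function(th) length(detect_spikes(tr, threshold = th)$times),
                   numeric(1))
  expect_equal(length(unique(counts)), 1)
})
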