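# Mechanistic analyses: the dynamic voltage window, the relationship
# between activation steepness and gain impact, average current per
# action potential, current-voltage loops with rate-matched occupancy
# histograms, KCa/calcium coupling manipulations, and the
# activation-shift experiment on the h channel.

#' Dynamic voltage window
#'
#' Simulates the model across a range of tonic drives and returns the
#' span of time-averaged membrane potentials (spikes included) over the
#' tonic-firing levels: the narrow voltage range the membrane occupies,
#' on average, while the cell fires across its input range.
#'
#' @param config a [neuron_config()]
#' @param levels tonic drive levels, uA/cm2
#' @param duration,transient per-level simulation span, ms
#' @return a list of class `voltage_window`: `lower`, `upper` (mV) and
#'   the per-level table `means`
#' @export
dynamic_voltage_window <- function(config, levels = seq(0, 2, length.out = 21),
                                   duration = 12000, transient = 2000) {
  rows <- lapply(levels, function(lev) {
    tr <- simulate_neuron(config, tonic_current(lev), duration, transient)
    sp <- detect_spikes(tr)
    data.frame(input = lev, rate = firing_rate(sp),
               pattern = classify_pattern(sp), mean_v = mean_voltage(tr))
  })
  means <- do.call(rbind, rows)
  tonic <- means[means$pattern == "tonic", , drop = FALSE]
  if (nrow(tonic) < 2)
    stop("need at least 2 tonic-firing levels to bound the voltage window")
  structure(list(lower = min(tonic$mean_v), upper = max(tonic$mean_v),
                 means = means),
            class = "voltage_window")
}

#' @export
print.voltage_window <- function(x, ...) {
  cat("<voltage_window> [", signif(x$lower, 5), ",", signif(x$upper, 5),
      "] mV over", sum(x$means$pattern == "tonic"), "tonic levels\n")
  invisible(x)
}

#' Steepness of a channel's activation inside a voltage window
#'
#' The absolute change of the steady-state activation across the dynamic
#' voltage window, `|m_inf(upper) - m_inf(lower)|`. The KCa channel is
#' evaluated at a fixed calcium concentration (default 15 uM, the
#' baseline-firing mean).
#'
#' @param spec a gated `channel_spec`
#' @param window a `voltage_window` (or list with `lower`/`upper`, mV)
#' @param ca calcium for the KCa channel, uM
#' @return absolute change in m_inf (unitless)
#' @export
activation_steepness <- function(spec, window, ca = 15) {
  ca_arg <- if (spec$ca_dep) ca else NULL
  m <- eval_gating(spec, c(window$lower, window$upper), Ca = ca_arg)$m_inf
  abs(m[2] - m[1])
}

#' Correlation between activation steepness and gain impact
#'
#' For the voltage-gated channels whose conductances are varied in the
#' gain analysis (A, Kd, KCa, CaS, h), computes (i) the absolute change
#' of each channel's steady-state activation across the dynamic voltage
#' window and (ii) the absolute impact of the channel on maximal gain
#' (percent gain per percent conductance at baseline), and returns the
#' Pearson correlation of the five pairs (both axes as positive
#' numbers).
#'
#' @param config a [neuron_config()]
#' @param channels channels to include
#' @param window optionally a precomputed `voltage_window`
#' @param levels tonic levels for tuning curves (and the window)
#' @param percents conductance grid for [gain_impact()]
#' @param kca_ca fixed calcium for the KCa steepness, uM
#' @param duration,transient per-simulation span, ms
#' @return a list of class `steepness_correlation`: `r`, and `table`
#'   with per-channel steepness, impact and sign
#' @export
steepness_impact_correlation <- function(config,
                                         channels = c("A", "Kd", "KCa",
                                                      "CaS", "h"),
                                         window = NULL,
                                         levels = seq(0, 2, length.out = 11),
                                         percents = c(70, 85, 100, 115, 130),
                                         kca_ca = 15,
                                         duration = 12000, transient = 2000) {
  if (is.null(window))
    window <- dynamic_voltage_window(config, levels = levels,
                                     duration = duration,
                                     transient = transient)
  rows <- lapply(channels, function(ch) {
    imp <- gain_impact(config, ch, percents = percents, levels = levels,
                       duration = duration, transient = transient)
    st <- activation_steepness(config$specs[[ch]], window, ca = kca_ca)
    data.frame(channel = ch, steepness = st, impact = imp$impact,
               abs_impact = abs(imp$impact))
  })
  tab <- do.call(rbind, rows)
  r <- stats::cor(tab$steepness, tab$abs_impact, method = "pearson")
  structure(list(r = r, table = tab, window = window),
            class = "steepness_correlation")
}

#' @export
print.steepness_correlation <- function(x, ...) {
  cat("<steepness_correlation> Pearson r =", signif(x$r, 4), "\n")
  print(x$table)
  invisible(x)
}

#' Average channel current per action potential across the firing range
#'
#' For each tonic drive level, time-averages one channel's current over
#' a window spanning 10 consecutive inter-spike intervals (from the 3rd
#' post-transient spike to the 13th, avoiding onset effects), and pairs
#' it with the firing rate. Inward currents are negative.
#'
#' @param config a [neuron_config()]
#' @param channel channel name
#' @param levels tonic drive levels, uA/cm2
#' @param duration,transient per-level simulation span, ms
#' @param first_spike index of the spike starting the averaging window
#' @return data frame with `input`, `rate` (Hz), `current` (uA/cm2,
#'   outward positive)
#' @export
current_per_ap_curve <- function(config, channel,
                                 levels = seq(0, 2, length.out = 11),
                                 duration = 12000, transient = 2000,
                                 first_spike = 3) {
  channel <- match.arg(channel, .channel_order)
  rows <- lapply(levels, function(lev) {
    tr <- simulate_neuron(config, tonic_current(lev), duration, transient)
    sp <- detect_spikes(tr)
    if (length(sp$times) < first_spike + 10)
      stop("fewer than ", first_spike + 10, " spikes at drive ", lev,
           " uA/cm2; cannot span 10 inter-spike intervals")
    t0 <- sp$times[first_spike]
    t1 <- sp$times[first_spike + 10]
    sel <- tr$time >= t0 & tr$time < t1
    data.frame(input = lev, rate = firing_rate(sp),
               current = mean(tr$currents[sel, channel]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Current-voltage loop of a channel during firing
#'
#' Pairs one channel's current with the membrane potential over 4
#' seconds of post-transient tonic firing at the standard 0.25 ms
#' resolution (16000 samples), together with the voltage-occupancy
#' histogram of the same segment.
#'
#' @param config a [neuron_config()]
#' @param channel channel name
#' @param drive tonic drive, uA/cm2
#' @param transient settle time before the 4 s segment, ms
#' @param bin_width occupancy bin width, mV
#' @return a list of class `iv_loop`: `V` (mV), `I` (uA/cm2), `rate`
#'   (Hz), `occupancy`
#' @export
iv_loop <- function(config, channel, drive = 0, transient = 2000,
                    bin_width = 1) {
  channel <- match.arg(channel, .channel_order)
  tr <- simulate_neuron(config, tonic_current(drive),
                        duration = transient + 4000, transient = transient)
  sp <- detect_spikes(tr)
  pat <- classify_pattern(sp)
  if (!identical(pat, "tonic"))
    stop("firing is ", pat, " at drive ", drive, " uA/cm2; the loop needs ",
         "tonic firing")
  idx <- which(tr$time > tr$transient)
  stopifnot(length(idx) == 16000)
  structure(list(V = tr$V[idx], I = tr$currents[idx, channel],
                 rate = firing_rate(sp),
                 occupancy = voltage_occupancy(tr, bin_width),
                 channel = channel, drive = drive),
            class = "iv_loop")
}

#' Find the tonic drive producing a target firing rate
#'
#' Bisection on the tonic drive amplitude until the firing rate is
#' within `tol` (relative) of the target or 20 iterations have elapsed.
#' The target must be bracketed by the rates at the bounds. Used to
#' compare voltage-occupancy histograms across conductance settings at
#' matched firing rates.
#'
#' @param config a [neuron_config()]
#' @param target target firing rate, Hz
#' @param bounds drive bounds, uA/cm2
#' @param tol relative rate tolerance
#' @param max_iter iteration cap
#' @param duration,transient per-evaluation simulation span, ms
#' @return the drive amplitude, uA/cm2 (attribute `rate` holds the
#'   achieved rate)
#' @export
match_firing_rate <- function(config, target, bounds = c(0, 2),
                              tol = 0.01, max_iter = 20,
                              duration = 8000, transient = 2000) {
  rate_at <- function(a) {
    tr <- simulate_neuron(config, tonic_current(a), duration, transient)
    firing_rate(detect_spikes(tr))
  }
  r_lo <- rate_at(bounds[1])
  r_hi <- rate_at(bounds[2])
  if (target < min(r_lo, r_hi) || target > max(r_lo, r_hi))
    stop("target rate ", target, " Hz not bracketed by rates [",
         signif(r_lo, 4), ", ", signif(r_hi, 4), "] Hz at the drive bounds")
  lo <- bounds[1]; hi <- bounds[2]
  mid <- lo; r_mid <- r_lo
  for (k in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r_mid <- rate_at(mid)
    if (abs(r_mid - target) <= tol * target) break
    # tonic f-I curves are increasing in drive
    if ((r_mid < target) == (r_hi >= r_lo)) lo <- mid else hi <- mid
  }
  structure(mid, rate = r_mid)
}

#' Scale the calcium sensitivity of the KCa channel
#'
#' Multiplies the steady-state activation of the calcium-activated K
#' channel by a coupling coefficient, scaling how strongly calcium
#' influx through the calcium channels recruits the K current.
#'
#' @param config a [neuron_config()]
#' @param c coupling coefficient (> 0; 1 leaves the model unchanged)
#' @return a modified `neuron_config`
#' @export
set_coupling <- function(config, c) {
  stopifnot(c > 0)
  config$coupling_c <- c
  config
}

#' Uncouple the KCa channel from intracellular calcium
#'
#' Fixes the calcium term of the KCa steady-state activation at a
#' constant concentration (default 15 uM, the mean intracellular
#' calcium at the baseline firing rate) while the calcium pool itself
#' keeps running for the calcium reversal potential.
#'
#' @param config a [neuron_config()]
#' @param fixed_ca calcium seen by the KCa activation, uM
#' @return a modified `neuron_config`
#' @export
uncouple_kca <- function(config, fixed_ca = 15) {
  stopifnot(fixed_ca > 0)
  config$kca_fixed_ca <- fixed_ca
  config
}

#' Shift the h channel's activation into the dynamic voltage window
#'
#' Returns a config whose h-type channel activation curve is
#' half-maximal at `v_half` (default -50 mV instead of the baseline -75
#' mV), slope unchanged: the activation-shift experiment that turns the
#' otherwise gain-neutral h channel into a gain modulator.
#'
#' @param config a [neuron_config()]
#' @param v_half new half-activation voltage, mV
#' @return a modified `neuron_config`
#' @export
shift_h_activation <- function(config, v_half = -50) {
  config$specs$h <- shift_activation(config$specs$h, v_half)
  config
}
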