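# Spike extraction and trace statistics. Spikes are upward threshold
# crossings of the sampled membrane potential; the model's action
# potentials overshoot far above any mid-range threshold, so detection is
# insensitive to the exact threshold (asserted by a property test).

#' Detect spikes in a simulated trace
#'
#' One spike per upward crossing of `threshold`; crossings closer than
#' `min_isi` are merged into one. Only the post-transient part of the
#' trace is searched.
#'
#' @param trace a `neuron_trace`
#' @param threshold detection threshold, mV
#' @param min_isi minimum separation between spikes, ms
#' @return an object of class `spike_train`: spike times (ms) plus the
#'   analysis window
#' @export
detect_spikes <- function(trace, threshold = -10, min_isi = 4) {
  idx <- post_transient(trace)
  v <- trace$V[idx]
  tt <- trace$time[idx]
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1
  times <- tt[up]
  if (length(times) > 1) {
    keep <- c(TRUE, diff(times) >= min_isi)
    times <- times[keep]
  }
  structure(list(times = times,
                 window = c(trace$transient, max(trace$time))),
            class = "spike_train")
}

#' Mean firing rate of a spike train
#'
#' Spike count divided by the analysis-window length.
#'
#' @param spikes a `spike_train`
#' @return firing rate, Hz
#' @export
firing_rate <- function(spikes) {
  w <- diff(spikes$window)
  stopifnot(w > 0)
  length(spikes$times) / (w / 1000)
}

#' Interval-based rate estimate for regular spike trains
#'
#' For a tonic train, `(n - 1) / (t_n - t_1)` estimates the same mean
#' rate as [firing_rate()] but is continuous-valued: it avoids the
#' 1/window quantization of the plain count, which matters when small
#' gain differences are read off fitted tuning-curve derivatives. Falls
#' back to the windowed count for trains with fewer than 2 spikes.
#'
#' @param spikes a `spike_train`
#' @return firing rate, Hz
#' @export
interval_rate <- function(spikes) {
  n <- length(spikes$times)
  if (n < 2) return(firing_rate(spikes))
  1000 * (n - 1) / (spikes$times[n] - spikes$times[1])
}

#' Classify the firing pattern of a spike train
#'
#' `"silent"` for fewer than 3 spikes; `"tonic"` when the coefficient of
#' variation of the inter-spike intervals is below `cv_max`; otherwise
#' `"non-tonic"` (irregular or bursting). The analyses in this package
#' are restricted to the tonic regime; non-tonic points are flagged and
#' excluded from gain fits.
#'
#' @param spikes a `spike_train`
#' @param cv_max CV cutoff for tonic firing
#' @return one of `"silent"`, `"tonic"`, `"non-tonic"`
#' @export
classify_pattern <- function(spikes, cv_max = 0.1) {
  if (length(spikes$times) < 3) return("silent")
  isi <- diff(spikes$times)
  cv <- stats::sd(isi) / mean(isi)
  if (cv < cv_max) "tonic" else "non-tonic"
}

#' Voltage-occupancy histogram
#'
#' Percentage of post-transient time the membrane spends in each voltage
#' bin. On the uniform output grid, sample counting equals time.
#'
#' @param trace a `neuron_trace`
#' @param bin_width bin width, mV
#' @param v_range histogram span, mV
#' @return an object of class `occupancy_histogram` with `breaks` (mV)
#'   and `percent` per bin (sums to 100)
#' @export
voltage_occupancy <- function(trace, bin_width = 1, v_range = c(-90, 60)) {
  stopifnot(bin_width > 0)
  v <- trace$V[post_transient(trace)]
  lo <- min(v_range[1], floor(min(v)))
  hi <- max(v_range[2], ceiling(max(v)))
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  counts <- graphics::hist(v, breaks = breaks, plot = FALSE)$counts
  structure(list(breaks = breaks, percent = 100 * counts / length(v)),
            class = "occupancy_histogram")
}

#' Time-averaged membrane potential of a trace
#'
#' Unweighted mean over the post-transient window, spikes included.
#'
#' @param trace a `neuron_trace`
#' @return mean membrane potential, mV
#' @export
mean_voltage <- function(trace) {
  idx <- post_transient(trace)
  stopifnot(length(idx) > 0)
  mean(trace$V[idx])
}

#' Time-averaged intracellular calcium of a trace
#'
#' @param trace a `neuron_trace`
#' @return mean intracellular calcium, uM
#' @export
mean_calcium <- function(trace) {
  idx <- post_transient(trace)
  stopifnot(length(idx) > 0)
  mean(trace$ca[idx])
}

#' @export
print.spike_train <- function(x, ...) {
  cat("<spike_train>", length(x$times), "spikes in [",
      x$window[1], ",", x$window[2], "] ms (",
      signif(firing_rate(x), 4), "Hz )\n")
  invisible(x)
}
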