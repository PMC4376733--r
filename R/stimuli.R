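# Synthetic depolarizing stimuli: a sustained (tonic) current step, or a
# train of brief rectangular current impulses separated by exponentially
# distributed gaps (a renewal "synaptic" input). Current densities are
# uA/cm2, depolarizing positive.

#' Tonic current step
#'
#' A sustained driving current of fixed amplitude switched on at `onset`.
#' The sweep range used throughout the gain analyses is 0 to 2 uA/cm2;
#' larger amplitudes are accepted with a warning.
#'
#' @param amplitude current density, uA/cm2 (must be nonnegative)
#' @param onset switch-on time, ms
#' @return an object of class `stimulus_protocol`
#' @export
tonic_current <- function(amplitude, onset = 0) {
  if (amplitude < 0) stop("amplitude must be nonnegative")
  if (amplitude > 2)
    warning("tonic amplitude ", amplitude,
            " uA/cm2 exceeds the standard 0-2 sweep range")
  structure(list(kind = "tonic", amplitude = amplitude, onset = onset,
                 width = NA_real_, lambda = NA_real_, seed = NA_integer_),
            class = "stimulus_protocol")
}

#' No stimulus
#'
#' @return a `stimulus_protocol` injecting zero current
#' @export
zero_stimulus <- function() {
  structure(list(kind = "zero", amplitude = 0, onset = 0,
                 width = NA_real_, lambda = NA_real_, seed = NA_integer_),
            class = "stimulus_protocol")
}

#' Poisson-interval synaptic impulse train
#'
#' A train of non-overlapping rectangular impulses (2 ms wide, 0.75
#' uA/cm2 by default) whose gaps -- from the end of one impulse to the
#' start of the next -- are independent exponential variates with mean
#' `lambda`. Input intensity is controlled by `lambda` (0.5 to 30 ms in
#' the standard sweeps; smaller means denser input). The train is fully
#' determined by `seed`: the impulse-onset list is reproduced exactly on
#' every realization.
#'
#' @param lambda mean inter-impulse gap, ms; must be positive
#' @param seed integer RNG seed for the gap sequence
#' @param amplitude impulse height, uA/cm2
#' @param width impulse width, ms
#' @param onset start of the train, ms
#' @return an object of class `stimulus_protocol`
#' @export
synaptic_train <- function(lambda, seed, amplitude = 0.75, width = 2,
                           onset = 0) {
  if (lambda <= 0) stop("lambda must be positive")
  if (lambda < 0.5 || lambda > 30)
    warning("lambda ", lambda, " ms is outside the standard 0.5-30 ms range")
  if (amplitude < 0) stop("amplitude must be nonnegative")
  stopifnot(width > 0)
  structure(list(kind = "synaptic", amplitude = amplitude, onset = onset,
                 width = width, lambda = lambda, seed = as.integer(seed)),
            class = "stimulus_protocol")
}

#' Realize the impulse-onset times of a stimulus over a time span
#'
#' For a synaptic train, draws the exponential gap sequence under the
#' protocol's seed (isolated from the global RNG state) until the span is
#' covered; deterministic for a fixed protocol. Tonic and zero stimuli
#' have no impulses.
#'
#' @param protocol a `stimulus_protocol`
#' @param duration span to cover, ms
#' @return numeric vector of impulse onset times, ms
#' @export
realize_pulses <- function(protocol, duration) {
  if (!identical(protocol$kind, "synaptic")) return(numeric(0))
  onsets <- withr::with_seed(protocol$seed, {
    # expected pulse count is duration/(width + lambda); draw in blocks
    out <- numeric(0)
    t <- protocol$onset
    repeat {
      n <- max(64, ceiling(1.3 * (duration - t) /
                             (protocol$width + protocol$lambda)))
      gaps <- stats::rexp(n, rate = 1 / protocol$lambda)
      starts <- t + cumsum(gaps + protocol$width) - protocol$width
      out <- c(out, starts)
      t <- out[length(out)] + protocol$width
      if (t > duration) break
    }
    out[out <= duration]
  })
  onsets
}

#' Evaluate a stimulus on a time grid
#'
#' @param protocol a `stimulus_protocol`
#' @param times times, ms
#' @param pulses optional pre-realized onset list (synaptic)
#' @return current density at each time, uA/cm2
#' @export
stimulus_current <- function(protocol, times, pulses = NULL) {
  switch(protocol$kind,
    zero = rep(0, length(times)),
    tonic = ifelse(times >= protocol$onset, protocol$amplitude, 0),
    synaptic = {
      if (is.null(pulses)) pulses <- realize_pulses(protocol, max(times))
      if (length(pulses) == 0) return(rep(0, length(times)))
      idx <- findInterval(times, pulses)
      on <- idx >= 1 & (times - pulses[pmax(idx, 1)]) < protocol$width
      ifelse(on, protocol$amplitude, 0)
    })
}

#' Mean injected current of a stimulus
#'
#' The time average of the injected current: the amplitude itself for a
#' tonic step, zero for no stimulus, and the renewal-process expectation
#' `amplitude * width / (width + lambda)` for the synaptic train (1.5 /
#' (2 + lambda) uA/cm2 at the standard impulse shape). This places tonic
#' and synaptic runs on a common input axis for tuning curves.
#'
#' @param protocol a `stimulus_protocol`
#' @param window averaging window, ms (unused for the analytic forms)
#' @return mean current density, uA/cm2
#' @export
mean_input <- function(protocol, window = NULL) {
  switch(protocol$kind,
    zero = 0,
    tonic = protocol$amplitude,
    synaptic = protocol$amplitude * protocol$width /
      (protocol$width + protocol$lambda))
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("<stimulus_protocol>", x$kind, "\n")
  if (x$kind == "tonic")
    cat("  amplitude", x$amplitude, "uA/cm2 from t =", x$onset, "ms\n")
  if (x$kind == "synaptic")
    cat("  impulses", x$amplitude, "uA/cm2 x", x$width,
        "ms, mean gap", x$lambda, "ms, seed", x$seed, "\n")
  invisible(x)
}
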