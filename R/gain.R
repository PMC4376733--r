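# Tuning curves (current-frequency relationships), maximal gain by
# spline or cubic-polynomial derivative, conductance sweeps, and the
# per-channel impact on gain.

derive_seed <- function(seed, level_index, replicate = 0L) {
  # deterministic per-level seeds: adding levels never perturbs existing
  as.integer((as.numeric(seed) * 131 + level_index * 7919 +
                replicate * 104729) %% 2147483647)
}

#' Current-frequency tuning curve
#'
#' Simulates the model at each input level and records the firing rate
#' and firing-pattern class. Tonic inputs are sustained current steps;
#' synaptic inputs are Poisson-interval impulse trains whose intensity
#' levels are mean inter-impulse gaps (`lambda`, ms) and whose rates are
#' averaged over several seeds per level. The synaptic input axis is the
#' analytic mean injected current so both kinds share units.
#'
#' @param config a [neuron_config()]
#' @param kind `"tonic"` or `"synaptic"`
#' @param levels tonic amplitudes (uA/cm2, increasing) or synaptic
#'   `lambda` values (ms); at least 6
#' @param seeds integer seeds for synaptic replicates (one rate average
#'   per level over all seeds)
#' @param duration,transient simulation span per level, ms
#' @param threshold,min_isi spike-detection settings
#' @return a data frame of class `tuning_curve` with columns `input`
#'   (uA/cm2), `level` (the raw level), `rate` (Hz), `pattern`;
#'   attributes carry `kind` and the config
#' @export
tuning_curve <- function(config, kind = c("tonic", "synaptic"),
                         levels = seq(0, 2, length.out = 21),
                         seeds = 1:5, duration = 12000, transient = 2000,
                         threshold = -10, min_isi = 4) {
  kind <- match.arg(kind)
  if (length(levels) < 6) stop("at least 6 input levels are required")
  rows <- lapply(seq_along(levels), function(i) {
    lev <- levels[i]
    if (kind == "tonic") {
      tr <- simulate_neuron(config, tonic_current(lev), duration, transient)
      sp <- detect_spikes(tr, threshold, min_isi)
      data.frame(input = lev, level = lev, rate = interval_rate(sp),
                 pattern = classify_pattern(sp))
    } else {
      rates <- numeric(length(seeds))
      pats <- character(length(seeds))
      for (k in seq_along(seeds)) {
        stim <- synaptic_train(lev, seed = derive_seed(seeds[k], i))
        tr <- simulate_neuron(config, stim, duration, transient)
        sp <- detect_spikes(tr, threshold, min_isi)
        rates[k] <- firing_rate(sp)
        pats[k] <- classify_pattern(sp)
      }
      # synaptic drive is irregular by construction; only silence is
      # excluded from the fit
      pat <- if (all(pats == "silent")) "silent" else "tonic"
      data.frame(input = mean_input(synaptic_train(lev, 1L)), level = lev,
                 rate = mean(rates), pattern = pat)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$input), ]
  rownames(out) <- NULL
  if (all(out$pattern == "silent")) stop("no firing range: all levels silent")
  structure(out, kind = kind, config = config,
            class = c("tuning_curve", "data.frame"))
}

fit_points <- function(curve) {
  ok <- curve$pattern == "tonic"
  curve[ok, , drop = FALSE]
}

#' Maximal gain of a tuning curve
#'
#' Fits the firing-rate-vs-input relationship of the tonic-labelled
#' points and returns the maximum of the fitted first derivative over the
#' fitted input range, evaluated on a dense grid. Tonic curves use a
#' cubic smoothing spline with smoothness chosen by generalized
#' cross-validation; synaptic curves use a third-order polynomial (their
#' rates carry between-simulation variability).
#'
#' @param curve a [tuning_curve()]
#' @param n_grid size of the dense derivative grid
#' @return a list of class `gain_result`: `gain` (Hz uA^-1 cm^2), `at`
#'   (input where the maximum occurs), `method`
#' @export
maximal_gain <- function(curve, n_grid = 200) {
  pts <- fit_points(curve)
  if (nrow(pts) < 4)
    stop("too few tonic points (", nrow(pts), ") to fit a tuning curve")
  method <- if (identical(attr(curve, "kind"), "synaptic"))
    "cubic-polynomial" else "spline"
  xg <- seq(min(pts$input), max(pts$input), length.out = n_grid)
  if (method == "spline") {
    fit <- stats::smooth.spline(pts$input, pts$rate, cv = FALSE)
    dg <- stats::predict(fit, xg, deriv = 1)$y
  } else {
    fit <- stats::lm(rate ~ input + I(input^2) + I(input^3), data = pts)
    b <- stats::coef(fit)
    dg <- b[2] + 2 * b[3] * xg + 3 * b[4] * xg^2
  }
  i <- which.max(dg)
  structure(list(gain = dg[i], at = xg[i], method = method),
            class = "gain_result")
}

#' @export
print.gain_result <- function(x, ...) {
  cat("<gain_result> maximal gain", signif(x$gain, 5),
      "Hz uA^-1 cm^2 at input", signif(x$at, 4), "uA/cm2 (",
      x$method, "fit )\n")
  invisible(x)
}

with_gbar <- function(config, channel, value) {
  g <- config$gbar
  g[[channel]] <- value
  config$gbar <- g
  config
}

#' Sweep a channel's maximal conductance and track maximal gain
#'
#' Rebuilds the tuning curve and maximal gain at each conductance value.
#' Values whose curves have too few tonic points to fit (the firing
#' pattern constraint) are flagged rather than fitted.
#'
#' @param config base [neuron_config()]
#' @param channel channel name
#' @param gbar_values conductances to test, mS/cm2 (should include the
#'   baseline)
#' @param ... passed to [tuning_curve()]
#' @param kind stimulus kind for the curves
#' @return a data frame of class `gain_sweep`: `channel`, `gbar`,
#'   `percent` (of baseline), `gain`, `gain_at`, `n_tonic`, `ok`
#' @export
conductance_sweep <- function(config, channel, gbar_values,
                              kind = "tonic", ...) {
  channel <- match.arg(channel, .channel_order)
  base_g <- .default_gbar[[channel]]
  rows <- lapply(gbar_values, function(g) {
    cfg <- with_gbar(config, channel, g)
    res <- tryCatch({
      curve <- tuning_curve(cfg, kind = kind, ...)
      gr <- maximal_gain(curve)
      data.frame(channel = channel, gbar = g,
                 percent = if (base_g > 0) 100 * g / base_g else NA_real_,
                 gain = gr$gain, gain_at = gr$at,
                 n_tonic = sum(curve$pattern == "tonic"), ok = TRUE)
    }, error = function(e) {
      warning("gbar ", g, " for ", channel, " excluded: ",
              conditionMessage(e), call. = FALSE)
      data.frame(channel = channel, gbar = g,
                 percent = if (base_g > 0) 100 * g / base_g else NA_real_,
                 gain = NA_real_, gain_at = NA_real_, n_tonic = 0L,
                 ok = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("gain_sweep", "data.frame"))
}

#' Impact of a channel on maximal gain
#'
#' The slope of percent change in maximal gain against percent change in
#' maximal conductance, evaluated at the baseline (100%) point by a
#' central difference over a +-30% sweep (the physiological modulation
#' range): conductances at 70, 85, 100, 115 and 130% of baseline.
#'
#' @param config base [neuron_config()]
#' @param channel channel name with nonzero baseline conductance
#' @param percents conductance grid, percent of baseline
#' @param ... passed to [tuning_curve()]
#' @return a list of class `impact_result`: `channel`, `impact`
#'   (% gain per % conductance), and the underlying `sweep`
#' @export
gain_impact <- function(config, channel,
                        percents = c(70, 85, 100, 115, 130), ...) {
  channel <- match.arg(channel, .channel_order)
  base_g <- config$gbar[[channel]]
  if (base_g <= 0)
    stop("channel ", channel, " has zero baseline conductance")
  stopifnot(100 %in% percents, length(percents) >= 3)
  percents <- sort(percents)
  sweep <- conductance_sweep(config, channel,
                             gbar_values = base_g * percents / 100, ...)
  sweep$percent <- percents  # percent of the *config's* baseline
  if (!sweep$ok[sweep$percent == 100])
    stop("model is not tonic over the input range at baseline ", channel)
  g100 <- sweep$gain[sweep$percent == 100]
  pg <- 100 * sweep$gain / g100
  i100 <- which(sweep$percent == 100)
  lo <- i100 - 1L
  hi <- i100 + 1L
  if (lo < 1 || hi > nrow(sweep) || !sweep$ok[lo] || !sweep$ok[hi])
    stop("neighbors of the 100% point are missing or non-tonic")
  impact <- (pg[hi] - pg[lo]) / (sweep$percent[hi] - sweep$percent[lo])
  structure(list(channel = channel, impact = impact, sweep = sweep),
            class = "impact_result")
}

#' @export
print.impact_result <- function(x, ...) {
  cat("<impact_result>", x$channel, ": ",
      signif(x$impact, 4), "% gain per % conductance at baseline\n")
  invisible(x)
}
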