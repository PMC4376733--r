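# Model configuration and the membrane equations.
#
# All currents are current densities in uA/cm2, outward positive, so the
# membrane equation reads Cm dV/dt = I_stim - sum(I_channel) with a
# depolarizing stimulus entered as a positive I_stim. Conductances are
# mS/cm2, potentials mV, time ms, intracellular calcium uM.

.channel_order <- c("Na", "CaS", "CaT", "A", "KCa", "Kd", "h",
                    "leak", "e", "i")

.default_gbar <- c(Na = 200, CaS = 4, CaT = 0, A = 10, KCa = 10,
                   Kd = 125, h = 0.05, leak = 0.04, e = 0, i = 0)

.default_erev <- c(Na = 50, CaS = NA, CaT = NA, A = -80, KCa = -80,
                   Kd = -80, h = -20, leak = -50, e = -20, i = -90)

#' Calcium-handling parameters
#'
#' The intracellular calcium pool rises with calcium influx through the
#' CaS and CaT channels and relaxes back to its baseline with time
#' constant `tau_ca` (a single exponentially decaying pool standing for
#' diffusion, buffering and sequestration):
#' `tau_ca * d[Ca]/dt = -f * (I_CaS + I_CaT) - ([Ca] - ca_base)`,
#' so `f` converts a calcium-current density directly into a
#' concentration (uM per uA/cm2) and enters the rate through the removal
#' time constant. The calcium reversal potential of the two calcium
#' channels follows the Nernst equation at body temperature.
#'
#' The Nernst valence `z` defaults to 2 (the charge of the calcium ion)
#' with a natural logarithm, which gives a reversal near +147 mV at the
#' 0.05 uM baseline and reproduces the model's 5 Hz spontaneous rate; see
#' the methods vignette for the calibration of this convention.
#'
#' @param tau_ca calcium removal time constant, ms
#' @param f conversion from calcium-current density to concentration,
#'   uM cm2 / uA
#' @param ca_base baseline intracellular calcium, uM
#' @param ca_out extracellular calcium, uM (3 mM)
#' @param temperature temperature, K
#' @param z Nernst charge number
#' @param log_base `"ln"` or `"log10"` in the Nernst expression
#' @return a list of class `calcium_config`
#' @export
calcium_config <- function(tau_ca = 200, f = 14.96, ca_base = 0.05,
                           ca_out = 3000, temperature = 310, z = 2,
                           log_base = c("ln", "log10")) {
  log_base <- match.arg(log_base)
  stopifnot(tau_ca > 0, f > 0, ca_base > 0, ca_out > 0, z > 0)
  R <- 8.3145      # J / (K mol)
  F <- 96485       # C / mol
  nernst_mv <- 1000 * R * temperature / (z * F)
  if (log_base == "log10") nernst_mv <- nernst_mv / log(10)
  structure(list(tau_ca = tau_ca, f = f, ca_base = ca_base,
                 ca_out = ca_out, temperature = temperature, z = z,
                 log_base = log_base, gas_constant = R, faraday = F,
                 nernst_mv = nernst_mv),
            class = "calcium_config")
}

#' Reversal potential of the calcium channels
#'
#' Nernst potential for the configured extracellular concentration,
#' temperature, charge number and logarithm convention.
#'
#' @param ca_i intracellular calcium, uM; must be positive
#' @param cfg a [calcium_config()]
#' @return reversal potential, mV
#' @examples
#' calcium_reversal(0.05, calcium_config())   # about +147 mV
#' @export
calcium_reversal <- function(ca_i, cfg = calcium_config()) {
  if (any(ca_i <= 0)) stop("ca_i must be positive")
  # nernst_mv already absorbs the log-base conversion, so the natural log
  # is used here for either convention
  cfg$nernst_mv * log(cfg$ca_out / ca_i)
}

#' Full neuron parameterization
#'
#' Assembles the complete single-compartment model: membrane capacitance,
#' the ten channels (maximal conductances and reversal potentials, with
#' the calcium channels' reversal dynamic), calcium handling, the
#' coupling state of the calcium-activated K channel, and the channel
#' kinetic specifications. Defaults are the baseline tonically-firing
#' parameter set.
#'
#' The KCa channel is by default coupled to the intracellular calcium
#' state. [uncouple_kca()] fixes the calcium term of its activation at a
#' constant concentration (while the calcium pool still runs, for the
#' calcium reversal); [set_coupling()] scales its steady-state activation
#' by a coupling coefficient.
#'
#' @param gbar named numeric vector of maximal conductance overrides,
#'   mS/cm2 (names among Na, CaS, CaT, A, KCa, Kd, h, leak, e, i)
#' @param erev named numeric vector of reversal-potential overrides, mV
#'   (CaS/CaT reversals are always dynamic and cannot be overridden)
#' @param cm specific membrane capacitance, uF/cm2
#' @param calcium a [calcium_config()]
#' @param specs channel kinetics, as from [default_channels()]
#' @param coupling_c KCa coupling coefficient (1 = unmodified)
#' @param kca_fixed_ca fixed calcium (uM) seen by KCa activation, or `NA`
#'   for the coupled state
#' @return an object of class `neuron_config`
#' @export
neuron_config <- function(gbar = NULL, erev = NULL, cm = 0.6,
                          calcium = calcium_config(),
                          specs = default_channels(),
                          coupling_c = 1, kca_fixed_ca = NA_real_) {
  stopifnot(cm > 0, coupling_c > 0)
  if (!is.na(kca_fixed_ca) && kca_fixed_ca <= 0)
    stop("kca_fixed_ca must be positive")
  g <- .default_gbar
  e <- .default_erev
  if (!is.null(gbar)) {
    bad <- setdiff(names(gbar), .channel_order)
    if (length(bad)) stop("unknown channel(s) in gbar: ",
                          paste(bad, collapse = ", "))
    if (any(gbar < 0)) stop("negative conductance for channel(s): ",
                            paste(names(gbar)[gbar < 0], collapse = ", "))
    g[names(gbar)] <- gbar
  }
  if (!is.null(erev)) {
    bad <- setdiff(names(erev), setdiff(.channel_order, c("CaS", "CaT")))
    if (length(bad)) stop("cannot set reversal for: ",
                          paste(bad, collapse = ", "))
    e[names(erev)] <- erev
  }
  stopifnot(identical(sort(names(specs)), sort(.channel_order)))
  structure(list(cm = cm, gbar = g, erev = e, calcium = calcium,
                 specs = specs, coupling_c = coupling_c,
                 kca_fixed_ca = kca_fixed_ca),
            class = "neuron_config")
}

#' @export
print.neuron_config <- function(x, ...) {
  cat("<neuron_config> Cm =", x$cm, "uF/cm2\n")
  cat("  gbar (mS/cm2):",
      paste(names(x$gbar), signif(x$gbar, 4), sep = "=", collapse = " "),
      "\n")
  mode <- if (!is.na(x$kca_fixed_ca))
    paste0("uncoupled (Ca fixed at ", x$kca_fixed_ca, " uM)")
  else if (x$coupling_c != 1)
    paste0("coupled, coefficient ", x$coupling_c)
  else "coupled"
  cat("  KCa coupling:", mode, "\n")
  invisible(x)
}

#' Current density through one channel
#'
#' Ohmic current `gbar * m^rho * h * (V - E)` for gated channels and
#' `gbar * (V - E)` for passive ones, outward positive. The calcium
#' channels use the dynamic Nernst reversal at the state's intracellular
#' calcium.
#'
#' @param name channel name
#' @param config a [neuron_config()]
#' @param state a [neuron_state()]
#' @return current density, uA/cm2 (outward positive)
#' @export
channel_current <- function(name, config, state) {
  name <- match.arg(name, .channel_order)
  g <- config$gbar[[name]]
  if (g == 0) return(0)
  E <- if (name %in% c("CaS", "CaT"))
    calcium_reversal(state$ca, config$calcium)
  else config$erev[[name]]
  spec <- config$specs[[name]]
  if (!is_gated(spec)) return(g * (state$V - E))
  m <- state$m[[name]]
  h <- if (!is.null(spec$inact)) state$h[[name]] else 1
  g * m^spec$rho * h * (state$V - E)
}

#' Construct a model state
#'
#' @param V membrane potential, mV
#' @param m named list/vector of activation variables (gated channels)
#' @param h named list/vector of inactivation variables (Na, CaS, CaT, A)
#' @param ca intracellular calcium, uM
#' @return an object of class `neuron_state`
#' @export
neuron_state <- function(V, m, h, ca) {
  stopifnot(is.finite(V), all(unlist(m) >= 0), ca > 0)
  structure(list(V = V, m = m, h = h, ca = ca), class = "neuron_state")
}

#' Steady-state initial condition at a holding potential
#'
#' Every gating variable is set to its steady-state value at `V0` (using
#' the baseline calcium concentration for the KCa channel, or the fixed
#' value in the uncoupled state) and the calcium pool starts at its
#' baseline.
#'
#' @param config a [neuron_config()]
#' @param V0 initial membrane potential, mV
#' @return a `neuron_state`
#' @export
initial_state <- function(config, V0 = -65) {
  ca0 <- config$calcium$ca_base
  ca_for_kca <- if (!is.na(config$kca_fixed_ca)) config$kca_fixed_ca else ca0
  m <- list(); h <- list()
  for (n in gated_channel_names()) {
    spec <- config$specs[[n]]
    g <- eval_gating(spec, V0, Ca = if (spec$ca_dep) ca_for_kca else NULL)
    m[[n]] <- if (identical(n, "KCa")) config$coupling_c * g$m_inf else g$m_inf
    if (!is.null(spec$inact)) h[[n]] <- g$h_inf
  }
  neuron_state(V = V0, m = m, h = h, ca = ca0)
}

#' Time derivative of the full model state
#'
#' Reference R implementation of the membrane, gating and calcium
#' equations: `Cm dV/dt = I_stim - sum(I)`, first-order relaxation of
#' every gating variable to its voltage-dependent steady state, and the
#' calcium pool driven by the calcium currents. The compiled integrator
#' used by [simulate_neuron()] implements the same dynamics; a test keeps
#' the two in agreement.
#'
#' @param state a `neuron_state`
#' @param config a [neuron_config()]
#' @param i_stim stimulus current density, uA/cm2 (depolarizing positive)
#' @return a list with `dV`, `dm`, `dh`, `dca` (per ms)
#' @export
state_derivative <- function(state, config, i_stim = 0) {
  stopifnot(is.finite(i_stim))
  currents <- vapply(.channel_order, channel_current, numeric(1),
                     config = config, state = state)
  dV <- (i_stim - sum(currents)) / config$cm
  ca_for_kca <- if (!is.na(config$kca_fixed_ca)) config$kca_fixed_ca
                else state$ca
  dm <- list(); dh <- list()
  for (n in gated_channel_names()) {
    spec <- config$specs[[n]]
    g <- eval_gating(spec, state$V,
                     Ca = if (spec$ca_dep) ca_for_kca else NULL)
    m_inf <- if (identical(n, "KCa")) config$coupling_c * g$m_inf else g$m_inf
    dm[[n]] <- (m_inf - state$m[[n]]) / g$tau_m
    if (!is.null(spec$inact)) dh[[n]] <- (g$h_inf - state$h[[n]]) / g$tau_h
  }
  dca <- (-config$calcium$f * (currents[["CaT"]] + currents[["CaS"]]) -
    (state$ca - config$calcium$ca_base)) / config$calcium$tau_ca
  list(dV = dV, dm = dm, dh = dh, dca = dca)
}
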