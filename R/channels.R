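#' @useDynLib neurogain
NULL

#' Gating-function constructors
#'
#' Every steady-state curve in the model's kinetics is a Boltzmann
#' sigmoid `1/(1 + exp((V + a)/k))`; time constants are scaled sigmoids
#' `c0 + c1/(1 + exp((V + a)/k))`, two-exponential quotients
#' `c0 + c1/(exp((V + a1)/k1) + exp((V + a2)/k2))`, or (for the Na
#' inactivation time constant) a product of two scaled sigmoids.
#' Constants are stored exactly as tabulated; these constructors let a
#' user assemble modified kinetics that flow straight into the compiled
#' integrator via [channel_spec] objects.
#'
#' @param a,a1,a2 offset constants, mV (the sigmoid half-voltage is `-a`)
#' @param k,k1,k2 slope constants, mV (negative: increasing with V)
#' @param c0,c1 additive and multiplicative constants (ms for time
#'   constants)
#' @param f1,f2 two `gating_function`s of scaled-sigmoid form
#' @return an object of class `gating_function`
#' @name gating_function
NULL

#' @rdname gating_function
#' @export
gate_sigmoid <- function(a, k) {
  structure(list(form = "sigmoid", a = a, k = k), class = "gating_function")
}

#' @rdname gating_function
#' @export
gate_scaled_sigmoid <- function(c0, c1, a, k) {
  structure(list(form = "scaled_sigmoid", c0 = c0, c1 = c1, a = a, k = k),
            class = "gating_function")
}

#' @rdname gating_function
#' @export
gate_exp_pair <- function(c0, c1, a1, k1, a2, k2) {
  structure(list(form = "exp_pair", c0 = c0, c1 = c1,
                 a1 = a1, k1 = k1, a2 = a2, k2 = k2),
            class = "gating_function")
}

#' @rdname gating_function
#' @export
gate_product <- function(f1, f2) {
  structure(list(form = "product", f1 = f1, f2 = f2),
            class = "gating_function")
}

#' Evaluate a gating function on a voltage grid
#'
#' @param gf a `gating_function`
#' @param V membrane potential(s), mV
#' @return numeric vector of the same length as `V`
#' @keywords internal
eval_gatefun <- function(gf, V) {
  switch(gf$form,
    sigmoid        = 1 / (1 + exp((V + gf$a) / gf$k)),
    scaled_sigmoid = gf$c0 + gf$c1 / (1 + exp((V + gf$a) / gf$k)),
    exp_pair       = gf$c0 + gf$c1 / (exp((V + gf$a1) / gf$k1) +
                                      exp((V + gf$a2) / gf$k2)),
    product        = eval_gatefun(gf$f1, V) * eval_gatefun(gf$f2, V),
    stop("unknown gating function form: ", gf$form)
  )
}

#' Channel kinetic specifications
#'
#' Build the kinetic specification of one membrane channel: the number of
#' activation gates (rho), the steady-state activation and inactivation
#' curves and their time constants, and, for the calcium-activated K
#' channel, the calcium dependence of activation. Defaults reproduce the
#' published kinetics table of the tonically-firing stomatogastric model
#' exactly. Passive channels (leak, e, i) carry no gating functions and
#' rho = 0.
#'
#' Intracellular calcium is expressed in micromolar throughout; the KCa
#' activation factor is `Ca / (Ca + ca_halfsat)` with a half-saturation of
#' 3 uM.
#'
#' @param name one of `"Na"`, `"CaS"`, `"CaT"`, `"A"`, `"KCa"`, `"Kd"`,
#'   `"h"`, `"leak"`, `"e"`, `"i"`
#' @return an object of class `channel_spec`
#' @examples
#' sp <- channel_spec("Kd")
#' eval_gating(sp, V = -50)$m_inf   # about 0.039
#' @export
channel_spec <- function(name) {
  name <- match.arg(name, c("Na", "CaS", "CaT", "A", "KCa", "Kd", "h",
                            "leak", "e", "i"))
  passive <- list(name = name, rho = 0L, ca_dep = FALSE, ca_halfsat = NA_real_,
                  act = NULL, inact = NULL)
  spec <- switch(name,
    Na = list(
      rho = 3L,
      act = list(inf = gate_sigmoid(25.5, -5.9),
                 tau = gate_scaled_sigmoid(2.64, -2.52, 120, -25)),
      inact = list(inf = gate_sigmoid(48.9, 5.18),
                   tau = gate_product(
                     gate_scaled_sigmoid(0, 1.34, 62.9, -10),
                     gate_scaled_sigmoid(1.5, 1, 34.9, -3.6)))),
    CaS = list(
      rho = 3L,
      act = list(inf = gate_sigmoid(33, -8.1),
                 tau = gate_exp_pair(2.8, 14, 27, 10, 70, -13)),
      inact = list(inf = gate_sigmoid(60, 6.2),
                   tau = gate_exp_pair(120, 300, 55, 9, 65, -16))),
    CaT = list(
      rho = 3L,
      act = list(inf = gate_sigmoid(27.1, -7.2),
                 tau = gate_scaled_sigmoid(43.4, -42.6, 68.1, -20.5)),
      inact = list(inf = gate_sigmoid(32.1, 5.5),
                   tau = gate_scaled_sigmoid(210, -179.6, 55, -16.9))),
    A = list(
      rho = 3L,
      act = list(inf = gate_sigmoid(27.2, -8.7),
                 tau = gate_scaled_sigmoid(23.2, -20.8, 32.9, -15.2)),
      inact = list(inf = gate_sigmoid(56.9, 4.9),
                   tau = gate_scaled_sigmoid(77.2, -58.4, 38.9, -26.5))),
    KCa = list(
      rho = 4L,
      act = list(inf = gate_sigmoid(28.3, -12.6),
                 tau = gate_scaled_sigmoid(180.6, -150.2, 46, -22.7)),
      inact = NULL),
    Kd = list(
      rho = 4L,
      act = list(inf = gate_sigmoid(12.3, -11.8),
                 tau = gate_scaled_sigmoid(14.4, -12.8, 28.3, -19.2)),
      inact = NULL),
    h = list(
      rho = 1L,
      act = list(inf = gate_sigmoid(75, 5.5),
                 tau = gate_exp_pair(0, 2, 169.7, -11.6, 26.7, 14.3)),
      inact = NULL),
    NULL)
  if (is.null(spec)) return(structure(passive, class = "channel_spec"))
  structure(list(name = name, rho = spec$rho,
                 ca_dep = identical(name, "KCa"),
                 ca_halfsat = if (identical(name, "KCa")) 3 else NA_real_,
                 act = spec$act, inact = spec$inact),
            class = "channel_spec")
}

#' All ten channel specifications at their published kinetics
#'
#' @return a named list of `channel_spec` objects (Na, CaS, CaT, A, KCa,
#'   Kd, h, leak, e, i)
#' @export
default_channels <- function() {
  nm <- c("Na", "CaS", "CaT", "A", "KCa", "Kd", "h", "leak", "e", "i")
  stats::setNames(lapply(nm, channel_spec), nm)
}

gated_channel_names <- function() c("Na", "CaS", "CaT", "A", "KCa", "Kd", "h")

is_gated <- function(spec) !is.null(spec$act)

#' Evaluate steady states and time constants of a gated channel
#'
#' Returns the four gating quantities at a membrane potential: the
#' steady-state activation `m_inf`, its time constant `tau_m` (ms), and
#' the inactivation pair `h_inf` / `tau_h` (reported as 1 and `NA` for
#' channels without an inactivation gate). For the calcium-activated K
#' channel `m_inf` includes the saturating calcium factor
#' `Ca/(Ca + 3 uM)`.
#'
#' @param spec a gated `channel_spec`
#' @param V membrane potential(s), mV; must be finite
#' @param Ca intracellular calcium, uM; required for the KCa channel
#' @return a list with vectors `m_inf`, `tau_m`, `h_inf`, `tau_h`
#' @export
eval_gating <- function(spec, V, Ca = NULL) {
  stopifnot(inherits(spec, "channel_spec"))
  if (!is_gated(spec))
    stop("channel '", spec$name, "' is passive and has no gating functions")
  if (any(!is.finite(V))) stop("V must be finite")
  m_inf <- eval_gatefun(spec$act$inf, V)
  if (spec$ca_dep) {
    if (is.null(Ca)) stop("Ca is required to evaluate the KCa channel")
    if (any(Ca <= 0)) stop("Ca must be positive")
    m_inf <- (Ca / (Ca + spec$ca_halfsat)) * m_inf
  }
  tau_m <- eval_gatefun(spec$act$tau, V)
  if (is.null(spec$inact)) {
    h_inf <- rep(1, length(V))
    tau_h <- rep(NA_real_, length(V))
  } else {
    h_inf <- eval_gatefun(spec$inact$inf, V)
    tau_h <- eval_gatefun(spec$inact$tau, V)
  }
  list(m_inf = m_inf, tau_m = tau_m, h_inf = h_inf, tau_h = tau_h)
}

#' Shift the half-activation voltage of a channel
#'
#' Returns a copy of the specification whose steady-state activation
#' sigmoid is half-maximal at `v_half` instead of its original
#' half-voltage. The slope of the sigmoid, the activation time constant,
#' and any inactivation functions are unchanged. Used to move a channel's
#' steep activation range into (or out of) the dynamic voltage window.
#'
#' @param spec a `channel_spec` whose activation curve is a plain sigmoid
#' @param v_half new half-activation voltage, mV
#' @return a modified `channel_spec`
#' @examples
#' h50 <- shift_activation(channel_spec("h"), -50)
#' eval_gating(h50, -50)$m_inf   # 0.5
#' @export
shift_activation <- function(spec, v_half) {
  stopifnot(inherits(spec, "channel_spec"))
  if (!is_gated(spec) || !identical(spec$act$inf$form, "sigmoid"))
    stop("channel '", spec$name, "' has no sigmoid activation curve to shift")
  spec$act$inf$a <- -v_half
  spec
}

activation_half_voltage <- function(spec) {
  stopifnot(identical(spec$act$inf$form, "sigmoid"))
  -spec$act$inf$a
}

#' Voltage profile of channel availability
#'
#' Computes `m_inf * h_inf / (tau_m * tau_h)` on a voltage grid, a summary
#' of the voltages at which a channel is simultaneously available and
#' fast: large where the channel activates (and is not inactivated) and
#' responds quickly. Inactivation terms are taken as 1 (and tau_h as 1)
#' for channels without an inactivation gate.
#'
#' @inheritParams eval_gating
#' @param V_grid voltages, mV; must be nonempty
#' @return numeric vector over `V_grid`
#' @export
availability_curve <- function(spec, V_grid, Ca = NULL) {
  if (length(V_grid) == 0) stop("V_grid is empty")
  g <- eval_gating(spec, V_grid, Ca)
  tau_h <- ifelse(is.na(g$tau_h), 1, g$tau_h)
  g$m_inf * g$h_inf / (g$tau_m * tau_h)
}

#' @export
print.channel_spec <- function(x, ...) {
  if (!is_gated(x)) {
    cat("<channel_spec>", x$name, "(passive)\n")
  } else {
    cat("<channel_spec>", x$name, " rho =", x$rho,
        if (x$ca_dep) " (calcium-dependent)" else "", "\n")
    if (identical(x$act$inf$form, "sigmoid"))
      cat("  activation half-voltage:", activation_half_voltage(x), "mV\n")
    cat("  inactivation:", if (is.null(x$inact)) "none" else "yes", "\n")
  }
  invisible(x)
}
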