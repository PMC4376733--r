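---
title: "Gain analysis in a tonically firing conductance-based neuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gain analysis in a tonically firing conductance-based neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`neurogain` simulates a single-compartment, Hodgkin-Huxley-type model of a
tonically firing neuron — the classic lobster stomatogastric parameterization
with seven voltage-gated channels — and quantifies how the expression level
(maximal conductance density) of each channel controls the *gain* of the
cell: the slope of its current–frequency (f–I) relationship. This vignette
is the package's methods reference: the model and its assumptions, the
conventions and tunable parameters, the numerical choices, and the known
limitations, including a kinetic sensitivity that materially changes the
headline results.

## The model

### Membrane and channels

The membrane potential $V$ (mV) of a single isopotential compartment obeys

$$C_m \frac{dV}{dt} = I_{\mathrm{stim}} - \sum_{\mathrm{ion}} I_{\mathrm{ion}},$$

with specific capacitance $C_m = 0.6\ \mu\mathrm{F\,cm^{-2}}$ by default and
all currents as densities in $\mu\mathrm{A\,cm^{-2}}$, **outward positive**;
a depolarizing stimulus enters as positive $I_{\mathrm{stim}}$. Each gated
channel carries

$$I_{\mathrm{ion}} = \bar G_{\mathrm{ion}}\, m^{\rho} h \,(V - E_{\mathrm{ion}}),$$

where $\bar G_{\mathrm{ion}}$ is the maximal specific conductance
(mS cm⁻²), $\rho$ the number of activation gates, and $m, h$ first-order
gating variables relaxing to voltage-dependent steady states:
$\dot m = (m_\infty - m)/\tau_m$, $\dot h = (h_\infty - h)/\tau_h$.
Passive channels (leak, and the optional passive excitatory/inhibitory
conductances `e` and `i`) are ohmic, $I = \bar G (V - E)$.

The ten channels and their baseline parameters (`neuron_config()` defaults):

| channel | $\rho$ | $\bar G$ (mS cm⁻²) | $E$ (mV) |
|---|---|---|---|
| Na | 3 | 200 | +50 |
| CaS (slow Ca²⁺) | 3 | 4 | Nernst, dynamic |
| CaT (fast Ca²⁺) | 3 | 0 | Nernst, dynamic |
| A (fast transient K⁺) | 3 | 10 | −80 |
| KCa (Ca²⁺-activated K⁺) | 4 | 10 | −80 |
| Kd (delayed rectifier) | 4 | 125 | −80 |
| h (hyperpolarization-activated) | 1 | 0.05 | −20 |
| leak | 0 | 0.04 | −50 |
| e / i (passive) | 0 | 0 | −20 / −90 |

Every $m_\infty$ and $h_\infty$ is a Boltzmann sigmoid
$1/(1+e^{(V+a)/k})$ and every time constant is a scaled sigmoid, a
two-exponential quotient, or (for Na inactivation) a product of two such
terms; `channel_spec()` stores the constants exactly as tabulated and
`eval_gating()` evaluates them. The constants are not hard-wired into the
integrator: the compiled right-hand side receives whatever constants the
configuration's channel specs carry, which is how `shift_activation()`
(moving a half-activation voltage with slope preserved) and the
sensitivity analysis below are expressed.

The KCa channel is doubly gated: its steady-state activation is the
voltage sigmoid multiplied by a saturating calcium factor
$[\mathrm{Ca}]/([\mathrm{Ca}]+3\ \mu M)$. All intracellular calcium is
expressed in $\mu M$; the half-saturation constant is read as 3 $\mu M$,
the only reading under which the channel is appreciably open at the
operating calcium of ~13–15 $\mu M$ (at millimolar units the factor would
be ~0.005 and the channel functionally absent, contradicting its strong
gain-reducing role).

### Calcium pool and calcium reversal

Calcium influx through CaS/CaT feeds a single well-mixed pool standing in
for diffusion, buffering and sequestration:

$$\tau_{Ca}\,\frac{d[\mathrm{Ca}]}{dt} = -f\,(I_{CaS}+I_{CaT}) -
\left([\mathrm{Ca}] - [\mathrm{Ca}]_b\right),$$

with $\tau_{Ca} = 200$ ms, baseline $[\mathrm{Ca}]_b = 0.05\ \mu M$, and
$f = 14.96\ \mu M$ per $\mu\mathrm{A\,cm^{-2}}$. Note the form: $f$
converts a current density directly into a concentration, and enters the
*rate* through the removal time constant. Writing the influx term outside
the $\tau_{Ca}$ division (with the same printed $f$) is dimensionally
inconsistent and drives the pool to ~2000 $\mu M$ within 100 ms,
silencing the neuron at a depolarized plateau; the form above is the one
the source lobster-STG model family uses and the one that reproduces a
tonic cell with micromolar operating calcium.

The calcium channels' reversal follows the Nernst equation at
$T = 310$ K with extracellular calcium 3 mM. The charge number and the
logarithm convention are configurable (`calcium_config(z =, log_base =)`)
because printed parameter tables in this literature are ambiguous on both.
The package default is the physical convention for Ca²⁺ — $z = 2$ with a
natural logarithm, giving $E_{Ca} \approx +147$ mV at baseline calcium —
which is also the convention, among $\{z{=}1\ \ln,\ z{=}2\ \ln,\
z{=}1\ \log_{10}\}$, that brings the spontaneous rate and mean calcium
closest to their published operating points (the alternatives give
7.2 Hz / 26.5 µM and 5.6 Hz / 12.1 µM against 5.7 Hz / 13.5 µM).

### Initial condition and transient

The rest state is not specified by the model's sources; the package
starts at $V_0 = -65$ mV with every gate at its steady state and calcium
at baseline, then discards a 2 s transient before computing any
statistic. The cell is an intrinsic oscillator with a single tonic
attractor at baseline, so long-run statistics are insensitive to $V_0$;
the transient policy makes that testable (the rate is stable to 0.1 Hz
across 10 s windows out to 40 s).

## Stimuli

Two synthetic drive families (`tonic_current()`, `synaptic_train()`):

* a sustained current step of 0–2 $\mu\mathrm{A\,cm^{-2}}$ (the standard
  sweep range for tuning curves), and
* a train of 2 ms rectangular impulses of 0.75 $\mu\mathrm{A\,cm^{-2}}$
  whose *gaps* (impulse offset to next onset) are i.i.d. exponential with
  mean $\lambda \in [0.5, 30]$ ms. The gap reading is deliberate: it is
  the only renewal interpretation that remains well defined when
  $\lambda$ (0.5 ms) is shorter than the impulse width (2 ms), and it
  guarantees non-overlapping impulses. Intensity is controlled by
  $\lambda$; the analytic mean current $0.75 \cdot 2/(2+\lambda)$ places
  synaptic runs on the same input axis as tonic runs. Trains are
  deterministic functions of their seed.

The generator emulates fluctuating excitatory drive as *current*
impulses only: no conductance-based (reversal-potential) synapses, no
inhibitory trains, no temporally correlated or bursty statistics. Results
obtained under it speak to input-mean effects, not to synaptic
shunting or variance effects.

## Measurements

**Spikes** are upward crossings of −10 mV with crossings closer than 4 ms
merged. The model's action potentials overshoot +40 mV from a sub −40 mV
base, so any mid-range threshold gives identical counts (asserted as a
property over thresholds −20…0 mV). **Firing rate** is spike count over
the post-transient window; inside tuning curves the equivalent
interval estimate $(n-1)/(t_n - t_1)$ is used instead because it is
continuous-valued — the count's 0.1 Hz quantization (10 s windows) is
visible in fitted derivatives. **Pattern** is `silent` below 3 spikes,
`tonic` when the ISI coefficient of variation is < 0.1 (a declared
convention; the baseline CV is ~0.001), otherwise `non-tonic`; non-tonic
points are flagged and excluded from gain fits. **Voltage occupancy** is
the percent of post-transient samples per 1 mV bin. **Mean membrane
potential** is the unweighted time average including spikes.

## The gain pipeline

A tuning curve (`tuning_curve()`) simulates 12 s (2 s transient) per
input level — 21 levels on [0, 2] $\mu\mathrm{A\,cm^{-2}}$ by default, 11
for the large sweep batteries; synaptic curves average 5 seeds per
$\lambda$. Gain (`maximal_gain()`) is the maximal first derivative of a
fit to the tonic points, evaluated on a 200-point dense grid: a cubic
smoothing spline with generalized cross-validation for tonic curves
(`stats::smooth.spline`; neither the spline family nor the smoothing rule
is prescribed by the sources, so the standard GCV choice is used), and a
third-order polynomial for synaptic curves, whose rates carry
between-simulation variability.

`conductance_sweep()` rebuilds the curve and gain across $\bar G$ values;
`gain_impact()` summarizes a channel's leverage as the slope of percent
gain against percent conductance at the 100% point, by central difference
over $\{70, 85, 100, 115, 130\}\%$ — the ±30% physiological modulation
range. The mechanistic layer (`dynamic_voltage_window()`,
`activation_steepness()`, `steepness_impact_correlation()`,
`current_per_ap_curve()`, `iv_loop()`, `match_firing_rate()`,
`set_coupling()`, `uncouple_kca()`, `shift_h_activation()`) implements
the window/steepness correlation, per-spike average currents over 10
ISIs (starting at the 3rd post-transient spike to avoid onset effects),
4 s current–voltage loops with rate-matched occupancy comparisons
(bisection to 1% rate tolerance), and the coupling and activation-shift
experiments. Defaults chosen where the sources are silent: coupling
coefficients $\{0.5, 0.75, 1, 1.5, 2\}$; steepness evaluated at the
fixed 15 µM calcium for KCa; the correlation set is the five channels
whose conductances the impact analysis varies (A, Kd, KCa, CaS, h).

## Numerical choices

* Integration: `deSolve::lsoda` over a compiled right-hand side,
  `rtol = 1e-7`, `atol = 1e-9`, dense output every 0.25 ms. The tighter-
  than-usual tolerances are deliberate: at 1e-6 the solution drifts
  0.6 mV (spike-phase drift) from a 1 µs fixed-step RK4 reference over
  500 ms; at 1e-7 the drift is 0.06 mV, and a 12 s run still takes ~0.1 s.
  Firing rates are tolerance-converged (identical at 1e-6…1e-10).
* Impulse trains cap the solver's internal step at 1 ms so no 2 ms
  impulse can be stepped over; injected charge matches the renewal
  expectation on the sampled grid.
* Calcium is floored at $10^{-9}\ \mu M$ inside the Nernst term only.
* Degenerate inputs: all-silent tuning curves, unbracketed rate targets,
  non-tonic loops and fewer than 4 tonic fit points are explicit errors,
  not NA results.
* Problem sizes used by the shipped tests and the acceptance script:
  12 s per simulation (2 s transient), 21-level window sweeps, 11-level
  impact sweeps, 8-level short diagnostics; the full suite is ~1,200
  simulations.

## A kinetic sensitivity that changes the headline results

The tabulated sodium inactivation time constant is

$$\tau_h^{Na} = \frac{1.34}{1+e^{(V+62.9)/-10}}\cdot
\left(1.5 + \frac{1}{1+e^{(V+34.9)/-3.6}}\right),$$

whereas the classic stomatogastric parameterization this model descends
from uses amplitude 0.67 and an inverted second slope (+3.6). The package
defaults keep the tabulated constants. The choice matters far beyond
spike shape, and the shipped tests pin down both sides:

* Under the **tabulated** constants the cell fires spontaneously at
  5.7 Hz with mean calcium 13.5 µM — close to the published 5 Hz /
  15 µM operating point — but raising the delayed-rectifier conductance
  *raises* maximal gain (faster spike repolarization means less calcium
  entry per spike, less KCa recruitment, faster recovery), and the
  calcium channel is not the strongest gain modulator.
* Under the **alternative** constants the spontaneous rate is 8.0 Hz and
  mean calcium lower, but the delayed rectifier becomes gain-*reducing*
  and the calcium channel's gain-raising impact strengthens — the
  directional pattern usually reported for this cell type, with the
  gain-modulating power of a channel tracking the steepness of its
  activation curve within the voltage window.

No single parameterization reproduces both the operating point and the
full directional pattern; users probing gain directions should treat
$\tau_h^{Na}$ as a sensitivity axis (`channel_spec` constants are fully
configurable) rather than a settled constant.

## The dynamic voltage window in this model

Across the tonic range the time-averaged membrane potential spans
[−55.7, −52.2] mV and *falls* with drive: the after-spike recovery from
the ~−77 mV AHP costs a roughly fixed ~50 ms, so at higher rates it
occupies a growing fraction of the ISI and pulls the mean down, even
though the occupancy mode stays near −50 mV. A narrow (< 2 mV) window
just below −50 mV would require the mean to be dominated by the
pre-spike plateau at all rates; that regime is not what these kinetics
produce. Steepness measures that depend on the window therefore use the
window the model actually generates.

## Limitations

* Single compartment; no morphology, no conductance-based synapses, no
  temperature ($Q_{10}$) scaling, no stochastic channel gating.
* One well-mixed calcium pool; no microdomains, stores, or buffering
  kinetics — the KCa coupling coefficient is a lumped stand-in for
  spatial proximity.
* Maximal gain on a concave f–I curve sits at the zero-drive edge, where
  it measures the slope of the spontaneous-rate region; anything that
  tonically depolarizes the cell (including the passive `e` conductance)
  moves the operating range into shallower slope and registers as a gain
  change. Mean-gain summaries are deliberately not provided.
* Bursting and irregular regimes are detected (`classify_pattern`) and
  excluded, not analysed.
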