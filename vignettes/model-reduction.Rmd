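---
title: "Reducing a conductance-based neuron with slow K+ currents to an adaptive threshold model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing a conductance-based neuron with slow K+ currents to an adaptive threshold model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matreduce)
```

## The problem

Cortical pyramidal neurons respond to a sustained current step with a burst of
spikes whose rate then declines — spike-frequency adaptation. Two slow K+
currents dominate this behaviour: the muscarinic M-current (`I_M`, a
voltage-gated K+ current with a slow gate `p`) and the Ca2+-activated
afterhyperpolarization current (`I_AHP`, whose gate `s` is driven by the
intracellular Ca2+ that each action potential injects). Conductance-based
models capture both, but their nonlinearity obscures *how* the slow currents
shape spike generation. This package implements a complete reduction chain
from such a detailed model to a multi-timescale adaptive threshold (MAT)
neuron, in which the effect of each slow current becomes a single exponential
term in a post-spike threshold kernel, and then uses the reduced model's
linearity to compute coding properties analytically.

## The detailed model

A single compartment obeys

$$C_m \dot V = -I_L - I_{Na} - I_{Kd} - I_M - I_{Ca} - I_{AHP} + I_{ex},$$

with Hodgkin–Huxley gates `m, h, n` (spike generation), `p` (M-current),
`q, r` (Ca2+ current) and `s` (AHP current), and a Ca2+ pool

$$\dot{[\mathrm{Ca}]} = -10^5 \frac{I_{Ca}}{2F} - \frac{[\mathrm{Ca}] - [\mathrm{Ca}]_\infty}{\tau_{Ca}}.$$

`conductance_params()` holds the standard parameter set (units: ms, mV,
uA/cm^2, mS/cm^2, uM; `tau_max` is quoted in seconds as is conventional).
The defaults are `C_m = 1`, `g_L = 0.1`, `g_Na = 50`, `g_Kd = 5`,
`g_M = 0.1`, `g_Ca = 0.001`, `g_AHP = 0.2`, `E_L = -80`, `E_Na = 50`,
`E_K = -90`, `E_Ca = 120`, `tau_max = 1 s`, `beta_s = 0.02 /ms`,
`tau_Ca = 200 ms`, `Ca_inf = 0.05 uM`. Three reference neurons are used
throughout: adaptation-free (`neuron_noadapt()`), M-current
(`neuron_im()`), and AHP (`neuron_ahp()`).

Integration is forward Euler at `dt = 0.025` ms (`simulate_neuron()`), the
classical choice for this model family; the per-ISI discretization bias at
this step is below a few percent and halving `dt` leaves the spike pattern
unchanged (the test suite pins this). Removable singularities in the rate
functions (e.g. the Na+ activation rate at V = −45 mV) are evaluated by
their analytic limits whenever the denominator argument is within 1e−7 of
the singular point. Spike times are upward 0 mV crossings located by linear
interpolation, with a 2 ms debounce so one action potential yields one
spike.

## Probing the instantaneous spike threshold

The spike threshold at time `t0` is measured operationally
(`instantaneous_threshold()`): shift the voltage instantaneously to a
candidate value `c` (gates and Ca2+ untouched), watch 50 ms for a spike, and
bisect `c` over [−80, 0] mV down to a 1e−4 mV interval. The threshold
`theta_V` is the boundary between the spiking and non-spiking sides; the
equivalent minimal pulse charge is `q_min = C_m (theta_V − V_pre)`.

The probing protocol (`evoked_spike_protocol()`) holds the neuron at
`V_c = −70` mV with a tuned current, evokes exactly one spike by lifting the
voltage to −45 mV, and records the full state so any post-spike instant can
seed a probe. From it we extract:

* `spike_triggered_current()`: `eta_ion(t) = I_ion(t) − I_ion(holding)`,
  analyzed from 4 ms after spike onset (the fast Na+/Kd/Ca transients are
  gone by then). Theory predicts `eta_M ≈ a_M e^{−t/\tau_p(\bar v)}` and
  `eta_AHP ≈ a_{AHP}(e^{−t/\tau_{Ca}} − e^{−t/\tilde\tau_s})` with
  `\tilde\tau_s = 1/\beta_s`; `fit_eta()` fits the amplitudes (and
  optionally the time constants).
* `threshold_variation()`: `h_ion(t)`, the post-spike threshold elevation
  attributable to the slow current, obtained by differencing the threshold
  recovery curves of matched neurons with and without the conductance.
  Each neuron's pre-spike holding threshold is subtracted first: the
  tonically active fraction of a slow current raises the *resting*
  threshold, which belongs to `theta_V^inf`, not to the spike-triggered
  kernel. After that subtraction `h_M` follows a single exponential at
  `tau_p(v̄)` essentially exactly, and `h_AHP` shows its characteristic
  interior hump.
* `spike_waveform_stats()`: the reset-rule constants — spike width `w_sp`
  (onset to the end of the fast repolarization, defined as the first
  post-peak sample where the downstroke flattens below 1 mV/ms) and the
  per-spike voltage change `delta_V`. For the reference neurons these come
  out near 3 ms and −24 mV.

## The reduction

Linearizing the subthreshold dynamics and moving every spike-triggered
effect into the threshold yields a non-resetting leaky integrator

$$\dot u = -u/\tau_m + I_{ex}/C_m, \qquad
\theta_u(t) = \theta_u^\infty + \sum_k H_u(t - t_k),$$

with the multi-timescale kernel

$$H_u(t) = \alpha_0 e^{-t/\tau_m} + \alpha_M e^{-t/\tau_p(\bar v)}
  + \alpha_{AHP}\left(e^{-t/\tau_{Ca}} - e^{-t/\tilde\tau_s}\right).$$

`assemble_theory_kernel()` builds this kernel from first principles: the
reset term `−\delta V e^{−(t−w_{sp})/\tau_m}`, the membrane-filtered
spike-triggered currents (the convolution of an exponential with the
membrane filter has the closed form implemented in
`filtered_exponential()`), and the fitted `h_ion` terms, projected onto the
parametric family by least squares on a dense grid. The slow weights
obtained this way scale as the theory predicts:
`alpha_M ∝ g_M(\bar v − E_K)\,\delta p / \tau_{max}` and
`alpha_AHP ∝ g_{AHP}(\bar v − E_K)\,\delta Ca\,
\tau_{Ca}\tilde\tau_s/(\tau_{Ca} − \tilde\tau_s)`
(`alpha_scaling_predictor()`); the proportionality constants are not
derived analytically here, so only scaling relations are asserted.

`simulate_mat()` integrates the reduced model with the exact exponential
update (dt-exact subthreshold dynamics; only threshold-crossing detection
is grid-bound) and one decaying accumulator per kernel exponential, so the
cost per step is independent of the spike history. The potential is never
reset; a 2 ms refractory period (configurable, 0 allowed) prevents
re-crossing on consecutive grid points.

## Fitting by coincidence maximization

`fit_mat()` optimizes the free threshold parameters
(`theta_inf`, `alpha_0`, and one slow weight) by Nelder–Mead maximization of
the coincidence factor

$$\Gamma = \frac{N_c - \langle N_c\rangle}{N_d + N_m}\,
           \frac{2}{1 - 2\nu\Delta},$$

with window `Delta = 4` ms, `nu` the prediction's rate, and
`\langle N_c\rangle = 2\nu N_d \Delta` the chance level
(`coincidence_factor()`; coincidences are counted by greedy in-order
one-to-one matching, which attains the maximum matching for this interval
structure — verified against an exhaustive oracle). Γ is piecewise constant
in the parameters, so the simplex can stall on plateaus; the mitigation is
several restarts jittered around the starting point (30, 35, 3) mV, keeping
the best. Structural parameters stay fixed during fitting: `tau_m = 10` ms,
`C_m = 1`, `tau_Ca = 200` ms, `tilde tau_s = 50` ms, and `tau_p` evaluated
at the mean subthreshold voltage of the training trace (150 ms is the
fallback when no trace is supplied).

The full validation (`run_evaluation_protocol()`) uses six
Ornstein–Uhlenbeck input conditions per neuron — three moderately noisy
(`sigma = mu`) and three highly noisy (`sigma = 2mu`), with means chosen so
the detailed neuron fires at 5, 10 and 20 Hz (`evaluation_inputs()` holds
the printed pairs) — each with 50 s of training and 50 s of held-out test
data. The OU currents use the exact discretization
`I(t{+}dt) = \mu + (I(t)-\mu)e^{-dt/\tau_{syn}} +
\sigma\sqrt{1-e^{-2dt/\tau_{syn}}}\,\xi` with `tau_syn = 2` ms, so tuned
rates carry no `dt` bias.

## Coding properties of the reduced model

Under constant drive the model settles into periodic firing; summing the
kernel over the infinite periodic history gives the inter-spike threshold
variation `eta_T_inf()`, and the period solves
`theta_inf + eta_T_inf(T; T) = I_0 tau_m` (`fi_adaptive()`; bracketed
bisection over a log-spaced grid, taking the smallest root with negative
threshold slope — the attracting orbit — when the non-monotone AHP kernel
admits several). Without slow terms the closed form
`f = 1/(\tau_m \log(1 + \alpha_0/(I_0\tau_m - \theta_u^\infty)))`
(`fi_closed_form()`) coincides with the root exactly. Subthreshold drive
returns `f = 0` rather than an error.

A small potential perturbation `delta_u` near a spike shifts the next spike
by `delta_T = delta_u / (d\eta_T^\infty/dt)(T)` (`noise_sensitivity()`; the
dispersion is reported as `|delta_T|/T`, with `delta_u = 1` mV by default).
This reproduces the differential picture: the M-current suppresses
dispersion across the whole 2–20 Hz range, while the AHP current does so
only near ~3 Hz. The coefficient of variation of the ISIs is not derived
analytically — no closed form is attempted — but is measured from
simulation via `isi_stats()`, which also computes the lag-1 serial ISI
correlation `rho_1` with the plug-in (global-mean) estimator; slow-K+
kernels make `rho_1` negative under noisy drive.

## What the generators emulate, and what they do not

All data are synthetic and regenerable from a seed (`generate_fixtures()`,
`run_pipeline()`): rectangular-step responses of the three reference
neurons, the six-condition OU train/test current sets, and a
known-parameter MAT data set for recovery checks. The generators emulate
the *in vivo*-like colored-noise drive and the steady-holding pulse
protocols; they do not emulate conductance-based (multiplicative) synaptic
input, dendritic filtering, channel noise, or electrode artifacts, so
passing tests demonstrate correctness of the reduction chain on its own
model class, not performance on experimental recordings. Likewise the
detailed model reproduces the slow component of threshold fatigue but not
the fast Na+-inactivation component seen in vitro.

## Numerical choices

* Forward Euler, `dt = 0.025` ms, fixed grid, no adaptive stepping; gates
  clipped only for sub-1e−12 excursions, anything larger surfaces as a
  divergence error naming the step.
* Relaxation to steady state stops when every state derivative falls below
  1e−7 (per ms); a spike during relaxation is an error, which is also how
  holding-current tuning detects overshoot.
* Threshold bisection: initial bracket [−80, 0] mV, termination width
  1e−4 mV, 50 ms observation horizon; bracket failures (both or neither
  end spiking) are errors, as with a Na+-free membrane.
* Degenerate inputs: empty spike trains are legal everywhere except
  fitting; `Gamma` refuses prediction rates with `2 nu Delta >= 1`;
  undefined ISI statistics are `NA`, never fabricated.
* Problem sizes: the shipped tests run the full six-condition, 50 s
  protocol for both neurons (the package's own validation standard), with
  four optimizer restarts per condition; exploratory fits in the unit
  tests use 15–20 s of data, which already recovers planted parameters to
  a few percent.

## Known limitations

* The proportionality constants linking the slow-current parameters to the
  kernel weights are fitted, not derived; only the scaling relations are
  testable.
* Γ-maximization on a piecewise-constant objective has no convergence
  guarantee; restarts make it reliable in practice but the fitted weights
  inherit a few-percent scatter across noise realizations.
* The reduction assumes the slow currents act through their spike-triggered
  component; with large subthreshold voltage excursions (strongly
  depolarized holding, very large `sigma`) the approximation degrades, as
  the subthreshold activation of `I_M` is not modeled.
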