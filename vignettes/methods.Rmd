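---
title: "Voltage-valley plasticity: model, reconstruction choices, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voltage-valley plasticity: model, reconstruction choices, and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter (with units,
defaults and the reasoning behind each), what the synthetic stimulus
generators do and do not emulate, and the numerical choices that a
maintainer would otherwise have to reverse-engineer.

## The model

### Neuron

All simulations use a conductance-based leaky integrate-and-fire neuron:

$$C \frac{dV}{dt} = g_L (V_{rest} - V) + g_e(t)(E_e - V) + g_i(t)(E_i - V) + I_{ADP}(t)$$

with $C = \tau_m g_L$. Synapses are instantaneous conductance jumps that
decay exponentially ($\tau_e$ = 5 ms, $\tau_i$ = 10 ms; $E_e$ = 0 mV,
$E_i$ = -80 mV). Spikes use a "soft" reset: at threshold (-50 mV) the
voltage is set to a spike peak of +20 mV and ramps linearly down to a
reset of -55 mV over the refractory period, after which an exponentially
decaying after-depolarizing (ADP) current of 50 pA ($\tau_{ADP}$ = 20 ms)
is injected. Cortical pyramidal cells do not reset to rest after an
action potential; the high reset plus ADP reproduces their post-spike
depolarized plateau, and that plateau is what makes post-before-pre spike
pairings depress (see below).

Integration is clock-driven at $\Delta t$ = 0.1 ms: conductances and the
ADP current use exact exponential updates, the membrane equation forward
Euler. During the spike ramp the membrane equation is suspended (the
shape is imposed, not emergent). Delays are rounded to the grid; spike
delivery is exact at bin resolution (arrival bin = emission bin +
round(delay/$\Delta t$)).

Defaults $\tau_m$ = 20 ms, $g_L$ = 10 nS, $V_{rest}$ = -70 mV are
*reconstructions*, not literature-fixed values: the combination must
satisfy several joint constraints. $V_{rest}$ = -70 mV keeps the
plasticity drive at rest below 5% of the near-threshold drive given the
fixed valley parameters below (at -60 mV it is ~13%). $g_L$ = 10 nS keeps
a 2 nS synapse's EPSP near 1.5 mV — small against the 3-4 mV valley
width, which is necessary for a presynaptic spike arriving on the
post-spike plateau to stay inside the depression zone rather than
depolarize out of it. The refractory ramp is 3 ms: with 2 ms the
action potential's positive contribution to the eligibility no longer
reliably outweighs the plateau's negative contribution and pre-post
pairing fails to potentiate.

### The valley objective and its gradient

The rule performs stochastic gradient ascent on an objective $g(V)$ of
the subthreshold voltage that penalizes intermediate depolarization and
rewards time spent near rest or near threshold — equivalently, it
maximizes the skewness of the subthreshold voltage distribution, the
spiking analogue of projection-pursuit/ICA-style non-Gaussianity
maximization. We use

$$g'(V) = \mathrm{logistic}\!\left(\frac{V - V_1}{\sigma_1}\right) -
  c\,\mathrm{logistic}\!\left(\frac{V - V_0}{\sigma_0}\right)$$

with $V_0$ = -55 mV, $\sigma_0$ = 4 mV (depression component) and $V_1$ =
-52 mV, $\sigma_1$ = 2 mV (potentiation component). The four voltage
parameters are fixed; only the relative depression amplitude $c$
(`ltd_weight`) is free. $g'$ is then *exactly* a difference of two
non-negative monotone sigmoids with the depression component
half-activating at the lower voltage — the functional form of a
dual-coincidence-detector mechanism (a high-threshold NMDA-like
potentiation detector and a low-threshold T-type/mGluR-like depression
detector), exposed by `decompose_gprime()`. The valley exists for
$c \gtrsim 0.29$ and near-threshold reward dominates rest reward for
$c \lesssim 0.52$; the default $c$ = 0.32 was calibrated once against the
spike-pairing protocol (below) and then frozen for every experiment in
the package.

### Eligibility, shrinkage, expression

Each presynaptic arrival (emission + delay) launches a peak-normalized
EPSP kernel $\varepsilon(t)$ — a difference of exponentials with rise
$\min(\tau_e, \tau_{eff})$ and decay $\max(\tau_e, \tau_{eff})$, where
$\tau_{eff} = C/(g_L + \bar g)$ shrinks with the running-average synaptic
conductance $\bar g$ (high-conductance state). The eligibility of synapse
$j$ accumulates the product of kernel and voltage gradient through a slow
exponential ($\tau_p$ = 1 s):

$$P_j(T) = \gamma\,(E_j - V_{rest}) \int_0^T e^{-(T-s)/\tau_p}\,
  g'(V(s)) \sum_f \varepsilon(s - t_f)\, ds$$

Direct evaluation costs O(synapses x steps). The package instead computes,
once per neuron and pattern, a backward-in-time lookup table $\kappa(t)$
by two first-order recursions over the voltage trace (one per kernel
exponential, composed with the $\tau_p$ accumulator, started from zero at
the pattern end), after which $P_j = \gamma (E_j - V_{rest}) \sum_f
\kappa(t_f)$ — O(steps + spikes) total. The two paths are algebraically
identical on the grid; the test suite holds them to 1e-6 relative
agreement on randomized instances, and the direct path remains in the
package as the reference semantics.

Updates are expressed once per input pattern ($T$ = 1 s, the natural
cadence of the backward pass): the eligibility, carried across patterns
with decay $e^{-T/\tau_p}$, is passed through a soft-threshold shrinkage
with dead zone $[\theta_d, \theta_p] = [-10, 50]$,

$$\Omega(P) = \begin{cases} P - \theta_p & P > \theta_p \\ 0 &
  \theta_d \le P \le \theta_p \\ P - \theta_d & P < \theta_d \end{cases}$$

and applied as $w \leftarrow \mathrm{clip}(w + \eta\,\Gamma\,\Omega(P),
w_{min}, w_{max})$ with $\Gamma$ the homeostatic gate. The piecewise-linear
$\Omega$ is a reconstruction: the simplest continuous monotone map with
the prescribed dead zone (1-Lipschitz, documented as such). Kernel tails
crossing pattern boundaries are truncated, which is exact in the limit
where the kernel support (~60 ms) is short against $T$; the fast path
warns if that assumption is violated.

The thresholds act on the *scale* of $P$, so the kernel-amplitude
convention matters. With the peak-normalized kernel and $(E_j - V_{rest})$
in mV, the remaining dimensionless gain $\gamma$ (`gain`, default 1.25)
and the learning rate $\eta$ (default 1e-4 nS per unit of shrunk
eligibility) were calibrated *once*, jointly with $c$, against the
in vitro battery:

* a single pre-post pairing at +10 ms must stay inside the dead zone
  (this is what abolishes potentiation at 0.1 Hz repetition — the
  shrinkage mechanism is critical for that result), while
* 1 Hz repetition, whose steady-state eligibility is
  $1/(1 - e^{-1}) \approx 1.58$ times the single-pair increment, must
  cross $\theta_p$, and
* post-pre-post triplets must accumulate net positive eligibility, which
  bounds the depression/potentiation drive ratio and hence $c$ from above.

These three constraints pin $\gamma \cdot$(single-pair increment) into a
narrow band just below $\theta_p$; the defaults sit at ~43 for the
+10 ms pair. After this calibration no rule parameter was changed for any
other experiment; the same parameter set produces the pairing curve, the
tetanus frequency dependence, the triplet asymmetry, the
pairing-frequency crossover, and all learning results.

### Homeostatic rate constraint

Gradient ascent on the valley objective alone is unstable (responses
drift above or below the plasticity thresholds). Stability comes from a
projection-style constraint on the mean firing rate: a per-neuron PI
controller on the rate estimate $\hat r$ (exponential average, $T_{rate}$
= 10 s) multiplies all *plastic excitatory* input weights by
$1 - k\,(e + \gamma_I I)\,\Delta t$ each pattern and gates
activity-dependent plasticity by
$\Gamma = \exp(-e^2/2\sigma_e^2 - I^2/2\sigma_I^2)$, so learning proceeds
only while the constraint is satisfied. (Scaling is restricted to the
plastic excitatory inputs; external inputs stay fixed throughout.)

The controller gains are set by loop-shaping, not taste: the plant from
log-weight to rate is roughly a gain $G = dr/d\ln w$ (tens to hundreds of
Hz near threshold) in series with the 10 s estimator lag, and the scaler
integrates, so stability requires $k G \lesssim 1/(2 T_{rate})$ and the
PI zero $\gamma_I$ below the crossover. Defaults $k$ = 2e-4 /Hz/s and
$\gamma_I$ = 0.01 are stable for set-points of 1.5 and 10 Hz; the ring
and digit task drivers use $k$ = 1e-2, where the rule's sustained
potentiation pressure would otherwise hold the rate a few hertz above
the set-point in a gate-against-controller tug-of-war. The gate widths are
$\sigma_e = 0.2\,r_0 + 0.3$ Hz — the additive floor keeps the estimator's
intrinsic Poisson noise ($\mathrm{sd} \approx \sqrt{r_0/2T_{rate}}$) from
holding the gate shut at low set-points — and $\sigma_I = 2 \sigma_e
T_{rate}$. The integral clamps at $2\sigma_I$ (anti-windup): a long
silent or saturated transient can then neither wind the controller up nor
keep the gate closed after the rate recovers. Gating acts on expression
only; eligibility continues to accumulate (a flag-level design choice —
the alternative of freezing accumulation too is a one-line change in the
training loop and made no qualitative difference in exploratory runs).

## Stimulus generators

**Ring ensemble.** 1000 excitatory Poisson sources on a virtual circle,
rate profile a wrapped Gaussian (peak 30 Hz, width 5% of the ring — both
reconstructed defaults; only the ring geometry and the 100 ms hold are
fixed), re-centred uniformly at random every 100 ms, plus 250
inhibitory sources at a constant 10 Hz with fixed 1 nS synapses. Sampling
is exact per constant-rate segment (Poisson counts, uniform times) rather
than per-step Bernoulli thinning — identical in distribution up to grid
rounding and far cheaper at 300+ simulated seconds.

**Synthetic cochleogram-like ensemble.** A licensed speech corpus and a
cochlear filterbank front-end are out of scope; the generator emulates
the front-end's *output format*: 11 classes x 93 frequency channels,
1 s epochs sampled at 500 Hz, normalized so every utterance has equal
summed activity, encoded as inhomogeneous Poisson trains with a 5 Hz
grand mean (intensity-to-rate mapping linear). Each class is a smooth
template of 3-6 oriented Gaussian ridges in (channel, time); each
"speaker" applies a systematic time warp and channel shift and every
utterance multiplicative amplitude noise; train and test splits use
disjoint speakers (8 and 6 by default). Variability defaults (+-35%
warp, +-8 channels, 60% amplitude noise) were calibrated once so that a
linear classifier on *raw channel spike counts* sits well between chance
(90.9%) and zero error — at milder settings the raw counts are nearly
linearly separable and the learned-representation comparisons have no
room to show anything. What passing these tests shows is that the rule
extracts reliable spatiotemporal coincidence structure under realistic
within-class variability; what they do not show is performance on real
speech — real cochleograms have correlated channel noise, amplitude
compression and far richer temporal fine structure.

## Architectures and calibration

The feedforward architecture gives each output plastic excitatory
synapses from a random half of the channels (initial weights U[0, 10] nS)
and static inhibition from every channel, delays U[0.1, 5] ms. The
inhibitory initial range defaults to U[0, 4] nS. A 10x larger range is
sometimes quoted for architectures of this type, but summed over all 93
channels at these membrane parameters it yields a ~93 nS mean inhibitory
conductance that no admissible excitatory weight can overcome, leaving
the 1.5 Hz set-point unreachable; the smaller default keeps the
architecture controllable and is exposed for override.

The recurrent sheet (4500 neurons, 4:1 E:I, periodic unit square, uniform
5% connectivity, no self-connections, delays U[0.1, 5] ms) draws initial
weights from Gaussians with sd = mean/3 truncated at zero, receives a
per-neuron 300 Hz Poisson background through a fixed 2 nS synapse, and
takes tonotopic external input (each channel contacts 5% of neurons with
probability following a Gaussian of torus distance, sigma 0.2). Initial
conductance means are not hard-coded: `calibrate_spontaneous_state()`
bisects a common scale factor on the recurrent means (inhibitory:
excitatory ratio fixed at 4, one scalar searched) until the spontaneous
population rate, driven by the background alone, reaches the 1.5 Hz
set-point; the found state is then characterized by its rate, CV-ISI and
mean pairwise correlation. Rate decreases monotonically with the coupling
scale in this inhibition-dominated regime, which is what makes bisection
valid; the builder exposes the monotonicity probe used to check it.

## Problem sizes

Simulations are sized for a single CPU. The test suite runs the ring task
at 250-600 patterns, the digit comparisons at up to ~70 output neurons
with 10 passes over 88 training utterances, recurrent checks at 800-1500
neurons, and the full 4500-neuron calibration only in the acceptance
path; the acceptance script uses the full configurations (1000+250 ring
inputs with 5 seeds; 20 feedforward neurons, 10 passes; 4500-neuron
recurrent calibration with a 10 s characterization probe). Ordering
contracts (classifier error, skewness, F-statistic across rules) are
asserted on seed-averaged values at these sizes; they reproduce rank
structure, not the absolute percentages reported for real speech, which
are out of scope along with the licensed corpus itself.

## Degenerate inputs and numerical edges

* `epsp_kernel` switches to the alpha-function limit when the two time
  constants coincide (relative difference below 1e-9) instead of dividing
  by zero; the switch is continuous to ~1e-4.
* Poisson sampling draws per-segment counts; coincident draws within one
  source are perturbed by 0.1 us to keep spike times strictly increasing.
* `f_statistic` refuses zero within-class variance, `cv_isi` requires 3
  spikes (population summaries exclude neurons with fewer than 5),
  `tuning_index` refuses all-zero rates, and the skewness estimator
  refuses constant traces — degenerate statistics fail loudly rather
  than return NaN.
* The simulator stops with a diagnostic on non-finite voltage
  (integration blow-up) rather than propagating NaNs.
* Weight updates clip to hard bounds after every expression and after
  every homeostatic rescale; scaling multipliers are floored at 0.1 per
  pattern.
* All randomness flows through R's RNG: a single `set.seed()` makes
  stimulus generation, network construction, background drive and
  training bit-reproducible; the experiment runner derives per-stage
  seeds from the master seed.

## Known limitations

* The exact analytic forms of the objective and the shrinkage are
  reconstructions constrained by their published shape properties;
  absolute weight-change magnitudes in the protocol reproductions
  (e.g. the depth of pairing LTD, which saturates the weight floor at
  the default learning rate) are therefore not calibrated to data —
  only signs, orderings and ratio bounds are meaningful.
* Clock-driven delivery quantizes delays at 0.1 ms; no event-driven path.
* The voltage-based eligibility treats the neuron's own EPSP as part of
  the voltage trace (no separation of "caused" vs "observed"
  depolarization); at realistic EPSP sizes this is the desired behaviour,
  but with very large unitary synapses (EPSPs comparable to the valley
  width) the post-pre depression window closes.
* The Clopath-style voltage rule is deliberately not implemented
  (unstable in large recurrent networks in the original comparison); the
  baseline set is rcSTDP, nearest-neighbour STDP and triplet STDP.
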