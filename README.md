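# convallis

Unsupervised feature learning in spiking cortical networks through a
voltage-dependent synaptic plasticity rule, plus the simulation apparatus
needed to study it: a conductance-based integrate-and-fire network engine,
homeostatic firing-rate control, STDP-family baseline rules, synthetic
spatiotemporal stimulus generators, in vitro plasticity protocol
reproductions, and a linear spike-count readout.

## The problem and the rule

How can a cortical neuron, with no labels or rewards, reshape its synapses
so that downstream neurons can read out what matters? One normative answer
is projection pursuit: seek inputs whose summed effect makes the neuron's
*subthreshold membrane potential distribution* maximally skewed —
real-world signal structure is non-Gaussian, uninformative mixtures are
Gaussian. The rule implemented here performs stochastic gradient ascent on
a valley-shaped objective \(g(V)\) of the subthreshold voltage: time near
rest or near spike threshold is rewarded, intermediate depolarization is
penalized. Its derivative is a difference of two non-negative sigmoids

\[ g'(V) = \mathrm{logistic}\big((V - V_1)/\sigma_1\big) -
          c\,\mathrm{logistic}\big((V - V_0)/\sigma_0\big), \]

a high-threshold potentiation detector minus a low-threshold depression
detector (\(V_0 = -55\) mV, \(V_1 = -52\) mV, \(\sigma_0 = 4\) mV,
\(\sigma_1 = 2\) mV). Per synapse \(j\), presynaptic arrivals \(t_f\) are
filtered by the EPSP kernel \(\varepsilon\) and combined with \(g'(V(t))\)
into an eligibility through a slow exponential (\(\tau_p\) = 1 s):

\[ P_j(T) = \gamma\,(E_j - V_{rest}) \int_0^T e^{-(T-s)/\tau_p}
   g'(V(s)) \sum_f \varepsilon(s - t_f)\, ds, \]

evaluated cheaply by a backward-in-time pass that turns an
O(synapses x steps) integral into O(steps + spikes). Weight changes are
expressed once per 1 s pattern through a soft-threshold shrinkage with
dead zone \([-10, 50]\) (isolated coincidences do nothing) under a
per-neuron homeostatic constraint: a PI controller on the firing rate
scales excitatory weights multiplicatively and gates plasticity off while
the rate is away from its set-point.

The same fixed parameter set reproduces classical in vitro phenomenology —
the biphasic spike-pairing (STDP) curve, frequency-dependent tetanus
(LTD at 3-10 Hz, LTP at 50-100 Hz), post-pre-post triplet potentiation
with pre-post-pre ineffective, and the conversion of post-pre depression
to potentiation at fast repetition rates — and trains feedforward and
recurrent spiking networks to form rate representations of multi-class
spatiotemporal patterns that a linear spike-count classifier can decode
better than the raw input or STDP-trained controls.

## Worked example: the spike-pairing protocol

```r
library(convallis)
rule <- convallis_rule()        # calibrated defaults
cc <- run_pairing_curve(dts = c(-10, 10, 30), rule = rule)
cc
#>   dt dw_percent
#>  -10 -17.558022
#>   10   6.167579
#>   30   0.000000
run_triplet("post_pre_post", rule = rule)
#> [1] 1.884574
run_triplet("pre_post_pre", rule = rule)
#> [1] 0
```

60 pairings at 1 Hz on a single 2 nS synapse: pre 10 ms before post
potentiates (+6.2%), post 10 ms before pre depresses (-17.6%), and at
+30 ms — beyond the EPSP kernel — the accumulated eligibility never
leaves the shrinkage dead zone, so the weight change is exactly zero.
Post-pre-post triplets potentiate (+1.9%) while pre-post-pre triplets do
not, a nonlinearity additive STDP cannot produce.

Learning example (a few minutes):

```r
res <- run_gaussian_task(rule = convallis_rule(), n_patterns = 350,
                         target_rate = 10, seed = 21)
mean(tail(res$diagnostics$rate, 100))   # ~10 Hz: constraint satisfied
res$tuning                              # ~0.95: ring-position selectivity
res$skewness                            # > 1: skewed subthreshold voltage
```

A command-line front end for configured experiments lives at
`inst/cli/convallis.R` (`run <config.yaml>`, `protocol`, `calibrate`).

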