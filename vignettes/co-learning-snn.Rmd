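---
title: "Co-learning weights, delays and adaptation in spiking networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-learning weights, delays and adaptation in spiking networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snncolearn)
```

## The model

`snncolearn` simulates and trains feed-forward spiking neural networks in
which three kinds of parameters are optimized jointly: synaptic weights,
per-synapse propagation delays, and per-neuron adaptation constants. The
hidden unit is the constrained adaptive leaky integrate-and-fire (cAdLIF)
neuron. With membrane potential $u[t]$, adaptation current $w[t]$ and spike
indicator $s[t]$, one 1 ms timestep is

$$
\begin{aligned}
u[t] &= \alpha\,u[t-1] + (1-\alpha)\,(I[t] - w[t-1]) - \theta\,s[t-1] \\
w[t] &= \beta\,w[t-1] + (1-\beta)\,a\,u[t-1] + b\,s[t-1] \\
s[t] &= \big[\, u[t] \ge \theta \,\big]
\end{aligned}
$$

with threshold $\theta = 1$ fixed, a *soft* reset (a spike subtracts
$\theta$; the potential is never clamped), and the update order exactly as
written: the new $u$ sees the old $w$ and vice versa. The four per-neuron
constants are trainable and clipped after every optimizer step to
$\alpha \in [0.36, 0.96]$, $\beta \in [0.96, 0.99]$, $a \in [0,1]$,
$b \in [0,2]$. The variant `"AdLIF"` relaxes $a$ to $[-1, 1]$ (the
unconstrained baseline the regime analysis argues against); `"LIF"` pins
$a = b = 0$, leaving only $\alpha$ trainable. Initialization is uniform
within the bounds — deliberate neuronal heterogeneity.

The architecture is fixed at two fully connected hidden layers plus a
*readout* layer of memoryless, infinite-threshold units: the readout
potential is simply the (possibly delayed) weighted input at each step.
Class scores are per-timestep softmaxes of the readout potentials summed
over time, so each sample's scores total $T$; the loss is the
cross-entropy of the normalized summed scores. We differentiate this loss
exactly; any constant factor (such as a $1/T$ on the update) is absorbed by
the learning rate.

Every feed-forward synapse may additionally carry a delay
$d_{ij} \in [0, d_{\max}]$ ($d_{\max}$ = 25 steps by default): the
presynaptic signal enters the weighted sum as $s_j[t - \mathrm{round}(d_{ij})]$.
Delays are stored as continuous shadow variables; the forward pass uses the
integer effective shift (nearest, ties toward zero). Learnable delays start
at zero, so a fresh network is exactly the delay-free network, and inputs
are right-padded by $d_{\max}$ so shifted content is not truncated.

## Training

Training is backpropagation-through-time with a surrogate spike derivative:
the Heaviside derivative is replaced in the backward pass by a boxcar,
$0.5$ when $|u - \theta| \le 0.5$ and $0$ otherwise. Weights, biases,
neuron parameters and delays are updated with Adam; the delay learning rate
is $10\times$ the weight rate by default, and both follow a plateau
scheduler (factor 0.7, patience 5 epochs, monitoring validation accuracy —
the monitored quantity is our choice; nothing in the setup pins it).
Neuron parameters and delays are clipped after every step. Dropout, when
enabled, is an inverted elementwise mask on each hidden layer's *emitted*
spike train; the layer's own recurrence (reset, adaptation) sees the
undropped spikes.

Because the delayed signal is a step function of its delay, $\partial
p/\partial d$ has no useful pointwise value on the 1-step grid. The delay
rule replaces it with a *temporal-context* factor per synapse and timestep,

$$ g[t] = \sum_{k=1}^{c} \big( p[t-k] - p[t+k] \big), \qquad c = 3, $$

summed unnormalized over the window (any constant is absorbed by the delay
learning rate; window edges are zero-padded). The past-minus-future
difference is positively aligned with the true sensitivity of a
later-shifted signal, so the chained update is a plain descent step on the
continuous delay. We verify the direction rather than assume it: on
single-synapse micro-instances with a leaky readout and a smooth target,
the sign of the chained pseudo-gradient agrees with the brute-force
integer-delay loss difference in well over 90% of decidable cases (the
acceptance script recomputes this rate). The smoothness of that oracle
matters: against a white-noise target the landscape itself is ragged at
lag 1 while the context integrates over $\pm 3$ steps, and sign agreement
drops to chance-like levels for reasons that have nothing to do with the
rule.

Gradient correctness of the BPTT core is checked differently: spikes are
temporarily replaced by a sigmoid relaxation (`spike_fn = "sigmoid"`) whose
exact derivative is used in the backward pass, making the whole network
smooth; analytic gradients for weights, biases and all four neuron
parameters then match central finite differences to relative error below
$10^{-3}$ (in practice $\sim 10^{-6}$) on a 3-neuron, $T = 5$ net. Entries
where the finite difference is below $10^{-5}$ are skipped — there the
quotient measures floating-point cancellation, not the gradient.

## Why the constraint: the adaptation regime map

`regime_map()` drives a single neuron with a fixed probe train (12 spikes,
one every 8 steps by default) over a grid of $(a, b)$ values and counts
output spikes, continuing 100 silent steps past the last input to catch
self-sustained firing. Cells that out-fire the probe are flagged chaotic.
The probe's synaptic weight is derived from a stated rule — an isolated
spike is sub-threshold, two successive probe spikes summate above threshold
(midpoint of $[1/((1-\alpha)(1+\alpha^{\mathrm{isi}})),\ 1/(1-\alpha)]$) —
so all regime statements are relative to a reproducible fixture.

One subtlety deserves a full account. Two conventions exist for coupling
the potential into the adaptation current. The *scaled* form above
($(1-\beta)\,a\,u$) makes the sub-threshold two-variable map a contraction
for every $|a| < 1$: its spectral radius crosses 1 exactly at $|a| = 1$,
and at that margin the spike jump $(-\theta, +b)$ strictly damps the
marginal mode. Within the declared bounds that neuron *cannot* fire more
than it is driven, for any probe — we verified this analytically and by
grid simulation. The *unscaled* form used by the baseline adaptive-LIF
implementation lineage, $w[t] = \beta w[t-1] + a\,u[t-1] + b\,s[t-1]$, is
unstable whenever $a < -(1-\beta)$ — essentially the entire negative-$a$
half-plane — and there the neuron runs away and keeps firing after input
ceases, which is precisely the phenomenon that motivates constraining
$a \ge 0$. The trainable neuron in this package implements the scaled
recurrence; `regime_map()` therefore defaults to `coupling = "unscaled"`,
the form whose instability the analysis exists to display (the two coincide
at $a = b = 0$, so the LIF anchor cell is convention-independent), and
offers `coupling = "scaled"` for reference, where the whole grid is
input-bounded.

```{r regime, eval = FALSE}
rm_ <- regime_map()
plot_regime_map(rm_)
```

## The synthetic lag task

`generate_lag_task()` emulates the one property of event-stream audio this
package's methods specifically target: class-discriminative inter-channel
timing. Channel 1 (reference) fires at random times; channel 2 (partner)
repeats each reference spike offset by the sample's class lag; all channels
carry independent Bernoulli background noise (the per-bin approximation of
Poisson noise). A class lag of `NA` produces an uncorrelated control class
with identical marginal rates, so only joint timing separates it from a
lagged class. Defaults — 4 channels, 40 steps, 6–8 reference spikes,
background rate 0.02 — are the package's reference conditions. What this
generator does *not* emulate: realistic channel counts (hundreds),
correlated bursts across many channels, rate envelopes, speaker
variability. Passing tests on this task demonstrate that the machinery
learns temporal structure end-to-end, not that it reaches any particular
accuracy on real speech.

One numerical consequence of the small synthetic inputs: with 4 sparse
channels, plain Xavier-scale weights never push the membrane near
threshold, and since the boxcar surrogate is zero away from threshold, the
network is born gradient-dead. Wide, densely active inputs (140-channel
binned speech) reach threshold under plain Xavier; the narrow tasks need a
larger initial weight scale to sit at the same operating point. `snn_config()`
exposes this as `init_gain` (multiplier on the Xavier limits; default 1 =
plain Xavier, the synthetic experiments use 5, chosen so the initial
membrane fluctuations straddle the threshold).

## Delay recovery: design and measurement

The recovery experiment asks whether the temporal-context rule rediscovers
a known lag. Design choices, and why:

* **Task**: lag-$L$ class versus the uncorrelated control class. With a
  lag-0 second class instead, gradient descent reliably finds shortcut
  solutions that reuse the zero-delay alignment (e.g. "partner spike with
  no coincident reference" inhibition motifs) and the delays never move;
  against the control class, *any* discriminative solution must align the
  two channels at $L$.
* **Delay locus**: delays are restricted to the input projection
  (`delay_layers = 1`). With delays everywhere, the compensation often
  migrates into the second layer or the readout, where no single synapse
  pair corresponds to the generating lag; restricting the locus makes the
  experiment controlled.
* **Measurement**: the primary estimate is behavioral — the peak of the
  `lag_tuning_curve()`, i.e. the probe lag the trained network most
  confidently classifies as "lagged". Trained networks implement the
  alignment through interchangeable motifs (excitatory coincidence,
  cancellation with mixed-sign weights, anti-coincidence detectors, or
  combinations spread across neurons); the tuning peak is invariant to the
  motif, while any single structural statistic is not. The
  relevance-weighted median of per-neuron shift differences is reported as
  a secondary diagnostic.
* **Training length**: 60 epochs with scheduler patience 10 for this
  experiment — with patience 5 the rate decays during the initial chance
  plateau and occasionally strands a run. The speech-scale defaults keep
  patience 5.

A run succeeds when the recovered lag is within $\pm 1$ step of truth.
Across development seeds 1–8 every run recovered the lag; the acceptance
script reruns 5 fresh seeds derived from its `--seed`, together with the
matched no-delay control (which stays far from the delay model's accuracy,
the qualitative delay benefit).

## Numerical and design notes

* Effective shifts round ties toward zero (2.5 → 2), so tiny delay updates
  around zero do not flip the forward pass.
* Shift arithmetic groups synapses by integer shift; each group is one
  masked matrix product, so the cost grows with the number of distinct
  shifts (≤ $d_{\max}+1$), not with synapse count.
* Class scores always sum to $T$; the loss normalizes per sample, and
  non-finite scores raise an error rather than being clamped.
* Biases have no printed bounds and are not clipped; optimizer moments are
  kept (not reset) when a parameter is clipped.
* The event container is a JSON text file with the same fields as the
  common neuromorphic HDF5 layouts (`times`, `units`, `label`, `n_units`);
  binning merges units in contiguous groups and ORs events within a
  (channel-group × 10 ms) cell — spike presence, matching the binary
  spike-train domain. Events at exactly the duration boundary land in the
  last bin.
* Checkpoints are versioned R lists written with `saveRDS` (config,
  weights, biases, neuron parameters, delays, training config, history,
  RNG state).
* Problem sizes used by the test and acceptance runs — hidden layers of
  16–24 neurons, 40-step sequences, 200-sample tasks, 30–60 epochs — are
  the package's reference experiment scale: large enough that every
  mechanism (adaptation, delays, scheduling, dropout) is exercised, small
  enough to iterate on quickly.

## Known limitations

* Exactly two hidden layers; no recurrent or convolutional variants.
* Integer-only effective delays (no fractional-delay interpolation) and a
  fixed, pre-chosen delay cap.
* The unconstrained-AdLIF lower bound $a \ge -1$ is a package choice for
  the ablation variant; only the cAdLIF bounds are externally given.
* Training is plain R matrix code: comfortable at the reference scale,
  not tuned for 140×512×512 speech-scale runs.
* The Mel-filterbank front end for raw audio is out of scope; real-valued
  feature frames are accepted directly as input currents.
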