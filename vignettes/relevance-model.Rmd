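---
title: "Relevance learning through plastic feedforward inhibition: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relevance learning through plastic feedforward inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inhibrel)
```

## The model

`inhibrel` simulates a two-layer feedforward Poisson rate network in which
the *overall level* of excitatory cortical activity encodes how relevant the
current sensory input is — the expected, temporally discounted magnitude of
upcoming reward or punishment, without regard to valence.

A sensory layer of `n = 1000` Poisson units drives `m = 800` excitatory
cortical units and one divisive feedforward inhibitory unit (standing in for
the synchronized population of fast-spiking PV+ interneurons).  Per step of
`dt = 20` ms:

* `x ~ Poisson(dt * phi_x)` — sensory spike counts;
* `I = W_xI . x + b_I` — inhibitory drive;
* `phi_E = (W_xE . x + b_E) / (W_IE * I + I_floor)` — element-wise divisive
  normalization, floored at `I_floor = 0.1`;
* `E ~ Poisson(dt * phi_E)` — excitatory spike counts.

The relevance code is carried by the L2 norm of the excitatory spike-count
vector.  Salience is its deviation from a homeostatic set-point,
`S(t) = ||E(t)|| - H`, and learning drives `S` toward `A * U(t)`, where
`U(t)` is the discounted sum of future unsigned reinforcement `u(t)`.  The
plasticity rule is an unsigned temporal-difference scheme on the
sensory-to-inhibitory weights: with prediction error
`beta(t) = A u(t) + gamma S(t) - S(t-1)`, each synapse moves by
`-alpha * beta(t) * x_j(t-1)` and is clipped at zero (Dale's law).  Positive
surprise releases inhibition; an unsurprising stimulus accrues inhibition
until its evoked population norm sits back at the set-point — the circuit
"learns to ignore" it.  The same gradient direction can instead be applied
to the sensory-to-excitatory or inhibitory-to-excitatory weights (the `xE`
and `IE` variants), which respond differently to inhibitory disruption.

Two output heads model downstream use of the code.  A winner-take-all
"amygdala" head thresholds its input at `theta = H/4` and learns by
US-gated competitive updates; it links salience to fear behaviour.  A
linear-normalized "category" head (rates summing to `kappa = 20` Hz) is
trained by gradient descent on a cross-entropy loss and demonstrates that
relevance (vector length) and identity (vector direction) can be
multiplexed in one population.

## Units and the norm convention

`H`, `A`, and `theta` are expressed in units of the per-step spike-count
norm, although such constants are conventionally quoted in Hz.  They are
mutually consistent only under the count reading: with `m` units at rate `r`
and step `dt`, `||E|| ~ sqrt(m r dt)`, so the baseline target 2.6 Hz gives
`sqrt(800 * 2.6 * 0.02) = 6.45 ~ H = 6.5`, and 3.9 Hz gives
`7.90 = H + A` with `A = 1.4`.  All internal thresholds therefore scale
with network size as `sqrt(m)`; the reduced-size test configuration rescales
`H` and `A` accordingly.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `dt` | 0.02 | s | pyramidal membrane time constant; bins are effectively binary |
| `H` | 6.5 | count-norm | baseline set-point, equals 2.6 Hz population rate |
| `A` | 1.4 | count-norm | relevant-stimulus deviation, reaching 3.9 Hz at `U = 1` |
| `gamma` | 0.9 | — | TD discount; see below |
| `alpha` | 0.02 | — | relevance learning rate; calibrated, see below |
| `theta` | `H/4` | count-norm | winner threshold from the original grid search |
| `phi_on` | 20 | Hz | firing rate of the 10% of sensory units coding a stimulus |
| `baseline_mode`, `baseline_var` | 0.6, 3 | Hz, Hz^2 | gamma law of spontaneous rates |
| `alpha_y` | 0.5 | — | competitive-head rate |
| `alpha_cat` | 30 | — | categorization-head rate (see below) |
| `us_gain` | 0.5 | — | additive US drive to the winning output unit |

**The discount `gamma`.**  No value is reported for the main simulations;
0.98 appears only in the eligibility-trace variant (`lambda = 0.8`), where a
slow trace requires a long value horizon.  For plain TD(0) we use
`gamma = 0.9` (a 200 ms horizon, the length of one stimulus), for two
reasons.  First, the homeostatic restoring force at baseline scales with
`(1 - gamma)|S|`; at 0.98 it is too weak for the weights to settle onto the
baseline statistics within the protocol's 60 s adaptation period, leaving
the baseline rate below its 2.6 Hz operating point, while at 0.9 the
reference operating point is reached within adaptation (the acceptance
criteria on the baseline rate and set-point norm verify this).  Second,
the fixed-point bias induced by sampling noise in the norm (see
*Numerical behaviour*) is amplified by `1/(1 - gamma)` and shrinks
accordingly.  `gamma^5 = 0.59` still bridges the 100 ms CS–US offset
comfortably.

**The learning rate `alpha`.**  Also unreported.  The calibration rule we
apply: the largest rate for which (a) the 60 s adaptation reaches the
set-point and (b) learning-to-ignore converges within 20 presentations,
without degrading the baseline fixed point.  Because each weight performs a
clipped random walk (`alpha * beta * x` with `beta` noise of order 0.5),
large `alpha` inflates a rectification bias at the zero bound that drags
the equilibrium norm below `H`, and the bias grows with `alpha`.
`alpha = 0.02` is the largest value that keeps the bias within the
acceptance tolerance on the set-point (criterion 3 verifies the norm).

**The categorization rate `alpha_cat`.**  The ten stimulus-evoked
excitatory patterns overlap heavily (cosine ~0.9), so the cross-entropy
gradient is nearly zero-sum across the fixed presentation cycle and small
rates stall in a "recency treadmill" where the most recently trained
class dominates.  A decade sweep located a stable window around 30 in
which the network escapes the treadmill and reaches its late-epoch
accuracy plateau (verified by acceptance criterion 1); much larger rates
collapse.  The competitive head has no such constraint and uses
`alpha_y = 0.5`.

**US duration in the 200 ms protocols.**  Not reported; we use `u = 1`
from US onset (100 ms after CS+ onset) to CS+ offset.  In the
learned-irrelevance and the 6 s-CS protocols the US duration is as
described for those designs (200 ms, and the whole CS respectively).

## The synthetic stimulus world

Each stimulus claims a disjoint 10% of the sensory layer; coding units fire
at 20 Hz while the stimulus is on.  Non-coding units always fire at a
baseline drawn once per run from a gamma distribution with mode 0.6 Hz and
variance 3 Hz² (shape 1.41, scale 1.46 — solved from the mode/variance
pair), emulating spontaneous rates of regular-firing cortical neurons.  The
categorization protocol flattens baselines to 2 Hz.  For the
latent-inhibition and fear-expression protocols the excitatory weights are
initialized as a smoothed diagonal band (Gaussian kernel, sigma = 5 sensory
units, scaled to the default mean weight) and masks are allocated as
contiguous index blocks, so stimulus identity is present in the initial
topography.

What this world does *not* emulate: correlated spontaneous activity,
stimulus-intensity variation, temporal structure within a stimulus, overlap
between stimulus representations, and receptive-field plasticity outside
the trained weight matrices.  A green simulation test therefore establishes
that the *learning rules* behave as claimed under idealized input
statistics, not that the circuit explains any particular biological
recording.

## Numerical behaviour and known limitations

**Credit-assignment pairing.**  `beta(t)` is paired with the input of step
`t-1` (the TD(0) trace), the conventional alignment; a config flag
(`literal_pairing`) restores the same-step pairing with `x(t)`.  The
choice matters: the norm plays double duty as prediction and sampled
target, so each pairing carries a sampling covariance into the fixed point.
Empirically the literal pairing settles far below the set-point while
the conventional pairing stays close to it; we default to the
conventional form.

**Divisive scale-invariance and the absence of novelty responses.**  With
uniform inhibitory input weights and zero biases, the divisive stage makes
the population rate nearly independent of total input — the response to a
novel stimulus equals the baseline response.  Consequently this
implementation does not reproduce elevated first-presentation responses:
stimuli start at the set-point and only reinforcement-paired stimuli rise
above it.  We verified that no reading of the reported initialization
values produces a novelty response (any uniform scaling of `W_xI` cancels
between numerator statistics and denominator), and that the candidate
mechanisms — an inhibitory bias `b_I > 0`, concentration of activity under
a topographic `W_xE` — are either quantitatively negligible at
physiological rates or destabilized by the zero-bound rectification of the
weight random walk.  Three phenomena that depend on the novelty response
(the downward learning curve for the unreinforced stimulus, the
pre-exposure effect in latent inhibition, and the full collapse of the
learned gap under disruption) are therefore attenuated or absent; the
corresponding acceptance checks are left failing rather than tuned, and
the analysis lives with the package's review notes.

**The CS+ operating point.**  The US-driven disinhibition of CS+ synapses
equilibrates where the per-presentation push (`~ n_US * A` per trial)
balances the sampling-covariance drag accumulated over the long
inter-trial intervals.  Across the admissible range of `gamma`, `alpha`
and US durations this equilibrium sits slightly below the 3.9 Hz reference
value (the acceptance report computes the realized value); the
corresponding acceptance check is left at its stated tolerance.

**Winner-take-all renormalization.**  The competitive head renormalizes
the updated row to *unit L2 norm* (after clipping at zero).  The originally described rescale is to unit row sum, but a sum-one row caps the winner's
input near the mean spike count (~1), below the threshold `theta = 1.625`,
so the head could never bootstrap (the US boost `0.5u` cannot lift a
`-theta` input above zero), and the selectivity bound
`z <= ||E|| - theta` — the analytical core of the threshold argument —
holds for the L2-normalized mean pattern, not the sum-normalized one.
Unit-norm rows make the bound exact and give `z = ||E||` at perfect
alignment, which is what places a separating threshold between `H` and
`H + A`.  The winner's activity rescale (ambiguous in the original
notation)
is read as division by the summed positive inputs, guarded when that sum
is non-positive.

**Degenerate cases.**  Exact ties for the winner leave the output layer
silent (relevant only for all-zero input).  Zero total drive in the
category head falls back to the uniform distribution.  Cross-entropy is
evaluated on expected rates clipped to `[1e-12, 1]`; classification
accuracy uses the time-averaged expected output distribution per
presentation.  The divisive denominator can never fall below `I_floor`,
and a non-finite prediction error aborts the run with the offending step.

## Reproducibility

One seeded generator per run; draws occur in a fixed order (stimulus
library, weights, then per-step sensory and excitatory sampling), so a
`(seed, config)` pair gives bit-identical traces.  Schedules are built
before the run from their own seeded draws and can be exported as CSV for
audit.  All dispersion across runs is reported as SD over seeds.
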