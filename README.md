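# inhibrel

Simulator for a cortical **relevance-learning** circuit in which plasticity
of feedforward *inhibition* teaches a network to ignore stimuli that predict
nothing.

## The scientific problem

Cortical circuits respond to novel inputs but learn to suppress responses
to inputs that never predict reward or punishment — the behavioural
phenomena of latent inhibition, blocking and learned irrelevance.  A
long-standing hypothesis ties failures of this filtering (as in
schizophrenia) to dysfunction of fast-spiking PV+ inhibitory interneurons.
`inhibrel` implements a computational account of that link: the *total*
level of excitatory activity in a population codes the expected unsigned
magnitude of upcoming reinforcement ("relevance"), and that code is
trained by a temporal-difference rule acting on the synapses that drive
feedforward inhibition.

## The model in brief

Per 20 ms step, sensory Poisson units `x` drive excitatory rates through
divisive feedforward inhibition

    I      = W_xI . x + b_I
    phi_E  = (W_xE . x + b_E) / (W_IE I + I_floor),   E ~ Poisson(dt phi_E)

Salience is the deviation of the excitatory spike-count norm from a
homeostatic set-point, `S(t) = ||E(t)||_2 - H`, and learning makes `S`
track `A U(t)`, the scaled unsigned value (discounted sum of future
US magnitudes), via the unsigned TD error

    beta(t) = A u(t) + gamma S(t) - S(t-1)
    W_xI,j <- max(0, W_xI,j - alpha beta(t) x_j(t-1))

so unsurprising stimuli accrue inhibition until the network treats them
like no stimulus at all (`||E|| -> H`, i.e. 2.6 Hz mean rate), while
US-predictive stimuli settle above it (toward `H + A`).  Downstream, a
winner-take-all "amygdala" head with threshold `theta = H/4` turns the
relevance code into gated fear learning/expression, and a
linear-normalized categorization head trained by gradient descent shows
that stimulus identity can be multiplexed with relevance in the same
population.

Six classical-conditioning protocols are built in: `learning_to_ignore`,
`blocking`, `latent_inhibition`, `fear_expression`, `categorization`,
`learned_irrelevance`.

## Worked example

```r
library(inhibrel)

cfg <- sim_config(seed = 42)
set.seed(42)
sched <- build_protocol("learning_to_ignore", cfg)
run <- run_protocol(sched, cfg, seed = 42)

tt <- run$trials
cs0 <- subset(tt, stimulus == 2)     # never paired with the US
csp <- subset(tt, stimulus == 1)     # predicts the US
round(c(cs0_norm = mean(tail(cs0$mean_norm, 10)),
        csp_rate = mean(tail(csp$mean_phi_E, 10)),
        csp_S    = mean(tail(csp$mean_S, 10))), 3)
#> cs0_norm csp_rate    csp_S
#>    6.376    3.207    0.914
```

After 50 presentations the unreinforced stimulus evokes a spike-count norm
of ~6.4, statistically at the homeostatic set-point `H = 6.5` — the
network treats it like no stimulus — while the US-predictive stimulus
holds a mean excitatory rate of ~3.2 Hz, above the 2.6 Hz baseline: a
positive salience (`S ~ 0.9` norm units) that a thresholded readout can
use to gate behaviour.

The same circuit can be driven from the command line:

```sh
Rscript -e 'inhibrel::inhibrel_main()' run latent_inhibition \
    --seed 7 --runs 3 --phase-disruption conditioning --out out/li
Rscript -e 'inhibrel::inhibrel_main()' report out/li
```

which exports `trials.csv` (per-presentation salience, rates, fear
responses) and `manifest.json` (full configuration and seeds).

## Package layout

* `R/network.R` — Poisson sampling, inhibitory drive, divisive rates
* `R/relevance.R` — salience, unsigned TD error, eligibility traces, the
  three plasticity variants
* `R/amygdala.R`, `R/category.R` — the two output heads
* `R/stimuli.R`, `R/protocols.R`, `R/run.R` — stimulus world, the six
  event schedules, and the simulation loop
* `R/metrics.R`, `R/cli.R` — trial metrics, export, command line
* `vignettes/relevance-model.Rmd` — model assumptions, parameter
  rationale, numerical choices and known limitations
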