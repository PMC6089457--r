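Package: inhibrel
Title: Relevance Learning Through Plastic Feedforward Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulator for a Poisson rate-network model of cortical relevance
    learning, in which an unsigned temporal-difference rule trains feedforward
    inhibitory synapses so that the norm of excitatory population activity
    encodes the expected magnitude of reward or punishment.  Includes a
    winner-take-all ("amygdala") output head, a linear-normalized
    categorization head trained by gradient descent, generators for the
    classical-conditioning protocols used to probe the model (learning to
    ignore, blocking, latent inhibition, fear expression, multiplexed
    categorization, learned irrelevance), trial-level metrics, delimited-text
    export, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
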