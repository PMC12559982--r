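Package: calyxstp
Title: Two-Step Vesicle Priming Kinetics, Tensor Decomposition and Pool
    Estimation for Synaptic Short-Term Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting synaptic strength and short-term plasticity
    at large glutamatergic terminals such as the calyx of Held. Implements a
    five-state kinetic scheme of synaptic vesicle docking, priming and fusion
    (empty, loosely docked, tightly docked, labile tightly docked and
    refractory sites) with calcium-dependent priming rates driven by a
    phenomenological 'effective' calcium transient; a hybrid ODE/event
    simulator of evoked release during stimulus trains; closed-form
    equilibrium analysis of the priming states; a constrained non-negative
    tensor factorization (NTF) that decomposes trains of quantal contents
    recorded across synapses and stimulation frequencies into per-synapse
    component amplitudes and shared base functions; estimators for the
    fast-releasing vesicle pool, fusion probability and classical short-term
    plasticity metrics; and a seeded synthetic-data generator emulating a
    heterogeneous population of model synapses for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
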