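Package: sedpnr
Title: Compartmental Modelling of Misinformation Spread in Online Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for the SEDPNR
    (Susceptible-Exposed-Doubtful-Positively infected-Negatively
    infected-Restrained) compartmental model of rumor and misinformation
    diffusion in online social networks. Provides deterministic ODE
    integration (adaptive and forward-Euler), stochastic agent-based
    simulation on scale-free contact graphs, next-generation-matrix basic
    reproduction number, Jacobian and eigenvalue stability analysis,
    equilibrium and Lyapunov diagnostics, a distrust extension, time-windowed
    intervention scenarios, country-level parameterization from HDI and
    internet-penetration indices, and constant-hazard SI/SIR/SIS/SEDIS
    baseline models for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
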