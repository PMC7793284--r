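Package: ctlsim
Title: Agent-Based Simulation and Model Selection for CTL-Mediated Killing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-dimensional off-lattice agent-based model of cytotoxic
    T lymphocytes (CTLs) searching for and killing stationary virus-infected
    target cells, as observed by intravital 2-photon microscopy. CTLs follow
    a persistent random walk with empirically binned speed and turning-angle
    distributions, hard-core nuclear repulsion and mixed periodic/closed
    boundaries. Nine alternative cell-death mechanisms are implemented
    (constant killing probability, contact-count integration on either cell
    side, per-cell heterogeneity, and four damage-accumulation variants with
    optional repair or saturation), together with the option of "zombie
    contacts" with targets that have already committed to die. Eight
    imaging-style readout distributions, the per-capita killing rate and
    kill fractions are computed from simulated contact logs, and a
    sum-of-squares cost with AIC-based ranking supports grid-search fitting
    and hypothesis discrimination.
License: MIT
Encoding: UTF-8
Imports: Rcpp, stats, utils, graphics, grDevices, jsonlite, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
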