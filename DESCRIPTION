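Package: anespec
Title: Analytic Power Spectra of a Linear Excitatory-Inhibitory Neural
    Population Model Under Propofol
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for a linear two-population (excitatory/inhibitory) neural
    model of anesthetic action on cortical EEG rhythms. Provides closed-form
    eigenvalue and stability analysis of the zero-wavenumber mode (trace and
    determinant geometry, stable-focus band in the ratio of inhibitory to
    excitatory synaptic decay times, Hopf-threshold loci at requested
    frequencies), the analytic power spectral density of the noise-driven
    system via its Green's function, the frequency and height of the spectral
    peak, scaling of the inhibitory synaptic decay time and efficacy with
    propofol concentration together with the critical-concentration analysis,
    and a seeded Euler-Maruyama simulator with Welch spectral estimation that
    cross-validates the analytics. A fixture generator produces random valid
    parameter sets for property-style testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
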