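Package: eetherm
Title: Stochastic Thermodynamics of Excitation Energy Transfer Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing excitation energy transfer (EET) in
    light-harvesting pigment-protein supercomplexes such as Photosystem II
    as continuous-time Markov chains. Reads and validates detailed-balanced
    excitonic rate matrices, attaches irreversible reaction-center traps and
    fluorescence/nonradiative loss channels, propagates the master equation,
    and decomposes the ensemble relaxation into time-resolved Shannon
    entropy, enthalpy and free-energy components. Extracts population
    contraction times (entropy maxima), enthalpy peaks, trap splitting
    probabilities, mean first passage trapping times and excitation
    lifetimes, with a kinetic Monte Carlo (Gillespie) cross-check and a
    generator of PSII-mimetic synthetic networks with Gaussian site-energy
    disorder for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
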