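Package: adcpbpk
Title: Physiologically Based Pharmacokinetic Simulation of Antibody-Drug
    Conjugate Drug-Drug Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the disposition of monomethyl auristatin E (MMAE)
    antibody-drug conjugates and their CYP3A4- and P-glycoprotein-mediated
    drug-drug interactions. A drug-to-antibody-ratio (DAR) stratified
    minimal PBPK model of the conjugated antibody (FcRn-mediated endosomal
    recycling, catabolism, DAR-proportional clearance, deconjugation)
    releases payload into a whole-body PBPK model for MMAE with a
    permeability-limited liver (CYP3A4 metabolism and P-gp biliary efflux).
    A DDI engine couples perpetrator concentration streams to victim
    elimination through competitive inhibition, mechanism-based
    inactivation, enzyme-turnover induction and a manual P-gp relative
    activity factor. Virtual cancer-population trials, noncompartmental
    analysis and geometric-mean-ratio statistics reproduce phase-1-style
    exposure and interaction summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
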