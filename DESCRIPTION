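Package: menpstim
Title: Simulating Neural Stimulation by Magnetoelectric Nanoparticles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models wireless stimulation of a CA1 pyramidal neuron by
    magnetoelectric nanoparticles (MENPs). MENPs are represented as
    split-sphere dipole sources in a homogeneous conductive medium, solved
    analytically as an exterior Laplace series in Legendre polynomials. The
    resulting static extracellular potential is coupled quasi-statically to a
    multicompartment active cable model (Na, KDR, KA and Ih conductances on a
    sectioned morphology with Hodgkin-Huxley style gating) integrated with an
    implicit Hines tree solver. Analysis tools include the activating
    function along the axon, spike detection and initiation-site
    classification, titration of the amplification coefficient required for
    action-potential generation, and sweep drivers over particle size,
    orientation, distance, stimulus frequency and static bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
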