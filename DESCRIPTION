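Package: ncavidity
Title: Multiscale Monte Carlo Model of Nanocarrier Adhesion to Fluctuating
    Cell Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the adhesion of antibody-functionalized nanocarriers to
    a thermally fluctuating cell membrane represented as a dynamically
    triangulated surface with Helfrich curvature elasticity.  Mobile flexural
    receptors on the membrane bind rigid ligands on the carrier through a Bell
    bond potential, and the coupled system is sampled with a seven-move
    Metropolis Monte Carlo engine that uses configurational-bias (Rosenbluth)
    sampling for the rare flexure and bond moves.  The package reconstructs
    potentials of mean force along the carrier-membrane separation by umbrella
    sampling with WHAM and thermodynamic-integration anchoring, extracts
    renormalized membrane elastic parameters from the height-fluctuation
    spectrum (including a mean-field cytoskeletal pinning workflow), assembles
    absolute multivalent association constants from bond statistics and
    entropy estimators, and converts those avidities into organ-level tissue
    targeting predictions with bootstrap statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
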