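Package: phenopet
Title: Multiscale Tumor Growth Simulation and Synthetic PET Radiomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Hybrid multiscale simulation of tumor growth in vascularized
    tissue coupling a cellular agent lattice with explicit finite-difference
    reaction-diffusion grids for oxygen and glucose (Michaelis-Menten
    consumption, periodic boundaries, Dirichlet vessel sources). Simulated
    cell maps are converted to pseudo-SUV images, forward-projected,
    degraded with Poisson noise and reconstructed with ordered-subset
    expectation maximization at PET resolution. Gray-level co-occurrence
    matrix (GLCM) Haralick texture features are extracted under a fixed-bin
    IBSI-style protocol, and phenotype discriminability is quantified with
    Welch t-scores, silhouette scores and the Calinski-Harabasz criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    cluster,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
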