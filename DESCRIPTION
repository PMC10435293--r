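Package: cnoddi
Title: Constrained NODDI Modelling of White Matter Microstructure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for neurite orientation dispersion and density imaging
    (NODDI) of the brain from multi-shell diffusion-weighted MRI, including a
    constrained variant (C-NODDI) in which the isotropic cerebrospinal-fluid
    signal fraction is estimated beforehand from the b=0 image by hidden Markov
    random field tissue segmentation and held fixed during model fitting.
    Provides Watson-distribution spherical mathematics, compartmental forward
    signal models with optional T1/T2 relaxation weighting for echo-time
    dependence experiments, voxelwise two-stage fitting, digital phantom and
    Rician noise simulation, and region-of-interest statistics (quadratic age
    models with false-discovery-rate control and plasma biomarker regression).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
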