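Package: renograft
Title: Simulation and Quantitative MRI Assessment of Cardiac-Death Kidney Grafts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Digital-phantom simulation and quantitative analysis of BOLD
    (T2*-weighted) and diffusion-weighted MRI of kidney grafts harvested
    after donor cardiac death. Generates compartmentalised kidney phantoms
    (cortex, outer/inner stripe of the outer medulla, inner medulla) with
    red-cell-congestion lesions and synthetic eosin histology; forward-models
    gradient-echo and diffusion-weighted signals with optional Gaussian or
    Rician noise; computes per-pixel T2* and apparent-diffusion-coefficient
    maps and the compartmental signal-intensity ratio; transfers compartment
    ROIs unchanged between co-registered maps and summarises them at the
    kidney level; quantifies congested-area fractions on synthetic eosin
    histology; runs the accompanying small-sample statistical protocol
    (pooled-variance t-tests from summary statistics, paired tests, one-way
    ANOVA with Tukey comparisons); and issues a rule-based graft-viability
    call from the joint pattern of inner-stripe signal depression and
    outer-medullary edema.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    tiff,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
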