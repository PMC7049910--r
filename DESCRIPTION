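Package: dcedyn
Title: Dynamic Spectral and Texture Descriptors for DCE-MRI of Cerebral
    Small Vessel Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterise dynamic contrast-enhanced MRI (DCE-MRI)
    of the brain with region-of-interest descriptors that evolve over the
    acquisition: radially averaged power spectra from the 3D discrete
    Fourier transform, Haralick features from grey-level co-occurrence
    matrices, uniform local binary pattern histograms, local configuration
    patterns, and signal-enhancement curves with their area-under-curve
    and post-peak-slope summaries.  Descriptor trajectories are reduced to
    a single score per subject and region with a multivariate functional
    principal component analysis, and scores are related to clinical
    covariates with Kruskal-Wallis tests and standardised multiple
    regression.  A digital phantom generator emulates the acquisition
    protocol and cohort covariate distributions so the full pipeline can
    be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
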