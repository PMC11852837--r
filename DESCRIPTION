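Package: gliopred
Title: Multiparametric MRI Response Assessment in Glioblastoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distinguishes true tumor progression from pseudoprogression in
    treated glioblastoma using multiparametric MRI. Fits per-voxel diffusion
    tensors from diffusion-weighted volumes and derives mean diffusivity,
    fractional anisotropy and Westin shape coefficients; converts dynamic
    susceptibility contrast time series to relaxation-rate curves, fits
    gamma-variate first-pass responses, applies a two-parameter leakage
    correction and integrates relative cerebral blood volume maps; segments
    contrast-enhancing lesions by subtraction-image thresholding and extracts
    per-lesion median and percentile features; scores lesions with a logistic
    predictive-probability model thresholded at 50 percent; and evaluates
    bidimensional tumor burden under modified RANO persistence rules. A seeded
    digital phantom generator makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
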