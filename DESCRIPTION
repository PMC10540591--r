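Package: cortexstress
Title: Decoding Self-Reported Stress Levels from Cortical fMRI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A simulation-backed framework for decoding an 8-level self-reported
    stress state from cortical fMRI data. Provides synthetic BOLD generation with
    a double-gamma hemodynamic response, AR(1) noise and ordinal spatial encoding;
    sampling of 4D volumes onto a triangulated gray-white surface; smoothing along
    the cortical manifold and farthest-point patch downsampling into a
    low-dimensional feature set; label alignment, nuisance regression, high-pass
    filtering, Wiener deconvolution and block averaging; per-subject SVM, SVR and
    multilayer-perceptron decoders evaluated by RMSE and accuracy over repeated
    report-level splits; and permutation-based significance testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    RNifti,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
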