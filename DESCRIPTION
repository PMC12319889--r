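Package: hippolaminar
Title: Laminar fMRI Analysis of Hippocampal Subfields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Depth-dependent (laminar) analysis of 7T gradient-echo BOLD fMRI
    of the human hippocampus on folded subfield surfaces. Builds equidistant
    depth-sampling schemes between inner and outer subfield boundaries with
    forced inclusion of the equivolume midthickness, extracts laminar profiles
    by tricubic resampling, maps venous and arterial vasculature from
    susceptibility-weighted and time-of-flight images (multiscale Hessian
    vesselness and a Haar wavelet detail filter), quantifies venous bias from
    a breath-hold hypercapnia experiment with multi-echo T2* fitting and
    inverse-TE echo weighting, characterizes depth-resolved noise (tSNR,
    Weisskoff test, anatomical-component nuisance regressors), fits robust
    weighted least-squares GLMs for an autobiographical-memory paradigm, and
    provides the matching inference layer (exact Wilcoxon signed-rank with
    Hochberg step-up, Benjamini-Hochberg FDR, and small-sample mixed-effects
    depth-model comparisons with Kenward-Roger approximated F-tests). A
    synthetic-data generator produces folded subfield surfaces, multi-echo
    volumes and task time series with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    RNifti,
    xml2,
    lme4,
    pbkrtest,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
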