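Package: strical
Title: Downstream Analysis of Microendoscopic Calcium Imaging During
    Self-Initiated and Learned Actions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream analysis of one-photon microendoscopic
    calcium imaging recorded together with head-mounted accelerometry in freely
    moving mice. Segments movement bouts from total body acceleration using a
    bimodal-histogram threshold, extracts somatic and annular (neuropil) dF/F
    with a sliding-minimum baseline, detects calcium transients, tests
    event-locked responses with a circular-shift bootstrap, quantifies response
    reliability, per-event population recruitment and cross-session overlap of
    responsive neurons, measures distance-binned pairwise signal correlations,
    and computes shift-predictor-corrected joint peristimulus time histograms
    (JPSTHs) with diagonal noise-correlation statistics. Includes a synthetic
    session generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
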