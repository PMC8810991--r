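Package: deferral
Title: Learning to Defer with Ensemble Uncertainty for Selective
    Clinical Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage selective prediction for computer-aided diagnosis.
    Stage one trains a deep ensemble of fully connected diagnostic
    networks and summarises its per-patient output as two entropy-based
    epistemic uncertainty measures (ensemble entropy and diagnostic
    entropy).  Stage two trains a defer network on the member
    probabilities plus both entropies with a weighted defer loss, so that
    each patient is either given an automated diagnosis or deferred to a
    human expert.  Includes the learning-to-defer baseline without
    uncertainty information (LD), direct triage by an entropy threshold
    (DT), a synthetic cohort generator with controllable difficulty
    structure, coverage-accuracy sweep tooling, and ggplot2 displays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
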