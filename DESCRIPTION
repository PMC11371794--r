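Package: cobci
Title: Group-Member Selection for Collaborative RSVP Brain-Computer Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-user (collaborative) EEG brain-computer interfaces
    based on rapid serial visual presentation (RSVP). Implements individual
    capability scoring via the xDAWN signal to signal-plus-noise ratio,
    collaborative capability scoring via inter-subject ERP correlation, the
    combined MIMC score with cross-validated weight selection, sequential
    forward floating selection (SFFS) of sub-groups, multi-user EEG fusion
    (average ERP, parallel/serial combination, weighted voting), hierarchical
    discriminant component analysis (HDCA) for single-trial ERP detection, and
    Euclidean-space covariance alignment for cross-session transfer. Includes a
    synthetic multi-subject RSVP EEG simulator with planted ground truth so the
    full pipeline can be exercised and validated without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
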