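Package: fbmap
Title: All-Optical Mapping of Cortico-Cortical Feedback Influence and
    Dendritic Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mesoscale all-optical experiments that
    combine two-photon holographic optogenetic stimulation with two-photon
    calcium imaging across retinotopically organized visual areas. Provides
    reverse-correlation receptive-field mapping and smoothed retinotopic
    surfaces with border-zone exclusion, rank-sum responder detection under
    false-discovery-rate control, null-normalized retinotopic-distance
    distributions with resampling-based matching controls, iterative detection
    and statistical confirmation of long-range feedback-recipient dendritic
    spines, a branch boosting-index statistic, spatial profiling of local
    dendritic calcium events, soma-dendrite pairing analyses, and a
    ground-truthed synthetic-data generator emulating population and dendrite
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
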