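Package: erpcluster
Title: Cluster-Based Permutation Tests and Effect Sizes for Event-Related EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Group-level nonparametric inference for multichannel event-related
    potentials (ERPs). Implements the spatio-temporal cluster-based permutation
    test with the max-cluster statistic for family-wise error control in paired,
    independent-groups and regression designs; three Cohen's d quantifications of
    cluster effects (average over the cluster, maximum within the cluster, and a
    circumscribing-rectangle summary); channel neighbourhood construction by
    distance or Delaunay triangulation; a deterministic single-subject
    preprocessing pipeline (epoching with oddball-paradigm trial selection,
    zero-phase band-pass filtering, whole-epoch baseline correction, automated
    artifact rejection, bad-channel interpolation, linked-mastoid re-referencing,
    per-condition averaging and a trial-retention inclusion rule); reading,
    writing and validation of BIDS-EEG dataset trees with BrainVision or
    tab-separated recordings; and a seeded oddball-ERP simulator with analytic
    ground truth for validating the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    deldir,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
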