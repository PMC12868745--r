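Package: fcmtools
Title: Fuzzy Cognitive Mapping for Participatory Causal Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, validates and simulates fuzzy cognitive maps (FCMs) elicited
    from stakeholder interviews. Provides Likert-to-fuzzy weight standardisation
    and consensus aggregation of respondent causal maps with presence and
    mean-weight retention rules; degree-based structural metrics with
    driver/receiver/ordinary typing; clamped-node steady-state scenario
    simulation with automatic pruning of unaffected concepts; reconstruction of
    a consensus network from published per-concept degree marginals; and a
    synthetic respondent generator for parameter-recovery experiments. Ships a
    36-concept acid-mine-drainage (AMD) case-study fixture reconstructed from
    its published marginal profile.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
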