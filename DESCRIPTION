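Package: pocketgauge
Title: Assessment of Predicted Multi-Domain Protein Structures Against
    Experimental References
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quality assessment of AI-predicted models of multi-subdomain
    proteins such as the NLRP3 inflammasome sensor. Aggregates per-residue
    pLDDT confidence into per-domain summaries, performs rigid-body (Kabsch)
    superposition with a domain-partitioned RMSD protocol against an
    experimental reference, quantifies binding-pocket formation through
    key-residue distance and deviation matrices, detects salt bridges and
    hydrogen bonds, and computes contact occupancies and RMSD time series
    over molecular-dynamics trajectories. Ships a synthetic-structure and
    trajectory generator with exact ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
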