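Package: silencerscape
Title: Discovery and Characterization of H3K27me3-Rich Regions (Super-Silencers)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for calling H3K27me3-rich regions (MRRs,
    candidate super-silencers) from ChIP-seq peaks and signal by stitching,
    ranking and a slope-1 rank cutoff; annotating chromatin-interaction
    anchors with chromatin states and computing observed/expected state-pair
    enrichment under a marginal homogeneous model; classifying gene-MRR
    looping as proximal, distal or internal; same-chromosome permutation
    overlap testing; entropy-based expression specificity across tissue
    facets; differential 4C-seq loop classification (gained/lost/unchanged)
    with bait-distance summaries; and ChIP-seq signal-area integration at 4C
    regions. A synthetic-data module generates every input with planted
    ground truth so the whole pipeline runs end-to-end without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
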