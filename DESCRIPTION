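Package: dusmapr
Title: Mapping and Quantifying tRNA Dihydrouridine from MALDI Fragment
    Masses, Aniline-Cleavage Sequencing and Flavoenzyme Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Inference machinery for locating dihydrouridine (D) in
    bacterial tRNAs and attributing each site to its synthase. Provides
    in silico RNase T1 and RNase A digestion of modification-annotated
    tRNA sequences, monoisotopic and average mass computation for
    modified oligonucleotide fragments, diagnostic-fragment selection
    and MALDI peak matching with a knockout-panel attribution grid,
    AlkAnilineSeq-style per-position cleavage scoring (NormCount and
    stop ratio) with site calling and stoichiometry heatmaps,
    Michaelis-Menten and Hill fitting for NAD(P)H oxidase activity and
    cooperative tRNA binding, and seeded synthetic-data generators that
    produce every input the pipeline consumes together with ground
    truth, so the whole analysis is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
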