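Package: csindel
Title: Conserved Signature Indels and Core-Protein Phylogenomics for
    Bacterial Taxon Demarcation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for demarcating bacterial taxa from proteome sets:
    greedy construction of core protein families, per-family multiple
    sequence alignment with gap-fraction trimming and concatenation into a
    partitioned super-matrix, core-protein average amino-acid identity
    (AAI) with per-clade summaries and a diagnostic neighbor-joining tree,
    and discovery of clade-specific conserved signature indels (CSIs) in
    protein alignments, including isolated-exception and
    missing-homologue bookkeeping. A clade-structured synthetic proteome
    generator plants indels with a ground-truth manifest so that every
    stage of the pipeline can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'aai.R'
    'accessors.R'
    'simulate.R'
    'csiscan.R'
    'families.R'
    'io.R'
    'msa.R'
    'render.R'
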