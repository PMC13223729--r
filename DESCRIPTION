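Package: karyopaint
Title: Ancestral Karyotype Painting and Chromosome Rearrangement Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-silico chromosome painting and ancestral karyotype
    reconstruction for fishes with lineage-specific whole-genome
    duplications. Genes on descendant chromosomes are assigned the
    identity of the ancestral chromosome carrying their best protein
    hit, minor colors are filtered, chromosomes are segmented into
    contiguous color blocks, and fusion, fission, translocation and
    complex rearrangement events are classified from block
    compositions and placed on a phylogeny by Dollo parsimony.
    Homoeologous chromosomes of tetraploid lineages are collapsed into
    ploidy units before event counting, and a consensus ancestral
    karyotype is reconstructed across species. A genome-evolution
    simulator generates painted gene tables under declared event
    histories for end-to-end validation, and assembly-level utilities
    estimate genome size from k-mer histograms and detect telomeric
    repeat arrays at sequence ends.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr
Config/testthat/edition: 3
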