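Package: plastscan
Title: Pairwise Plastid Genome Comparison and Marker Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares two annotated plastid (chloroplast) genomes at low
    divergence and ranks their noncoding regions as candidate phylogenetic
    markers. From a pair of annotated genome records (or a supplied pairwise
    alignment) it extracts introns and intergenic spacers, calls SNPs, indel
    events and inversions, computes per-region potentially informative
    characters (PICs) and p-distances, characterises the mutational context
    (homopolymer, simple-sequence-repeat and other indel classes; AT content
    around substitutions; 500 bp sliding-window tracks), and applies an
    amplicon-size and microsatellite-aware marker selection heuristic. A
    bundled simulator generates circular quadripartite genome pairs with a
    known edit script for ground-truth validation of every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
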