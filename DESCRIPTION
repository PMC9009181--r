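Package: flavhap
Title: Haplotype Evidence Chains for Flavonoid 3'5'-Hydroxylase Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based evidence chain for classifying natural coding-sequence
    haplotypes of cytochrome P450 flavonoid hydroxylase genes (CYP75 family).
    Calls nucleotide variants between haplotypes and a reference CDS, derives
    protein-level consequences (frameshifts, premature stops, domain
    truncations), annotates the core P450 motifs and substrate recognition
    sites (SRS1-6), discriminates flavonoid 3'5'-hydroxylase from
    3'-hydroxylase by the SRS6 rule residue, builds median haplotype networks,
    detects intragenic recombinant haplotypes by triplet scanning with a
    permutation test, and screens proteomes with the heme-motif/domain
    completeness filter cascade. Ships a deterministic synthetic-data
    generator emulating the nine common-bean V-gene haplotypes together with
    seeded random mutation panels carrying ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
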