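Package: haplosweep
Title: Selective-Sweep and Gene-Flow Analysis of Phased Haplotype Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic analysis of per-locus haplotype alignments,
    oriented towards amplicon resequencing of insecticide-resistance loci in
    Anopheles mosquitoes. Computes per-population diversity summaries
    (segregating sites, haplotype diversity, nucleotide diversity, Watterson's
    theta), neutrality tests (Tajima's D, Fu and Li's D*, Fu's FS with
    coalescent significance), Nei-Gojobori pN/pS ratios, pairwise population
    differentiation (Hudson FST, GST, HST, KST, NST with permutation tests and
    Nm), statistical-parsimony haplotype networks with a 95% connection limit,
    neighbour-joining trees on Kimura 2-parameter and FST distances, and a
    multi-locus sweep scan across a genomic region. A seed-deterministic
    coalescent simulator (neutral, island-model structure, and star-genealogy
    partial sweeps) generates synthetic regional datasets so the whole
    pipeline can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
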