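Package: divscan
Title: Windowed Divergence Scans and Genomic Islands of Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for scanning two-population whole-genome SNP data for
    genomic islands of differentiation. Reads multi-sample (all-sites) VCF,
    population maps and GFF3 annotation; applies configurable hard filters
    and greedy pairwise-r2 LD pruning; computes per-individual
    heterozygosity and sliding-window nucleotide diversity (pi), absolute
    divergence (Dxy) and Weir-Cockerham Fst with missing-data-aware
    denominators; flags empirical top-1% outlier windows, merges them into
    regions and intersects Fst and Dxy outliers into core islands with
    overlapping genes; estimates pairwise method-of-moments IBD relatedness
    (PI_HAT) and LD decay in distance bins; and tests functional-term
    over-representation with one-sided hypergeometric tests. Includes a
    Balding-Nichols two-population simulator with planted divergence
    islands, invariant sites, missingness and pedigree pairs that emits
    ground-truth fixtures in the pipeline's input formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
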