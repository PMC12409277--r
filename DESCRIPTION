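Package: sedsift
Title: Authentication of Ancient DNA and Proteins from Bone-Adhered Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for authenticating ancient biomolecules recovered from
    sediments adhering to archaeological bone. Implements read-level quality
    control (length, mean quality, DUST low-complexity, exact
    deduplication), validation of k-mer taxonomic classification reports
    with an E-score statistic, competitive assignment of reads among
    phylogenetically close candidate reference genomes, position-wise
    terminal deamination (C-to-T / G-to-A) misincorporation profiling with
    group comparisons, per-sample biological statistics (Ry and
    coverage-ratio genetic sex, mitochondrial contamination from allele
    depths, transversion-based heterozygosity screening, filtered consensus
    calling), genotype-level concordance statistics for imputed and
    pseudohaploid calls, and species-diagnostic peptide discrimination from
    peptide-spectrum-match tables. A self-contained simulator generates
    reads, alignments, pileups, classification reports and PSM tables with
    known truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
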