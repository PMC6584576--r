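Package: uvlinker
Title: Sex-Linked Sequence Discovery and Molecular Divergence for UV Sex-Chromosome Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative genomics of haploid (UV) sex-chromosome
    systems such as dioecious liverworts. Provides GC-content contamination
    screening of read sets and scaffolds, k-mer based coverage estimation,
    a windowed male:female differential-coverage scan for sex-linked regions,
    a sex-marker candidate cascade over homology hits, pairwise dN/dS
    estimation by Nei-Gojobori (1986) counting with Jukes-Cantor correction,
    percent-identity summaries by sequence class, candidate-gene copy-number
    flagging, and qPCR relative quantification with factorial expression
    models. A synthetic-data generator emulates the statistical structure of
    a male/female whole-genome resequencing study (GC-distinct contaminants,
    U/V sex-specific segments, organelles at elevated depth, ortholog codon
    pairs evolved at controlled omega) so every stage is testable against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    graphics,
    lmerTest,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
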