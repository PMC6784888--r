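Package: sagkit
Title: Ploidy, Genome Recovery and Comparative Screens for Single
    Amplified Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for single amplified genomes (SAGs) from
    uncultured fungi. Simulates multiple displacement amplification (MDA)
    coverage dropout with tract structure and per-tract gain variability,
    plants phased heterozygous variants under haploid, diploid or triploid
    models, and pools cells into sequencing libraries. Calls variants from
    per-site pileups with pooled-frequency filters, classifies ploidy from
    allele frequency spectra and k-mer spectra, and measures heterozygous
    SNP sharing across independent libraries. Models per-library genome
    recovery, co-assembly union recovery and marker-based completeness.
    Implements comparative screens: a core-metabolism deficiency filter on
    binary enzyme presence/absence matrices, CAZyme-to-protease ratio
    regression, single-copy orthogroup selection with supermatrix missing
    data statistics, Fitch parsimony ancestral gain/loss reconstruction and
    Robinson-Foulds tree congruence checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
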