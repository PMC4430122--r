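Package: oligohops
Title: Design and Analysis of Oligopaint and Haplotype-Specific FISH Probes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for oligonucleotide fluorescence in-situ hybridization
    (FISH) experiments built on Oligopaint probes. Mines candidate probe
    sequences from a genome under composition, melting-temperature, motif and
    k-mer uniqueness filters; designs cognate pairs of haplotype-specific
    (HOP) probes around single-nucleotide polymorphisms together with
    SNP-avoiding interstitial probes; assembles synthesis-ready oligos with
    primer and secondary-oligo/DNA-PAINT docking architectures and screens
    secondary oligos for orthogonality; simulates single-molecule (STORM)
    localization data on lattice polymer models grown as self-avoiding walks
    and equilibrated by bond-fluctuation and pivot Monte-Carlo moves; and
    quantifies FISH spot tables via focus merging, chromatic correction,
    co-localization, homologue-pairing calls, concordance tables and exact
    tests. Includes seeded synthetic generators for diploid genomes with SNPs
    and for nuclear spot fields with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    vcfR,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
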